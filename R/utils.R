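## internal helpers shared across modules

# run code under a fixed seed without clobbering the caller's RNG state;
# generators must be pure functions of (config, seed)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# percentage rounded half away from zero to `digits` decimals (base round()
# is half-even and would break printed-table arithmetic)
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

pct <- function(num, den, digits = 2L) {
  if (den == 0) return(0)
  round_half_up(num / den * 100, digits)
}

# log(sum(exp(lx))) without overflow
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf,
                                 integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_input(sprintf("'%s' must be a single number", name))
  if (x < lo || x > hi)
    stop_input(sprintf("'%s' must be in [%s, %s], got %s", name, lo, hi, x))
  if (integerish && x != floor(x))
    stop_input(sprintf("'%s' must be an integer, got %s", name, x))
  invisible(x)
}

is_nucleotide <- function(x) grepl("^[ACGT]*$", x)
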