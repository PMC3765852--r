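#' Delta-delta-Ct relative expression from qPCR threshold cycles
#'
#' Technical replicates are averaged within each biological replicate, target
#' and reference (internal control) cycles are differenced to a per-replicate
#' delta-Ct, biological replicates are then averaged per condition; delta-
#' delta-Ct is the treated minus control difference and relative expression is
#' `2^(-ddCt)`. The across-biological-replicate standard deviation of the
#' per-replicate relative expression is reported alongside.
#'
#' @param measurements data frame with columns `gene`, `condition` (the value
#'   `"control"` names the baseline; every other value is a treated
#'   condition), `bio_rep`, `tech_rep`, `ct_target`, `ct_reference`. Ct
#'   values must be positive and finite.
#' @param pooled average all technical x biological wells together instead of
#'   the nested technical-within-biological scheme.
#' @return data frame with one row per gene x treated condition: columns
#'   `gene`, `condition`, `dct_control`, `dct_treated`, `ddct`, `rel_expr`,
#'   `sd_rel`, `n_bio`.
#' @export
#' @examples
#' ct <- expand.grid(gene = "PAL", condition = c("control", "treated"),
#'                   bio_rep = 1:3, tech_rep = 1:2)
#' ct$ct_target <- ifelse(ct$condition == "treated", 22, 23)
#' ct$ct_reference <- 18
#' ddct(ct)$rel_expr  # 2: one-cycle earlier amplification
ddct <- function(measurements, pooled = FALSE) {
  need <- c("gene", "condition", "bio_rep", "tech_rep",
            "ct_target", "ct_reference")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements)))
    stop_input("measurements need columns ",
               paste(need, collapse = ", "))
  m <- measurements
  m$gene <- as.character(m$gene)
  m$condition <- as.character(m$condition)
  if (!all(is.finite(m$ct_target)) || !all(is.finite(m$ct_reference)) ||
      any(m$ct_target <= 0) || any(m$ct_reference <= 0))
    stop_input("Ct values must be positive and finite")
  if (!"control" %in% m$condition)
    stop_input("no rows for the 'control' condition")

  # delta-Ct per (gene, condition, biological replicate): technical replicates
  # averaged first, then target minus reference
  key <- interaction(m$gene, m$condition, m$bio_rep, drop = TRUE)
  dct_bio <- data.frame(
    gene = tapply(m$gene, key, `[`, 1),
    condition = tapply(m$condition, key, `[`, 1),
    dct = tapply(m$ct_target, key, mean) - tapply(m$ct_reference, key, mean),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (pooled) {
    key2 <- interaction(m$gene, m$condition, drop = TRUE)
    dct_bio <- data.frame(
      gene = tapply(m$gene, key2, `[`, 1),
      condition = tapply(m$condition, key2, `[`, 1),
      dct = tapply(m$ct_target, key2, mean) -
        tapply(m$ct_reference, key2, mean),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }

  out <- list()
  for (g in unique(dct_bio$gene)) {
    gb <- dct_bio[dct_bio$gene == g, , drop = FALSE]
    ctrl <- gb$dct[gb$condition == "control"]
    if (length(ctrl) == 0L)
      stop_input("gene '", g, "' has no control measurements")
    treated_conditions <- setdiff(unique(gb$condition), "control")
    if (length(treated_conditions) == 0L)
      stop_input("gene '", g, "' has no treated measurements")
    for (cond in treated_conditions) {
      trt <- gb$dct[gb$condition == cond]
      ddct_val <- mean(trt) - mean(ctrl)
      rel_bio <- 2^(-(trt - mean(ctrl)))
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = cond,
        dct_control = mean(ctrl), dct_treated = mean(trt),
        ddct = ddct_val, rel_expr = 2^(-ddct_val),
        sd_rel = if (length(rel_bio) > 1L) sd(rel_bio) else NA_real_,
        n_bio = length(trt), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
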