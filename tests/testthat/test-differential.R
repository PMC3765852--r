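test_that("AC kernel reproduces closed-form values", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5, tolerance = 1e-12)
  expect_equal(ac_probability(1, 0, 1e6, 1e6), 0.25, tolerance = 1e-12)
  # exact rational value: C(20,15) / 2^21
  expect_equal(ac_probability(5, 15, 1e6, 1e6), 15504 / 2097152,
               tolerance = 1e-12)
  expect_error(ac_probability(-1, 0, 10, 10), "nonnegative")
  expect_error(ac_probability(0, 0, 0, 10), "at least 1")
})

test_that("AC kernel is a proper distribution over the second count", {
  for (x in c(0, 1, 5, 50)) {
    for (r in c(0.5, 1, 2)) {
      N1 <- 1e6
      total <- sum(ac_probability(x, 0:5000, N1, r * N1))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("AC p-value is symmetric and capped at the equal-count center", {
  expect_equal(ac_pvalue(10, 10, 1e5, 1e5), 1.0)
  expect_equal(ac_pvalue(0, 0, 3e5, 3e5), 1.0)
  set.seed(5)
  for (i in 1:50) {
    x <- rpois(1, 50); y <- rpois(1, 50)
    N1 <- sample(1e5:1e6, 1); N2 <- sample(1e5:1e6, 1)
    expect_equal(ac_pvalue(x, y, N1, N2), ac_pvalue(y, x, N2, N1),
                 tolerance = 1e-12)
  }
})

test_that("AC p-value matches the direct-summation oracle", {
  expect_equal(ac_pvalue(5, 50, 1e5, 1e5), oracle_ac_pvalue(5, 50, 1e5, 1e5),
               tolerance = 1e-10)
  set.seed(7)
  n <- 300
  x <- rpois(n, lambda = sample(c(1, 10, 100, 1000), n, TRUE))
  y <- rpois(n, lambda = sample(c(1, 10, 100, 1000), n, TRUE))
  N1 <- sample(1e4:1e7, n); N2 <- sample(1e4:1e7, n)
  expect_equal(ac_pvalue(x, y, N1, N2), oracle_ac_pvalue(x, y, N1, N2),
               tolerance = 1e-10)
})

test_that("identical profiles produce zero DE calls", {
  prof <- to_tpm(setNames(c(100, 50, 10), c("a", "b", "c")), 1e4)
  de <- call_degs(prof, prof)
  expect_equal(sum(de$call != "ns"), 0L)
  expect_equal(de$p_value, rep(1, 3), tolerance = 1e-9)
})

test_that("zero-TPM substitution fixes the log2 ratio, not the p-value", {
  p1 <- to_tpm(setNames(c(0, 100), c("a", "b")), 1e6)
  p2 <- to_tpm(setNames(c(8, 100), c("a", "b")), 1e6)
  de <- call_degs(p1, p2)
  expect_equal(de$log2_ratio[de$gene_id == "a"], log2(8 / 0.001),
               tolerance = 1e-9)
  # p-value comes from raw counts, unaffected by the substitution constant
  de2 <- call_degs(p1, p2, zero_tpm = 0.01)
  expect_equal(de$p_value, de2$p_value)
  expect_equal(de$p_value[de$gene_id == "a"],
               ac_pvalue(0, 8, 1e6, 1e6))
})

test_that("genes silent in both libraries are excluded from testing", {
  p1 <- to_tpm(setNames(c(0, 30), c("a", "b")), 1e4)
  p2 <- to_tpm(setNames(c(0, 35), c("a", "b")), 1e4)
  de <- call_degs(p1, p2)
  expect_true(is.na(de$p_value[de$gene_id == "a"]))
  expect_equal(attr(de, "n_tested"), 1L)
  expect_error(call_degs(p1, to_tpm(setNames(1, "zz"), 10)), "universe")
})

test_that("FDR is the BH step-up transform of the tested p-values", {
  set.seed(11)
  x <- rpois(300, 50); y <- rpois(300, 60)
  p1 <- to_tpm(setNames(x, paste0("g", 1:300)), 1e5)
  p2 <- to_tpm(setNames(y, paste0("g", 1:300)), 1e5)
  de <- call_degs(p1, p2)
  tested <- !is.na(de$p_value)
  expect_equal(de$fdr[tested], p.adjust(de$p_value[tested], "BH"))
  expect_true(all(de$fdr[tested] <= 1))
  # step-up: sorted FDRs are non-decreasing in p order after cummin from top
  ord <- order(de$p_value[tested])
  expect_true(all(diff(de$fdr[tested][ord]) >= -1e-12))
})

test_that("null count pairs keep the type-I error at or under nominal", {
  set.seed(13)
  m <- 2000
  lv <- rlnorm(m, 0, 1.2); lv <- lv / sum(lv)
  N <- 5e5
  x <- as.integer(rmultinom(1, N, lv))
  y <- as.integer(rmultinom(1, N, lv))
  keep <- x + y > 0
  p <- ac_pvalue(x[keep], y[keep], N, N)
  for (alpha in c(0.05, 0.01)) {
    se <- sqrt(alpha * (1 - alpha) / sum(keep))
    expect_lte(mean(p <= alpha), alpha + 3 * se)
  }
})

test_that("top table ranks by |log2 ratio| with FDR then id tie-breaks", {
  de <- structure(
    data.frame(gene_id = c("g1", "g2", "g3", "g4"),
               x = c(10, 0, 40, 5), y = c(100, 50, 4, 6),
               tpm1 = c(10, 0, 40, 5), tpm2 = c(100, 50, 4, 6),
               log2_ratio = c(3, 3, -3, 0.2),
               p_value = c(1e-8, 1e-6, 1e-9, 0.5),
               fdr = c(1e-7, 1e-5, 1e-8, 0.6),
               call = c("up", "up", "down", "ns"),
               stringsAsFactors = FALSE),
    class = c("differential_result", "data.frame"))
  top <- top_table(de, n = 20)
  expect_equal(top$gene_id, c("g3", "g1", "g2"))  # brute-force order
  expect_equal(top$single_sample, c(FALSE, FALSE, TRUE))
  expect_equal(top_table(de, n = 20, direction = "up")$gene_id,
               c("g1", "g2"))
  expect_equal(nrow(top_table(de, n = 1)), 1L)
  expect_error(top_table(de, n = 0), "positive")
  # sort-oracle on a random result set
  set.seed(17)
  m <- 50
  rde <- structure(
    data.frame(gene_id = sprintf("g%02d", 1:m),
               x = rpois(m, 20), y = rpois(m, 20),
               tpm1 = runif(m), tpm2 = runif(m),
               log2_ratio = round(rnorm(m), 1),
               p_value = runif(m), fdr = round(runif(m), 2),
               call = sample(c("up", "down", "ns"), m, TRUE),
               stringsAsFactors = FALSE),
    class = c("differential_result", "data.frame"))
  top <- top_table(rde, n = 10)
  sig <- rde[rde$call != "ns", ]
  oracle <- sig[order(-abs(sig$log2_ratio), sig$fdr, sig$gene_id), ][1:10, ]
  expect_equal(top$gene_id, oracle$gene_id)
})
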