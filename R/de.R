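#' Call differentially expressed genes between two libraries
#'
#' Per gene: the Audic-Claverie two-sided p-value on raw unambiguous counts,
#' Benjamini-Hochberg step-up FDR over all tested genes (genes at zero in
#' both libraries are excluded from testing), and the log2 TPM ratio
#' (library 2 over library 1) with 0 TPM replaced by 0.001 so genes expressed
#' in only one sample remain computable. A gene is called `up` when
#' `fdr <= fdr_threshold` and `log2Ratio >= min_abs_log2ratio`, `down` for the
#' mirrored condition, otherwise `ns`. The substitution rule affects the
#' log2Ratio only, never the p-value.
#'
#' @param profile_1,profile_2 [to_tpm()] expression profiles over the same
#'   gene universe (library 1 is the control/reference of the ratio).
#' @param fdr_threshold FDR significance cutoff.
#' @param min_abs_log2ratio minimum absolute log2 fold change.
#' @param zero_tpm TPM substituted for 0 in the ratio.
#' @return object of class `differential_result`: data frame with columns
#'   `gene_id`, `x`, `y`, `tpm1`, `tpm2`, `log2_ratio`, `p_value`, `fdr`,
#'   `call`; attributes `n_up`, `n_down`, `n_tested`.
#' @export
call_degs <- function(profile_1, profile_2, fdr_threshold = 0.001,
                      min_abs_log2ratio = 1, zero_tpm = 0.001) {
  stopifnot(inherits(profile_1, "expression_profile"),
            inherits(profile_2, "expression_profile"))
  if (!identical(sort(profile_1$gene_id), sort(profile_2$gene_id)))
    stop_input("profiles cover different gene universes")
  p2 <- profile_2[match(profile_1$gene_id, profile_2$gene_id), ]
  x <- profile_1$count
  y <- p2$count
  N1 <- attr(profile_1, "total_clean")
  N2 <- attr(profile_2, "total_clean")
  if (all(x + y == 0))
    stop_input("no gene with a nonzero count in either library")
  tpm1 <- profile_1$tpm
  tpm2 <- p2$tpm
  l2r <- log2(ifelse(tpm2 == 0, zero_tpm, tpm2) /
              ifelse(tpm1 == 0, zero_tpm, tpm1))

  tested <- x + y > 0
  pv <- rep(NA_real_, length(x))
  pv[tested] <- ac_pvalue(x[tested], y[tested], N1, N2)
  fdr <- rep(NA_real_, length(x))
  fdr[tested] <- p.adjust(pv[tested], method = "BH")

  call <- rep("ns", length(x))
  call[tested & fdr <= fdr_threshold & l2r >= min_abs_log2ratio] <- "up"
  call[tested & fdr <= fdr_threshold & l2r <= -min_abs_log2ratio] <- "down"

  out <- data.frame(gene_id = profile_1$gene_id, x = x, y = y,
                    tpm1 = tpm1, tpm2 = tpm2, log2_ratio = l2r,
                    p_value = pv, fdr = fdr, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "n_up") <- sum(call == "up")
  attr(out, "n_down") <- sum(call == "down")
  attr(out, "n_tested") <- sum(tested)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Top differentially expressed genes
#'
#' The `n` strongest significant calls in the requested direction, ranked by
#' absolute log2 ratio (descending), ties broken by smaller FDR then gene id.
#' Genes expressed in only one sample are flagged.
#'
#' @param results a [call_degs()] result.
#' @param n maximum number of genes to return (> 0).
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return data frame of ranked rows with an added logical column
#'   `single_sample`.
#' @export
top_table <- function(results, n = 20L, direction = c("both", "up", "down")) {
  stopifnot(inherits(results, "differential_result"))
  direction <- match.arg(direction)
  if (n <= 0) stop_input("n must be positive")
  keep <- results$call != "ns"
  if (direction != "both") keep <- keep & results$call == direction
  sig <- results[keep, , drop = FALSE]
  ord <- order(-abs(sig$log2_ratio), sig$fdr, sig$gene_id)
  sig <- sig[head(ord, n), , drop = FALSE]
  sig$single_sample <- sig$x == 0 | sig$y == 0
  rownames(sig) <- NULL
  sig
}
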