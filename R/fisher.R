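# Inter-tissue comparison of responder proportions.

#' Fisher's exact test on two responder proportions
#'
#' Two-sided Fisher's exact test for the 2x2 table
#' `[[count_a, total_a - count_a], [count_b, total_b - count_b]]`: the
#' p-value sums the probabilities of all tables (with the observed margins)
#' at most as probable as the observed one.
#'
#' @param count_a,total_a responders and total genes in tissue A.
#' @param count_b,total_b responders and total genes in tissue B.
#' @return the two-sided p-value.
#' @export
#' @examples
#' fisher_tissue_comparison(91, 13528, 2279, 9905)   # << 1e-4
fisher_tissue_comparison <- function(count_a, total_a, count_b, total_b) {
  v <- c(count_a, total_a, count_b, total_b)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    tsr_stop("counts and totals must be non-negative integers", "invalid_table")
  if (count_a > total_a || count_b > total_b)
    tsr_stop("count exceeds total", "invalid_table")
  tab <- matrix(c(count_a, total_a - count_a,
                  count_b, total_b - count_b),
                nrow = 2L, byrow = TRUE)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Compare every tissue's responder proportion against a reference tissue
#'
#' Runs [fisher_tissue_comparison] of each non-reference tissue against the
#' reference, separately for up- and downregulated counts.
#'
#' @param counts data.frame with columns `tissue`, `up`, `down`, `total`
#'   (responder counts per tissue and the tissue's analysed-gene total).
#' @param reference reference tissue name (default `"intestine"`).
#' @param alpha significance threshold for the flag column (default 1e-4).
#' @return data.frame: tissue, direction, count, total, ref_count, ref_total,
#'   p, significant.
#' @export
compare_tissue_proportions <- function(counts, reference = "intestine",
                                       alpha = 1e-4) {
  need <- c("tissue", "up", "down", "total")
  if (!all(need %in% names(counts)))
    tsr_stop(paste("counts needs columns:", paste(need, collapse = ", ")),
             "invalid_table")
  if (!reference %in% counts$tissue)
    tsr_stop(sprintf("reference tissue '%s' not in counts", reference),
             "unknown_tissue")
  ref <- counts[counts$tissue == reference, ]
  oth <- counts[counts$tissue != reference, ]
  res <- do.call(rbind, lapply(c("up", "down"), function(dir) {
    data.frame(
      tissue = oth$tissue,
      direction = dir,
      count = oth[[dir]],
      total = oth$total,
      ref_count = ref[[dir]],
      ref_total = ref$total,
      p = mapply(fisher_tissue_comparison,
                 oth[[dir]], oth$total, ref[[dir]], ref$total),
      stringsAsFactors = FALSE)
  }))
  res$significant <- res$p < alpha
  res[order(match(res$direction, c("up", "down")), res$tissue), ]
}
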