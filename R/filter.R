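# Expression filtering ahead of SR scoring.
#
# SR is a log ratio of RPKM values, so both the spaceflight and the ground
# control sample of a tissue must show real expression before the ratio is
# meaningful. A gene passes in a tissue when RPKM >= min_rpkm AND reads >=
# min_reads in BOTH conditions; thresholds are inclusive.

#' Filtering thresholds
#'
#' @param min_rpkm minimum RPKM required in both SF and GC (default 1.0).
#' @param min_reads minimum read count required in both SF and GC (default 5).
#' @param scope `"all-tissues"`: a gene must pass in every tissue (the
#'   construction behind the cross-tissue analysis set); `"per-tissue"`:
#'   one passing set per tissue.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_rpkm = 1.0, min_reads = 5L,
                          scope = c("all-tissues", "per-tissue")) {
  scope <- match.arg(scope)
  if (!is.numeric(min_rpkm) || length(min_rpkm) != 1L || min_rpkm < 0)
    tsr_stop("min_rpkm must be a single number >= 0", "invalid_config")
  if (!is_count(min_reads))
    tsr_stop("min_reads must be a single integer >= 0", "invalid_config")
  structure(list(min_rpkm = min_rpkm, min_reads = as.integer(min_reads),
                 scope = scope),
            class = "filter_config")
}

#' Filter genes by minimum expression
#'
#' @param expr an [expression_table][quantify_samples].
#' @param cfg a [filter_config]; thresholds are inclusive (`>=`).
#' @param tissues tissues in scope; defaults to every tissue in `expr`.
#' @return `scope = "all-tissues"`: character vector of genes passing in all
#'   tissues. `scope = "per-tissue"`: named list of per-tissue gene vectors.
#' @export
filter_genes <- function(expr, cfg = filter_config(), tissues = NULL) {
  stopifnot(inherits(expr, "expression_table"), inherits(cfg, "filter_config"))
  if (is.null(tissues)) tissues <- unique(expr$samples$tissue)
  pass <- vapply(tissues, function(t) {
    sf <- sample_col(expr, t, "SF")
    gc <- sample_col(expr, t, "GC")
    expr$rpkm[, sf] >= cfg$min_rpkm & expr$rpkm[, gc] >= cfg$min_rpkm &
      expr$counts[, sf] >= cfg$min_reads & expr$counts[, gc] >= cfg$min_reads
  }, logical(length(expr$genes)))
  if (length(expr$genes) == 1L) pass <- matrix(pass, nrow = 1L,
                                               dimnames = list(expr$genes, tissues))
  if (cfg$scope == "all-tissues") {
    expr$genes[rowSums(pass) == length(tissues)]
  } else {
    stats::setNames(lapply(tissues, function(t) expr$genes[pass[, t]]), tissues)
  }
}
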