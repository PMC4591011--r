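# Space responsiveness (SR) and its cross-tissue composite norm ||TSR||.
#
# SR is the per-tissue log2 ratio of spaceflight over ground-control RPKM.
# ||TSR|| ranks genes by overall responsiveness across all tissues at once:
# the Euclidean norm of the six-tissue SR vector (published tables print it
# as ||Z||).

#' Space responsiveness: log2 SF/GC RPKM ratio
#'
#' @param rpkm_sf,rpkm_gc positive RPKM values (positivity is guaranteed by
#'   upstream filtering; zeros are rejected here rather than propagated as
#'   infinities). Vectorised.
#' @return `log2(rpkm_sf / rpkm_gc)`; antisymmetric under argument swap.
#' @export
#' @examples
#' space_responsiveness(2.61, 7.42)   # -1.509...
space_responsiveness <- function(rpkm_sf, rpkm_gc) {
  if (any(!is.finite(rpkm_sf)) || any(!is.finite(rpkm_gc)) ||
      any(rpkm_sf <= 0) || any(rpkm_gc <= 0))
    tsr_stop("SR needs strictly positive RPKM in both conditions; filter genes first",
             "nonpositive_rpkm")
  log2(rpkm_sf / rpkm_gc)
}

#' Total space responsiveness: Euclidean norm of an SR vector
#'
#' @param sr numeric vector of per-tissue SR values (no missing values), or a
#'   matrix with one gene per row.
#' @return `sqrt(sum(sr^2))` per gene.
#' @export
#' @examples
#' total_space_responsiveness(c(2.69, 2.72, 0.59, 0.40, 4.48, 4.34))  # 7.35...
total_space_responsiveness <- function(sr) {
  if (anyNA(sr))
    tsr_stop("SR vector has missing values; ||TSR|| requires all tissues",
             "missing_sr")
  if (is.matrix(sr)) sqrt(rowSums(sr^2)) else sqrt(sum(sr^2))
}

#' SR table: per-gene SR across tissues plus ||TSR||
#'
#' @param sr numeric matrix of SR values, genes in rows (rownames = gene_ids),
#'   tissues in columns (colnames = tissue names).
#' @return object of class `sr_table`: list with `genes`, `tissues`, `sr`
#'   matrix, and `tsr` (named vector of Euclidean norms).
#' @export
sr_table <- function(sr) {
  if (!is.matrix(sr) || is.null(rownames(sr)) || is.null(colnames(sr)))
    tsr_stop("sr must be a matrix with gene rownames and tissue colnames",
             "invalid_sr_table")
  structure(
    list(genes = rownames(sr), tissues = colnames(sr), sr = sr,
         tsr = stats::setNames(total_space_responsiveness(sr), rownames(sr))),
    class = "sr_table")
}

#' Compute the SR table from an expression table
#'
#' @param expr an [expression_table][quantify_samples].
#' @param genes genes to score (typically the filtered set — every gene must
#'   have positive RPKM in both conditions of every tissue).
#' @param tissues tissue order for the SR columns; defaults to order of
#'   appearance in `expr`.
#' @return an [sr_table].
#' @export
compute_sr_table <- function(expr, genes = NULL, tissues = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  if (is.null(tissues)) tissues <- unique(expr$samples$tissue)
  if (is.null(genes)) genes <- expr$genes
  sr <- vapply(tissues, function(t) {
    space_responsiveness(expr$rpkm[genes, sample_col(expr, t, "SF")],
                         expr$rpkm[genes, sample_col(expr, t, "GC")])
  }, numeric(length(genes)))
  if (length(genes) == 1L) sr <- matrix(sr, nrow = 1L)
  dimnames(sr) <- list(genes, tissues)
  sr_table(sr)
}

#' @export
print.sr_table <- function(x, ...) {
  cat(sprintf("sr_table: %d genes x %d tissues (%s)\n",
              length(x$genes), length(x$tissues),
              paste(x$tissues, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.sr_table <- function(x, ...) {
  data.frame(gene_id = x$genes, x$sr, tsr = unname(x$tsr),
             row.names = NULL, check.names = FALSE)
}

#' Twofold responder call for a single SR value
#'
#' A twofold change on the RPKM ratio scale is |SR| >= 1 on the log2 scale;
#' the threshold is inclusive (SR = 1 means exactly twofold up).
#'
#' @param sr SR value(s).
#' @return character vector: `"up"` (SR >= 1), `"down"` (SR <= -1), `"none"`.
#' @export
classify_twofold <- function(sr) {
  ifelse(sr >= 1, "up", ifelse(sr <= -1, "down", "none"))
}

#' Genes responding in many tissues at once
#'
#' Calls genes whose |SR| meets `sr_threshold` in at least `min_tissues`
#' tissues. Direction is `"up"` if every qualifying tissue is positive,
#' `"down"` if every one is negative, else `"mixed"`.
#'
#' @param srt an [sr_table].
#' @param sr_threshold inclusive |SR| threshold (default 1, i.e. twofold).
#' @param min_tissues minimum number of qualifying tissues (default 4).
#' @return data.frame: gene_id, class, tissues (comma-joined qualifying
#'   tissues), n_tissues, direction. Zero rows when nothing qualifies.
#' @export
multi_tissue_responders <- function(srt, sr_threshold = 1.0, min_tissues = 4L) {
  stopifnot(inherits(srt, "sr_table"))
  hit <- abs(srt$sr) >= sr_threshold
  n_hit <- rowSums(hit)
  keep <- which(n_hit >= min_tissues)
  if (!length(keep))
    return(data.frame(gene_id = character(), class = character(),
                      tissues = character(), n_tissues = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  direction <- vapply(keep, function(i) {
    s <- srt$sr[i, hit[i, ]]
    if (all(s > 0)) "up" else if (all(s < 0)) "down" else "mixed"
  }, "")
  data.frame(
    gene_id = srt$genes[keep],
    class = "multi-tissue",
    tissues = vapply(keep, function(i)
      paste(srt$tissues[hit[i, ]], collapse = ","), ""),
    n_tissues = n_hit[keep],
    direction = direction,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Genes responding in (essentially) one tissue only
#'
#' A "tissue-specific" responder is defined by a dominant-tissue rule: the
#' focal tissue's |SR| must reach `min_focal_sr`, be the largest |SR| of the
#' gene, and exceed the second-largest |SR| by at least `dominance_ratio`.
#'
#' @param srt an [sr_table].
#' @param focal_tissue tissue name (must be a column of `srt`).
#' @param min_focal_sr minimum |SR| in the focal tissue (default 2, fourfold).
#' @param dominance_ratio required ratio of focal |SR| over the
#'   second-largest |SR| (default 2).
#' @return data.frame: gene_id, class, tissues (the focal tissue), direction
#'   (sign of the focal SR), sr_focal, sr_second (second-largest |SR|).
#' @export
tissue_specific_responders <- function(srt, focal_tissue,
                                       min_focal_sr = 2.0,
                                       dominance_ratio = 2.0) {
  stopifnot(inherits(srt, "sr_table"))
  if (!focal_tissue %in% srt$tissues)
    tsr_stop(sprintf("unknown focal tissue '%s'", focal_tissue),
             "unknown_tissue")
  a <- abs(srt$sr)
  focal <- a[, focal_tissue]
  others <- a[, setdiff(srt$tissues, focal_tissue), drop = FALSE]
  second <- apply(others, 1L, max)
  keep <- which(focal >= min_focal_sr & focal > second &
                  focal >= dominance_ratio * second)
  if (!length(keep))
    return(data.frame(gene_id = character(), class = character(),
                      tissues = character(), direction = character(),
                      sr_focal = numeric(), sr_second = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(
    gene_id = srt$genes[keep],
    class = "tissue-specific",
    tissues = if (length(keep)) focal_tissue else character(),
    direction = ifelse(srt$sr[keep, focal_tissue] > 0, "up", "down"),
    sr_focal = unname(srt$sr[keep, focal_tissue]),
    sr_second = unname(second[keep]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Top genes by composite responsiveness
#'
#' @param srt an [sr_table].
#' @param n how many genes (default 400). Must not exceed the table size.
#' @return character vector of gene_ids sorted by ||TSR|| descending; ties
#'   broken lexicographically by gene_id for reproducibility.
#' @export
rank_top_n <- function(srt, n = 400L) {
  stopifnot(inherits(srt, "sr_table"))
  if (n > length(srt$genes))
    tsr_stop(sprintf("n = %d exceeds the %d genes available", n, length(srt$genes)),
             "invalid_config")
  ord <- order(-srt$tsr, srt$genes, method = "radix")
  srt$genes[ord][seq_len(n)]
}
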