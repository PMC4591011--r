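# RPKM quantification from per-gene read counts.

#' Reads per kilobase of exon per million mapped reads
#'
#' `RPKM = count / ((length_bp/1000) * (total_mapped_reads/1e6))`. The
#' denominator uses the library-wide total of mapped reads, which is a
#' supplied per-sample quantity: it is never recomputed by summing gene
#' counts, because multi-mapping and intergenic reads make that sum wrong.
#'
#' Vectorised over `count` and `length_bp` (recycled against each other).
#'
#' @param count non-negative read count(s).
#' @param length_bp positive integrated exonic length(s) in bp.
#' @param total_mapped_reads positive scalar, total mapped reads of the sample.
#' @return RPKM value(s); zero count gives zero RPKM.
#' @export
#' @examples
#' compute_rpkm(1000, 1000, 1e6)   # 1000
compute_rpkm <- function(count, length_bp, total_mapped_reads) {
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    tsr_stop("length_bp must be > 0", "invalid_denominator")
  if (any(!is.finite(total_mapped_reads)) || any(total_mapped_reads <= 0))
    tsr_stop("total_mapped_reads must be > 0", "invalid_denominator")
  if (any(count < 0))
    tsr_stop("counts must be non-negative", "invalid_count")
  count / ((length_bp / 1000) * (total_mapped_reads / 1e6))
}

#' Per-sample read counts
#'
#' Container for one library's per-gene counts and its total mapped reads.
#'
#' @param tissue,condition sample identity; `condition` is `"SF"`
#'   (spaceflight) or `"GC"` (ground control).
#' @param gene_counts named non-negative integer vector, gene_id -> reads.
#' @param total_mapped_reads positive scalar; must be at least the largest
#'   single gene count.
#' @return object of class `sample_counts`.
#' @export
sample_counts <- function(tissue, condition, gene_counts, total_mapped_reads) {
  condition <- match.arg(condition, c("SF", "GC"))
  if (length(gene_counts) && is.null(names(gene_counts)))
    tsr_stop("gene_counts must be named by gene_id", "invalid_count")
  if (any(gene_counts < 0) || any(gene_counts != round(gene_counts)))
    tsr_stop("gene_counts must be non-negative integers", "invalid_count")
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0)
    tsr_stop("total_mapped_reads must be positive", "invalid_denominator")
  if (length(gene_counts) && total_mapped_reads < max(gene_counts))
    tsr_stop("total_mapped_reads is smaller than a single gene's count",
             "invalid_denominator")
  structure(
    list(sample_id = paste(tissue, condition, sep = "_"),
         tissue = tissue, condition = condition,
         gene_counts = gene_counts,
         total_mapped_reads = total_mapped_reads),
    class = "sample_counts")
}

#' Quantify a set of samples against gene models
#'
#' Builds the (gene x sample) count and RPKM matrices. Genes present in the
#' models but absent from a sample's counts get count 0 and RPKM 0; a counted
#' gene with no model is an error (it has no length to normalise by).
#'
#' @param models named list of [gene_model][flatten_gene_model] objects (names
#'   are gene_ids), or a named numeric vector of exonic lengths in bp.
#' @param samples list of [sample_counts] objects.
#' @return object of class `expression_table`: list with `genes`, `samples`
#'   (data.frame: sample_id, tissue, condition, total_mapped_reads),
#'   `counts` and `rpkm` matrices (genes x samples), `gene_lengths`.
#' @export
quantify_samples <- function(models, samples) {
  if (inherits(samples, "sample_counts")) samples <- list(samples)
  lengths_bp <- if (is.numeric(models)) models
                else vapply(models, function(m) as.numeric(m$length_bp), 0)
  if (is.null(names(lengths_bp)))
    tsr_stop("models must be named by gene_id", "unknown_gene")
  genes <- names(lengths_bp)
  unknown <- unique(unlist(lapply(samples, function(s)
    setdiff(names(s$gene_counts), genes))))
  if (length(unknown))
    tsr_stop(paste0("counts contain gene(s) with no gene model: ",
                    paste(utils::head(unknown, 10), collapse = ", "),
                    if (length(unknown) > 10) sprintf(" (+%d more)", length(unknown) - 10)),
             "unknown_gene")
  ids <- vapply(samples, function(s) s$sample_id, "")
  if (anyDuplicated(ids))
    tsr_stop("duplicate sample_id in samples", "duplicate_record")
  counts <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, ids))
  for (j in seq_along(samples)) {
    gc <- samples[[j]]$gene_counts
    if (length(gc)) counts[names(gc), j] <- as.numeric(gc)
  }
  totals <- vapply(samples, function(s) s$total_mapped_reads, 0)
  rpkm <- sweep(counts / (lengths_bp / 1000), 2, totals / 1e6, "/")
  structure(
    list(genes = genes,
         samples = data.frame(
           sample_id = ids,
           tissue = vapply(samples, function(s) s$tissue, ""),
           condition = vapply(samples, function(s) s$condition, ""),
           total_mapped_reads = totals,
           stringsAsFactors = FALSE),
         counts = counts, rpkm = rpkm, gene_lengths = lengths_bp),
    class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              length(x$genes), nrow(x$samples),
              paste(x$samples$sample_id, collapse = ", ")))
  invisible(x)
}

# Column index helper: sample column for (tissue, condition); errors if absent.
sample_col <- function(expr, tissue, condition) {
  i <- which(expr$samples$tissue == tissue & expr$samples$condition == condition)
  if (length(i) != 1L)
    tsr_stop(sprintf("expected exactly one %s sample for tissue '%s' (found %d)",
                     condition, tissue, length(i)),
             "incomplete_design")
  i
}
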