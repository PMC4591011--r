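# Gene models: per-gene integrated exon sets.
#
# A gene is quantified over the union of the exons of all its transcripts
# (the "integrated exons"). Where two transcripts disagree on an exon
# boundary the longer extent wins, which is exactly what an interval union
# produces; overlapping exons merge. Coordinates are 1-based with inclusive
# ends throughout (the GTF convention).

#' Flatten transcript exons into an integrated gene model
#'
#' Computes the interval union of all exons of all transcripts of one gene.
#' The union subsumes the "pick the longer exon" rule for exons that share a
#' boundary, and is the only interpretation that keeps the exonic length
#' well-defined for arbitrary overlap patterns.
#'
#' @param transcripts named list, one element per transcript. Each element is
#'   a data.frame (or 2-column matrix) with columns `start` and `end`,
#'   1-based inclusive. An optional `chrom` column is checked for
#'   consistency across transcripts.
#' @param gene_id gene identifier carried on the result.
#' @param chrom,strand chromosome and strand; strand is carried but never
#'   used by quantification (counts arrive pre-assigned to genes).
#' @return an object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `transcripts`, `integrated_exons` (data.frame `start`,`end`,
#'   disjoint, sorted by start) and `length_bp`.
#' @export
#' @examples
#' m <- flatten_gene_model(
#'   list(tx1 = data.frame(start = c(100, 300), end = c(199, 399)),
#'        tx2 = data.frame(start = 100, end = 249)),
#'   gene_id = "g1")
#' m$integrated_exons
#' m$length_bp
flatten_gene_model <- function(transcripts, gene_id = NA_character_,
                               chrom = NA_character_, strand = NA_character_) {
  if (!is.list(transcripts) || length(transcripts) == 0L)
    tsr_stop("'transcripts' must be a non-empty list of exon tables",
             "inconsistent_model")
  exons <- lapply(transcripts, function(tx) {
    tx <- as.data.frame(tx)
    if (is.null(tx$start) && ncol(tx) >= 2L) names(tx)[1:2] <- c("start", "end")
    if (!all(c("start", "end") %in% names(tx)))
      tsr_stop("each transcript needs 'start' and 'end' columns",
               "malformed_interval")
    tx
  })
  chroms <- unique(unlist(lapply(exons, function(tx) unique(tx$chrom))))
  chroms <- chroms[!is.na(chroms)]
  if (!is.na(chrom)) chroms <- unique(c(chrom, chroms))
  if (length(chroms) > 1L)
    tsr_stop(sprintf("gene '%s': transcripts span multiple chromosomes (%s)",
                     gene_id, paste(chroms, collapse = ", ")),
             "inconsistent_model")
  if (length(chroms) == 1L) chrom <- chroms
  all_ex <- do.call(rbind, lapply(exons, function(tx) tx[c("start", "end")]))
  bad <- all_ex$start > all_ex$end | all_ex$start < 1
  if (any(bad))
    tsr_stop(sprintf("gene '%s': %d malformed exon interval(s) (start > end or start < 1)",
                     gene_id, sum(bad)),
             "malformed_interval")
  ir <- IRanges::reduce(IRanges::IRanges(start = all_ex$start, end = all_ex$end))
  integrated <- data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         transcripts = exons,
         integrated_exons = integrated,
         length_bp = sum(integrated$end - integrated$start + 1L)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' (%s%s): %d transcript(s), %d integrated exon(s), %d bp\n",
              x$gene_id,
              ifelse(is.na(x$chrom), "?", x$chrom),
              ifelse(is.na(x$strand), "", paste0(":", x$strand)),
              length(x$transcripts), nrow(x$integrated_exons), x$length_bp))
  invisible(x)
}
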