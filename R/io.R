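# File dialects: counts/totals TSV, GTF gene models, SR and result tables.
#
# Counts TSV: header `gene_id` then one column per sample named
# <tissue>_<SF|GC>. Totals TSV: sample_id, total_mapped_reads. Minus signs
# are always written as ASCII hyphen-minus; readers also accept Unicode
# minus/en-dash (published tables frequently typeset those).

#' Read a counts table
#'
#' @param path TSV with a `gene_id` column and `<tissue>_<SF|GC>` sample
#'   columns.
#' @param totals named numeric vector (or path to a totals TSV) giving
#'   total_mapped_reads per sample_id.
#' @param tissues if given, sample columns are validated against this set.
#' @return list of [sample_counts], one per sample column.
#' @export
read_counts_table <- function(path, totals, tissues = NULL) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!"gene_id" %in% names(d))
    tsr_stop(sprintf("%s: no 'gene_id' column", path), "parse_error")
  if (nrow(d) == 0L)
    warning(sprintf("%s: header only, empty counts table", path), call. = FALSE)
  dup <- d$gene_id[duplicated(d$gene_id)]
  if (length(dup))
    tsr_stop(sprintf("%s: duplicate gene_id '%s'", path, dup[1]),
             "duplicate_record")
  sample_cols <- setdiff(names(d), "gene_id")
  m <- regmatches(sample_cols, regexec("^(.*)_(SF|GC)$", sample_cols))
  bad <- sample_cols[vapply(m, length, 0L) != 3L]
  if (length(bad))
    tsr_stop(sprintf("%s: sample column '%s' is not <tissue>_<SF|GC>",
                     path, bad[1]), "parse_error")
  col_tissue <- vapply(m, `[[`, "", 2L)
  if (!is.null(tissues) && length(setdiff(col_tissue, tissues)))
    tsr_stop(sprintf("%s: unknown tissue(s): %s", path,
                     paste(setdiff(col_tissue, tissues), collapse = ", ")),
             "unknown_tissue")
  if (is.character(totals)) totals <- read_totals_table(totals)
  lapply(seq_along(sample_cols), function(j) {
    cn <- sample_cols[j]
    v <- d[[cn]]
    nonint <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(nonint))
      tsr_stop(sprintf("%s: non-integer count at row %d, column '%s'",
                       path, nonint[1], cn), "parse_error")
    if (!cn %in% names(totals))
      tsr_stop(sprintf("no total_mapped_reads supplied for sample '%s'", cn),
               "incomplete_design")
    sample_counts(col_tissue[j], vapply(m, `[[`, "", 3L)[j],
                  stats::setNames(as.integer(v), d$gene_id), totals[[cn]])
  })
}

#' Read a totals table (sample_id, total_mapped_reads)
#' @param path TSV path.
#' @return named numeric vector.
#' @export
read_totals_table <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "total_mapped_reads") %in% names(d)))
    tsr_stop(sprintf("%s: need columns sample_id, total_mapped_reads", path),
             "parse_error")
  stats::setNames(as.numeric(d$total_mapped_reads), d$sample_id)
}

#' Write counts (and totals) of an expression table or synthetic study
#'
#' @param expr an [expression_table][quantify_samples].
#' @param counts_path,totals_path output TSV paths.
#' @return invisibly the two paths.
#' @export
write_counts_table <- function(expr, counts_path, totals_path) {
  d <- data.frame(gene_id = expr$genes, expr$counts, check.names = FALSE)
  data.table::fwrite(d, counts_path, sep = "\t")
  data.table::fwrite(data.frame(sample_id = expr$samples$sample_id,
                                total_mapped_reads = expr$samples$total_mapped_reads),
                     totals_path, sep = "\t")
  invisible(c(counts_path, totals_path))
}

#' Write an RPKM table
#' @param expr an [expression_table][quantify_samples].
#' @param path output TSV path.
#' @export
write_rpkm_table <- function(expr, path) {
  data.table::fwrite(data.frame(gene_id = expr$genes, expr$rpkm,
                                check.names = FALSE),
                     path, sep = "\t")
  invisible(path)
}

#' Write / read an SR table
#'
#' @param srt an [sr_table]; `path` a TSV path. Values are written at full
#'   precision; two-decimal rounding is for report display only.
#' @export
write_sr_table <- function(srt, path) {
  data.table::fwrite(as.data.frame(srt), path, sep = "\t")
  invisible(path)
}

#' @rdname write_sr_table
#' @export
read_sr_table <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (names(d)[1] != "gene_id" || names(d)[ncol(d)] != "tsr")
    tsr_stop(sprintf("%s: not an SR table (gene_id ... tsr)", path),
             "parse_error")
  tiss <- names(d)[-c(1, ncol(d))]
  # tolerate typographic minus variants in hand-made tables
  sr <- as.matrix(as.data.frame(lapply(d[tiss], function(col) {
    if (is.character(col)) as.numeric(gsub("[−–]", "-", col)) else col
  })))
  dimnames(sr) <- list(d$gene_id, tiss)
  sr_table(sr)
}

#' Read gene models from a GTF file
#'
#' Uses rtracklayer for parsing (exon features only; `gene_id` and
#' `transcript_id` attributes required), then flattens each gene with
#' [flatten_gene_model].
#'
#' @param path GTF file path.
#' @return named list of `gene_model` objects.
#' @export
read_gtf_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    tsr_stop("reading GTF requires the rtracklayer package", "parse_error")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gr$gene_id, transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  by_gene <- split(df, df$gene_id)
  models <- lapply(by_gene, function(g) {
    txs <- lapply(split(g[c("start", "end", "chrom")], g$transcript_id),
                  function(tx) tx)
    flatten_gene_model(txs, gene_id = g$gene_id[1], strand = g$strand[1])
  })
  models[order(names(models))]
}

#' Write gene models as GTF
#'
#' @param models named list of `gene_model` objects.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(m) {
    unlist(lapply(names(m$transcripts), function(tx) {
      e <- m$transcripts[[tx]]
      sprintf('%s\ttsrpipe\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
              m$chrom, e$start, e$end,
              ifelse(is.na(m$strand), ".", m$strand), m$gene_id, tx)
    }))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic study to disk in the dialects the pipeline reads
#'
#' Emits `genes.gtf`, `counts.tsv`, `totals.tsv`, `orthologs.tsv`,
#' `gene2ensembl.tsv`, `gene2go.tsv` and `truth.tsv` under `dir`.
#' Deterministic: the same study writes byte-identical files.
#'
#' @param study a [simulate_study] result.
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gtf(study$models, p("genes.gtf"))
  expr <- quantify_samples(study$models, study$samples)
  write_counts_table(expr, p("counts.tsv"), p("totals.tsv"))
  data.table::fwrite(study$maps$ortholog, p("orthologs.tsv"), sep = "\t")
  data.table::fwrite(study$maps$gene2ensembl, p("gene2ensembl.tsv"), sep = "\t")
  data.table::fwrite(study$maps$gene2go, p("gene2go.tsv"), sep = "\t")
  data.table::fwrite(study$truth, p("truth.tsv"), sep = "\t")
  invisible(stats::setNames(
    p(c("genes.gtf", "counts.tsv", "totals.tsv", "orthologs.tsv",
        "gene2ensembl.tsv", "gene2go.tsv", "truth.tsv")),
    c("gtf", "counts", "totals", "ortholog", "gene2ensembl", "gene2go",
      "truth")))
}
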