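# Gene -> GO annotation via the ortholog join chain.
#
# Model-organism gene IDs rarely carry GO annotation directly; the pipeline
# borrows human annotation through a three-step join:
#   species gene ID -> human Ensembl gene ID   (BioMart-style ortholog table)
#   human Ensembl ID -> Entrez gene ID         (NCBI gene2ensembl)
#   Entrez gene ID  -> GO IDs (+ term labels)  (NCBI gene2go)
# All links are many-to-many; a gene's resolved GO set is the union over
# every path, and a gene failing any link resolves to the empty set. No
# GO-graph propagation is performed: records are joined flat.

GO_ID_RE <- "^GO:[0-9]{7}$"

#' Read a two-column ortholog map (species gene -> human Ensembl gene)
#'
#' @param path TSV with columns `species_gene_id`, `human_gene_id` (any
#'   header names; first two columns are used).
#' @return data.frame with the two columns named canonically.
#' @export
read_ortholog_map <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character", data.table = FALSE)
  if (ncol(d) < 2L)
    tsr_stop(sprintf("%s: expected >= 2 columns", path), "parse_error")
  stats::setNames(d[, 1:2], c("species_gene_id", "human_gene_id"))
}

#' Read a gene2ensembl-style table (tax_id, entrez_id, ensembl_gene_id)
#'
#' @param path TSV with at least three columns in NCBI gene2ensembl order.
#' @return data.frame with columns `entrez_id` (integer), `ensembl_gene_id`.
#' @export
read_gene2ensembl <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character", data.table = FALSE)
  if (ncol(d) < 3L)
    tsr_stop(sprintf("%s: expected >= 3 columns (tax_id, entrez_id, ensembl_gene_id)", path),
             "parse_error")
  data.frame(entrez_id = as.integer(d[[2]]), ensembl_gene_id = d[[3]],
             stringsAsFactors = FALSE)
}

#' Read a gene2go-style table
#'
#' @param path TSV in NCBI gene2go column order: tax_id, entrez_id, go_id,
#'   evidence, qualifier, term_label (extra columns ignored).
#' @return data.frame with columns `entrez_id`, `go_id`, `term_label`.
#' @export
read_gene2go <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character", data.table = FALSE)
  if (ncol(d) < 3L)
    tsr_stop(sprintf("%s: expected >= 3 columns (tax_id, entrez_id, go_id, ...)", path),
             "parse_error")
  bad <- which(!grepl(GO_ID_RE, d[[3]]))
  if (length(bad))
    tsr_stop(sprintf("%s: malformed GO ID '%s' at data line %d (want GO: + 7 digits)",
                     path, d[[3]][bad[1]], bad[1]),
             "parse_error")
  data.frame(entrez_id = as.integer(d[[2]]), go_id = d[[3]],
             term_label = if (ncol(d) >= 6L) d[[6]] else NA_character_,
             stringsAsFactors = FALSE)
}

#' Build the gene -> GO annotation map
#'
#' Composes the three mapping tables. Accepts file paths or pre-read
#' data.frames with the canonical columns of the `read_*` functions.
#'
#' @param ortholog species -> human ortholog table (path or data.frame).
#' @param gene2ensembl human Ensembl -> Entrez table (path or data.frame).
#' @param gene2go Entrez -> GO table (path or data.frame).
#' @param genes optional character vector: the gene universe to resolve.
#'   Defaults to all genes present in the ortholog table. Genes outside the
#'   ortholog table resolve to empty GO sets.
#' @return object of class `annotation_map`: list with the three source
#'   tables, `resolved` (named list gene_id -> sorted unique GO IDs),
#'   and `terms` (named vector go_id -> term label).
#' @export
build_annotation_map <- function(ortholog, gene2ensembl, gene2go, genes = NULL) {
  if (is.character(ortholog)) ortholog <- read_ortholog_map(ortholog)
  if (is.character(gene2ensembl)) gene2ensembl <- read_gene2ensembl(gene2ensembl)
  if (is.character(gene2go)) gene2go <- read_gene2go(gene2go)
  bad <- which(!grepl(GO_ID_RE, gene2go$go_id))
  if (length(bad))
    tsr_stop(sprintf("malformed GO ID '%s' at gene2go row %d",
                     gene2go$go_id[bad[1]], bad[1]),
             "parse_error")
  if (nrow(ortholog) == 0L || nrow(gene2ensembl) == 0L || nrow(gene2go) == 0L)
    warning("empty mapping table: all genes will resolve to empty GO sets",
            call. = FALSE)
  if (is.null(genes)) genes <- sort(unique(ortholog$species_gene_id))
  # species gene -> human -> entrez -> GO, duplicates collapsed at the end
  j1 <- merge(ortholog, gene2ensembl,
              by.x = "human_gene_id", by.y = "ensembl_gene_id")
  j2 <- merge(j1, gene2go, by = "entrez_id")
  resolved <- lapply(stats::setNames(genes, genes), function(g) character(0))
  if (nrow(j2)) {
    sp <- split(j2$go_id, j2$species_gene_id)
    sp <- lapply(sp, function(x) sort(unique(x)))
    keep <- intersect(names(sp), genes)
    resolved[keep] <- sp[keep]
  }
  terms <- gene2go$term_label
  names(terms) <- gene2go$go_id
  terms <- terms[!duplicated(names(terms))]
  structure(list(ortholog = ortholog, gene2ensembl = gene2ensembl,
                 gene2go = gene2go, resolved = resolved, terms = terms),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  n_ann <- sum(lengths(x$resolved) > 0)
  cat(sprintf("annotation_map: %d genes (%d with >= 1 GO ID), %d GO terms\n",
              length(x$resolved), n_ann, length(x$terms)))
  invisible(x)
}
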