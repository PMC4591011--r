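# CDT/GTR output in the Eisen Cluster / Java TreeView dialect.
#
# CDT: tab-delimited expression table with GID/ORF/NAME/GWEIGHT header
# columns and an EWEIGHT row, genes listed in dendrogram leaf order.
# GTR: one line per merge, "NODEmX <child> <child> <similarity>", children
# being GENEiX (zero-based leaves) or earlier NODEmX ids; similarity is
# 1 - joining distance, so it is non-increasing down the file.

gid_of <- function(code) {
  ifelse(code < 0L, sprintf("GENE%dX", -code - 1L), sprintf("NODE%dX", code))
}

#' Write CDT and GTR files for a clustered SR table
#'
#' @param srt the [sr_table] the tree was built from.
#' @param tree a [cluster_tree][average_linkage_tree] over a subset of
#'   `srt`'s genes.
#' @param cdt_path,gtr_path output file paths.
#' @return invisibly, a list with the two paths.
#' @export
write_cdt_gtr <- function(srt, tree, cdt_path, gtr_path) {
  stopifnot(inherits(srt, "sr_table"), inherits(tree, "cluster_tree"))
  if (!all(tree$labels %in% srt$genes))
    tsr_stop("tree leaves are not all present in the SR table",
             "consistency_error")
  # GTR
  gtr <- sprintf("NODE%dX\t%s\t%s\t%.6g",
                 seq_len(nrow(tree$merge)),
                 gid_of(tree$merge[, 1L]), gid_of(tree$merge[, 2L]),
                 tree$similarity)
  writeLines(gtr, gtr_path)
  # CDT, genes in leaf order
  ord <- tree$order
  genes <- tree$labels[ord]
  x <- srt$sr[genes, , drop = FALSE]
  header <- paste(c("GID", "ORF", "NAME", "GWEIGHT", srt$tissues),
                  collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "", rep("1", length(srt$tissues))),
                   collapse = "\t")
  rows <- vapply(seq_along(genes), function(r) {
    paste(c(sprintf("GENE%dX", ord[r] - 1L), genes[r], genes[r], "1",
            sprintf("%.6g", x[r, ])), collapse = "\t")
  }, "")
  writeLines(c(header, eweight, rows), cdt_path)
  invisible(list(cdt = cdt_path, gtr = gtr_path))
}

#' Read a CDT file back
#'
#' @param path CDT file written by [write_cdt_gtr].
#' @return list: `genes` (in file = leaf order), `gid` (GENEiX ids),
#'   `tissues`, `sr` matrix.
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  tissues <- header[-(1:4)]
  body <- lines[-(1:2)]                     # drop header + EWEIGHT
  parts <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, "", 2L)
  sr <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-(1:4)])))
  dimnames(sr) <- list(genes, tissues)
  list(genes = genes, gid = vapply(parts, `[[`, "", 1L),
       tissues = tissues, sr = sr)
}

#' Read a GTR file back
#'
#' @param path GTR file written by [write_cdt_gtr].
#' @return list: `merge` (hclust-coded matrix), `similarity` vector.
#' @export
read_gtr <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  decode <- function(id) {
    num <- as.integer(sub("^(GENE|NODE)([0-9]+)X$", "\\2", id))
    ifelse(grepl("^GENE", id), -(num + 1L), num)
  }
  merge <- cbind(decode(vapply(parts, `[[`, "", 2L)),
                 decode(vapply(parts, `[[`, "", 3L)))
  list(merge = merge,
       similarity = as.numeric(vapply(parts, `[[`, "", 4L)))
}
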