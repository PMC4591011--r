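# Shared fixtures and independent oracles. Every oracle here is a direct,
# brute-force restatement of the definition, kept free of the package's own
# code paths.

# random transcript structures on one chromosome
rand_transcripts <- function(n_tx = 3, max_exons = 5, span = 2000) {
  lapply(stats::setNames(seq_len(n_tx), paste0("tx", seq_len(n_tx))),
         function(i) {
           k <- sample(1:max_exons, 1)
           s <- sort(sample(span, k))
           data.frame(start = s, end = s + sample(10:120, k, replace = TRUE))
         })
}

# per-base boolean-membership union of exon intervals
flatten_oracle <- function(transcripts) {
  hi <- max(vapply(transcripts, function(tx) max(tx$end), 0))
  covered <- logical(hi)
  for (tx in transcripts) for (r in seq_len(nrow(tx)))
    covered[tx$start[r]:tx$end[r]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# expression table with explicit RPKM values for given tissues; counts are
# made large enough to clear any read filter unless overridden
expr_from_rpkm <- function(rpkm_sf, rpkm_gc, tissues, genes = NULL,
                           length_bp = 1000, total = 1e6,
                           counts_sf = NULL, counts_gc = NULL) {
  # rpkm_sf / rpkm_gc: genes x tissues matrices (or vectors for one gene)
  rpkm_sf <- rbind(rpkm_sf); rpkm_gc <- rbind(rpkm_gc)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(rpkm_sf)))
  lens <- stats::setNames(rep(length_bp, length(genes)), genes)
  to_counts <- function(rpkm) round(rpkm * (length_bp / 1000) * (total / 1e6))
  samples <- list()
  for (t in seq_along(tissues)) {
    csf <- if (is.null(counts_sf)) to_counts(rpkm_sf[, t]) else counts_sf[, t]
    cgc <- if (is.null(counts_gc)) to_counts(rpkm_gc[, t]) else counts_gc[, t]
    samples <- c(samples,
                 list(sample_counts(tissues[t], "SF", stats::setNames(csf, genes), total),
                      sample_counts(tissues[t], "GC", stats::setNames(cgc, genes), total)))
  }
  quantify_samples(lens, samples)
}

rand_sr_table <- function(n_genes = 20, tissues = c("brain", "eye", "ovary",
                                                    "testis", "liver", "intestine"),
                          sd = 1.5) {
  m <- matrix(stats::rnorm(n_genes * length(tissues), sd = sd),
              n_genes, length(tissues),
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), tissues))
  sr_table(m)
}

# tiny annotation chain from explicit link lists
make_ann <- function(links, genes = NULL) {
  # links: list(gene = list(human, entrez, go = c(...))) possibly repeated genes
  orth <- do.call(rbind, lapply(names(links), function(g)
    data.frame(species_gene_id = g, human_gene_id = links[[g]]$human,
               stringsAsFactors = FALSE)))
  g2e <- unique(do.call(rbind, lapply(links, function(l)
    data.frame(tax_id = 9606L, entrez_id = l$entrez,
               ensembl_gene_id = l$human, stringsAsFactors = FALSE))))
  g2g <- do.call(rbind, lapply(links, function(l)
    if (length(l$go)) data.frame(tax_id = 9606L, entrez_id = l$entrez,
                                 go_id = l$go, evidence = "IEA",
                                 qualifier = "-", term_label = l$go,
                                 stringsAsFactors = FALSE) else NULL))
  build_annotation_map(orth, data.frame(entrez_id = g2e$entrez_id,
                                        ensembl_gene_id = g2e$ensembl_gene_id),
                       data.frame(entrez_id = g2g$entrez_id, go_id = g2g$go_id,
                                  term_label = g2g$term_label),
                       genes = genes)
}

# annotation map where gene -> GO sets are given directly (one synthetic
# human/entrez link per gene)
ann_from_sets <- function(go_sets, genes = names(go_sets)) {
  links <- lapply(seq_along(go_sets), function(i)
    list(human = sprintf("H%04d", i), entrez = i, go = go_sets[[i]]))
  names(links) <- names(go_sets)
  make_ann(links, genes = genes)
}

# exhaustive-draw hypergeometric upper tail: population N with K successes,
# draw n, P(X >= k) by enumerating all C(N, n) draws
hyper_enum <- function(k, K, n, N) {
  pop <- c(rep(TRUE, K), rep(FALSE, N - K))
  draws <- utils::combn(N, n)
  mean(colSums(matrix(pop[draws], nrow = n)) >= k)
}

# two-sided Fisher p by enumerating all tables with the observed margins
fisher_enum <- function(a, b, c, d) {
  # table [[a, b], [c, d]]; margins fixed
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

paper_table <- function(name) {
  read.delim(system.file("extdata", name, package = "tsrpipe"),
             check.names = FALSE)
}

six_tissues <- c("brain", "eye", "ovary", "testis", "liver", "intestine")
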