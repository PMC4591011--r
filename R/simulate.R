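# Synthetic studies with planted effects.
#
# Emulates the experimental design the pipeline targets: six tissues, one
# pooled spaceflight (SF) and one pooled ground-control (GC) library per
# tissue, no replicates. Counts are negative binomial around expected
# values proportional to baseline expression x exonic length x library
# depth, times 2^(planted log2 effect) in the SF condition. A configurable
# number of genes carry multi-tissue effects (|log2| >= 1 in >= 4 tissues)
# or a single dominant-tissue effect, and a planted GO category is enriched
# among the focal tissue's upregulated genes. Everything is driven by one
# seed: identical configs give identical studies.

#' Simulation configuration
#'
#' @param n_genes number of genes (default 2000).
#' @param tissues tissue names (default the six-tissue design).
#' @param baseline_log_mean,baseline_log_sd lognormal (meanlog/sdlog)
#'   baseline relative expression across genes. The sdlog default 1.5 gives
#'   a realistic dynamic range of ~4 orders of magnitude and leaves a low
#'   tail of genes that deliberately fail the RPKM/read filters.
#' @param tissue_log_sd sdlog of the per-(gene, tissue) expression factor;
#'   shared by SF and GC of a tissue, so it cancels out of SR.
#' @param nb_dispersion negative binomial dispersion (1/size). The default
#'   0.005 reflects technical-only variation between two libraries from
#'   pooled RNA; there is no biological replication to inflate it.
#' @param library_size total mapped reads per sample (default 1e7).
#' @param aligned_fraction fraction of the library landing on gene models
#'   (the rest emulates intergenic/multi-mapped reads; default 0.85).
#' @param n_multi_tissue genes planted with |log2 effect| in \[1.5, 3.5\] in
#'   4..6 tissues, one sign per gene (default 30).
#' @param n_tissue_specific genes planted with a dominant effect (|log2| in
#'   \[2.5, 5\]) in `ts_focal_tissue` only (default 30).
#' @param ts_focal_tissue focal tissue for the tissue-specific genes
#'   (default `"intestine"`).
#' @param ts_direction `"up"`, `"down"` or `"mixed"` sign of the
#'   tissue-specific effects (default `"up"`).
#' @param planted_go_id GO ID enriched among the tissue-specific genes
#'   (default `"GO:0055114"`, oxidation-reduction).
#' @param planted_go_overlap_fraction fraction of tissue-specific genes
#'   annotated with the planted GO ID (default 0.5).
#' @param n_go_terms size of the background GO term pool (default 40).
#' @param go_background_rate probability that any other annotated gene
#'   carries the planted GO ID (default 0.015).
#' @param ortholog_rate fraction of genes with a human ortholog, hence
#'   resolvable GO annotation (default 0.9).
#' @param seed integer RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              tissues = c("brain", "eye", "ovary",
                                          "testis", "liver", "intestine"),
                              baseline_log_mean = 3,
                              baseline_log_sd = 1.5,
                              tissue_log_sd = 0.3,
                              nb_dispersion = 0.005,
                              library_size = 1e7,
                              aligned_fraction = 0.85,
                              n_multi_tissue = 30L,
                              n_tissue_specific = 30L,
                              ts_focal_tissue = "intestine",
                              ts_direction = c("up", "down", "mixed"),
                              planted_go_id = "GO:0055114",
                              planted_go_overlap_fraction = 0.5,
                              n_go_terms = 40L,
                              go_background_rate = 0.015,
                              ortholog_rate = 0.9,
                              seed = 1L) {
  ts_direction <- match.arg(ts_direction)
  if (!is_count(n_genes, 1) || n_genes < 2)
    tsr_stop("n_genes must be a positive integer", "invalid_config")
  if (n_multi_tissue + n_tissue_specific > n_genes)
    tsr_stop("more planted genes than genes", "invalid_config")
  if (nb_dispersion <= 0 || baseline_log_sd <= 0 || tissue_log_sd < 0)
    tsr_stop("dispersion/variance parameters must be positive", "invalid_config")
  if (!ts_focal_tissue %in% tissues)
    tsr_stop("ts_focal_tissue must be one of the configured tissues",
             "invalid_config")
  if (!grepl(GO_ID_RE, planted_go_id))
    tsr_stop("planted_go_id must match GO:[0-9]{7}", "invalid_config")
  if (planted_go_overlap_fraction < 0 || planted_go_overlap_fraction > 1)
    tsr_stop("planted_go_overlap_fraction must be in [0, 1]", "invalid_config")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a complete study
#'
#' @param cfg a [simulation_config].
#' @return object of class `synthetic_study`: list with `cfg`, `models`
#'   (named list of [gene_model][flatten_gene_model]), `samples` (list of
#'   [sample_counts]), `truth` (data.frame: gene_id, class, direction,
#'   planted_go, one `effect_<tissue>` column per tissue), and `maps`
#'   (ortholog / gene2ensembl / gene2go data.frames).
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  tissues <- cfg$tissues
  genes <- sprintf("GENE%05d", seq_len(n))

  models <- sim_gene_models(genes)
  len_bp <- vapply(models, function(m) as.numeric(m$length_bp), 0)

  # planted log2 effects
  effect <- matrix(0, n, length(tissues), dimnames = list(genes, tissues))
  class <- rep("null", n)
  direction <- rep("none", n)
  planted <- sample(n, cfg$n_multi_tissue + cfg$n_tissue_specific)
  mt <- planted[seq_len(cfg$n_multi_tissue)]
  ts <- planted[cfg$n_multi_tissue + seq_len(cfg$n_tissue_specific)]
  for (i in mt) {
    k <- sample(4:length(tissues), 1L)
    sgn <- sample(c(-1, 1), 1L)
    cols <- sample(length(tissues), k)
    effect[i, cols] <- sgn * stats::runif(k, 1.5, 3.5)
  }
  class[mt] <- "multi-tissue"
  direction[mt] <- ifelse(rowSums(effect[mt, , drop = FALSE]) > 0, "up", "down")
  ts_sign <- switch(cfg$ts_direction,
                    up = rep(1, length(ts)),
                    down = rep(-1, length(ts)),
                    mixed = sample(c(-1, 1), length(ts), replace = TRUE))
  effect[ts, cfg$ts_focal_tissue] <- ts_sign * stats::runif(length(ts), 2.5, 5)
  class[ts] <- "tissue-specific"
  direction[ts] <- ifelse(ts_sign > 0, "up", "down")

  # expression and counts
  rel <- stats::rlnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)
  tissue_fac <- matrix(stats::rlnorm(n * length(tissues), 0, cfg$tissue_log_sd),
                       n, length(tissues))
  size_nb <- 1 / cfg$nb_dispersion
  reads_on_genes <- cfg$library_size * cfg$aligned_fraction
  samples <- list()
  for (t in seq_along(tissues)) {
    # One scale per tissue pair, shared by SF and GC, so a planted effect
    # changes only its own gene's mean (no compositional compression of the
    # null genes; mu_SF / mu_GC = 2^effect exactly).
    w_gc <- rel * tissue_fac[, t] * (len_bp / 1000)
    w_sf <- w_gc * 2^effect[, t]
    scale_t <- reads_on_genes / mean(c(sum(w_gc), sum(w_sf)))
    for (cond in c("SF", "GC")) {
      mu <- scale_t * (if (cond == "SF") w_sf else w_gc)
      counts <- stats::rnbinom(n, size = size_nb, mu = mu)
      # nominal library size, raised only if a small, heavily planted
      # simulation generates more aligned reads than the nominal total
      total <- max(cfg$library_size, sum(counts))
      samples[[length(samples) + 1L]] <-
        sample_counts(tissues[t], cond,
                      stats::setNames(counts, genes), total)
    }
  }

  maps <- sim_annotation_maps(cfg, genes, which(class == "tissue-specific" &
                                                  direction == "up"))
  truth <- data.frame(gene_id = genes, class = class, direction = direction,
                      planted_go = genes %in% maps$planted_go_genes,
                      stringsAsFactors = FALSE)
  eff_df <- as.data.frame(effect)
  names(eff_df) <- paste0("effect_", tissues)
  truth <- cbind(truth, eff_df)
  rownames(truth) <- NULL

  structure(list(cfg = cfg, models = models, samples = samples,
                 truth = truth,
                 maps = maps[c("ortholog", "gene2ensembl", "gene2go")]),
            class = "synthetic_study")
}

# Gene models on 5 synthetic chromosomes: 1-3 transcripts per gene over a
# shared exon scaffold, with occasional 3'-extension of the last used exon
# so transcripts genuinely disagree on exon boundaries.
sim_gene_models <- function(genes) {
  n <- length(genes)
  chrom_of <- sprintf("chr%d", (seq_len(n) - 1L) %% 5L + 1L)
  cursor <- stats::setNames(rep(1000L, 5), sprintf("chr%d", 1:5))
  models <- vector("list", n)
  for (i in seq_len(n)) {
    n_ex <- sample(2:6, 1L)
    lens <- sample(80:400, n_ex, replace = TRUE)
    gaps <- sample(200:2000, n_ex, replace = TRUE)
    start <- cursor[chrom_of[i]] + gaps[1]
    starts <- start + cumsum(c(0L, (lens + gaps)[-n_ex]))
    ends <- starts + lens - 1L
    n_tx <- sample(1:3, 1L)
    txs <- list()
    for (j in seq_len(n_tx)) {
      first <- if (j == 1L) 1L else sample(seq_len(n_ex), 1L)
      idx <- first:n_ex
      ex <- data.frame(start = starts[idx], end = ends[idx])
      if (j > 1L && stats::runif(1) < 0.5)   # disagreeing 3' boundary
        ex$end[nrow(ex)] <- ex$end[nrow(ex)] + sample(10:120, 1L)
      txs[[sprintf("%s.t%d", genes[i], j)]] <- ex
    }
    models[[i]] <- flatten_gene_model(txs, gene_id = genes[i],
                                      chrom = chrom_of[i],
                                      strand = sample(c("+", "-"), 1L))
    cursor[chrom_of[i]] <- max(vapply(txs, function(e) max(e$end), 0)) + 1L
  }
  stats::setNames(models, genes)
}

# Ortholog/Entrez/GO tables with one planted category among the focal
# tissue's upregulated tissue-specific genes.
sim_annotation_maps <- function(cfg, genes, ts_up_idx) {
  n <- length(genes)
  has_orth <- stats::runif(n) < cfg$ortholog_rate
  # genes meant to carry the planted GO ID must be annotatable
  n_planted_go <- round(cfg$planted_go_overlap_fraction * length(ts_up_idx))
  go_carriers <- if (n_planted_go > 0)
    sort(sample(ts_up_idx, n_planted_go)) else integer(0)
  has_orth[go_carriers] <- TRUE
  human <- sprintf("ENSG%011d", seq_len(n))
  ortholog <- data.frame(species_gene_id = genes[has_orth],
                         human_gene_id = human[has_orth],
                         stringsAsFactors = FALSE)
  # a few many-to-many links: extra ortholog pointing at a neighbour's human id
  extra <- which(has_orth & stats::runif(n) < 0.05)
  extra <- extra[has_orth[(extra %% n) + 1L]]
  if (length(extra))
    ortholog <- rbind(ortholog,
                      data.frame(species_gene_id = genes[extra],
                                 human_gene_id = human[(extra %% n) + 1L],
                                 stringsAsFactors = FALSE))
  ortholog <- ortholog[order(ortholog$species_gene_id, ortholog$human_gene_id), ]
  entrez <- seq_len(n) + 1000L
  gene2ensembl <- data.frame(tax_id = 9606L, entrez_id = entrez,
                             ensembl_gene_id = human,
                             stringsAsFactors = FALSE)
  pool <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  if (cfg$planted_go_id %in% pool)
    tsr_stop("planted_go_id collides with the background term pool",
             "invalid_config")
  # popularity-weighted background terms per gene
  popularity <- stats::rexp(cfg$n_go_terms) + 0.2
  rows <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, 2.5)
    terms <- if (k > 0) sample(pool, min(k, cfg$n_go_terms),
                               prob = popularity) else character(0)
    if (i %in% go_carriers) terms <- c(terms, cfg$planted_go_id)
    else if (stats::runif(1) < cfg$go_background_rate)
      terms <- c(terms, cfg$planted_go_id)
    if (!length(terms)) return(NULL)
    data.frame(tax_id = 9606L, entrez_id = entrez[i], go_id = terms,
               evidence = "IEA", qualifier = "-",
               term_label = ifelse(terms == cfg$planted_go_id,
                                   "planted synthetic category",
                                   sprintf("synthetic category %s",
                                           sub("GO:", "", terms))),
               stringsAsFactors = FALSE)
  })
  gene2go <- do.call(rbind, rows)
  rownames(gene2go) <- NULL
  list(ortholog = ortholog, gene2ensembl = gene2ensembl, gene2go = gene2go,
       planted_go_genes = genes[go_carriers])
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d genes, %d samples; planted: %d multi-tissue, %d tissue-specific (seed %d)\n",
              length(x$models), length(x$samples),
              sum(x$truth$class == "multi-tissue"),
              sum(x$truth$class == "tissue-specific"), x$cfg$seed))
  invisible(x)
}

#' Score responder calls against the planted truth
#'
#' @param truth the `truth` data.frame of a [simulate_study] result.
#' @param calls data.frame of calls with columns `gene_id` and `class`
#'   (e.g. rbind of [multi_tissue_responders] and
#'   [tissue_specific_responders] outputs).
#' @param analyzed_genes genes that survived filtering; planted genes outside
#'   this set are excluded from the recall denominator (they were never
#'   testable). Default: all genes in `truth`.
#' @return data.frame per class: tp, fp, fn, precision, recall. Precision is
#'   NA ("not applicable") when a class was never called.
#' @export
evaluate_recovery <- function(truth, calls, analyzed_genes = NULL) {
  if (is.null(analyzed_genes)) analyzed_genes <- truth$gene_id
  truth <- truth[truth$gene_id %in% analyzed_genes, ]
  calls <- calls[calls$gene_id %in% analyzed_genes, , drop = FALSE]
  classes <- sort(unique(c(setdiff(truth$class, "null"), calls$class)))
  res <- lapply(classes, function(cl) {
    truth_set <- truth$gene_id[truth$class == cl]
    call_set <- unique(calls$gene_id[calls$class == cl])
    tp <- length(intersect(call_set, truth_set))
    fp <- length(setdiff(call_set, truth_set))
    fn <- length(setdiff(truth_set, call_set))
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
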