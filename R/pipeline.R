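# Top-level pipeline: quantify -> filter -> SR/||TSR|| -> responders ->
# Fisher comparisons -> GO enrichment -> clustering, with every intermediate
# written as TSV plus a machine-readable run manifest.

#' Pipeline configuration
#'
#' Unknown keys are rejected, every threshold is validated at construction.
#'
#' @param gtf,counts,totals,ortholog,gene2ensembl,gene2go input file paths.
#' @param out_dir output directory.
#' @param tissues tissue names expected in the counts table.
#' @param reference_tissue reference for the Fisher proportion comparisons.
#' @param min_rpkm,min_reads filtering thresholds (see [filter_config]).
#' @param sr_threshold,min_tissues multi-tissue responder thresholds.
#' @param min_focal_sr,dominance_ratio tissue-specific responder thresholds;
#'   the focal tissue is `reference_tissue`.
#' @param p_cut,q_cut enrichment significance cutoffs.
#' @param top_n,metric,k clustering options: genes ranked by ||TSR||,
#'   distance metric, number of flat clusters.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters only when the inputs were simulated).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(gtf, counts, totals, ortholog = NULL,
                            gene2ensembl = NULL, gene2go = NULL,
                            out_dir = ".",
                            tissues = c("brain", "eye", "ovary",
                                        "testis", "liver", "intestine"),
                            reference_tissue = "intestine",
                            min_rpkm = 1.0, min_reads = 5L,
                            sr_threshold = 1.0, min_tissues = 4L,
                            min_focal_sr = 2.0, dominance_ratio = 2.0,
                            p_cut = 0.05, q_cut = 0.05,
                            top_n = 400L,
                            metric = c("uncentered", "centered", "euclidean"),
                            k = 5L, seed = 1L) {
  metric <- match.arg(metric)
  if (!reference_tissue %in% tissues)
    tsr_stop(sprintf("reference_tissue '%s' is not in tissues", reference_tissue),
             "invalid_config")
  filter_config(min_rpkm, min_reads)  # validates thresholds
  for (nm in c("sr_threshold", "min_focal_sr", "dominance_ratio"))
    if (get(nm) < 0) tsr_stop(paste(nm, "must be >= 0"), "invalid_config")
  for (nm in c("p_cut", "q_cut"))
    if (get(nm) <= 0 || get(nm) > 1)
      tsr_stop(paste(nm, "must be in (0, 1]"), "invalid_config")
  if (!is_count(min_tissues, 1) || !is_count(top_n, 1) || !is_count(k, 1))
    tsr_stop("min_tissues, top_n and k must be positive integers",
             "invalid_config")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Keys mirror the arguments of [pipeline_config]; unknown keys are
#' rejected before any computation.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(pipeline_config)), "metric")
  unknown <- setdiff(names(vals), c(known, "metric"))
  if (length(unknown))
    tsr_stop(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
             "invalid_config")
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes quantification, filtering, SR/||TSR|| scoring, responder
#' classification, Fisher inter-tissue comparisons, GO enrichment (when
#' mapping files are configured) and hierarchical clustering. Writes every
#' intermediate TSV plus `manifest.json` under `cfg$out_dir`. Re-running
#' with identical config and inputs produces byte-identical outputs.
#'
#' @param cfg a [pipeline_config].
#' @param quiet suppress stage progress messages (default TRUE).
#' @return invisibly, a result bundle: expression table, filtered sets, SR
#'   table, responder calls, Fisher table, enrichment results, tree,
#'   cluster labels, and the manifest list.
#' @export
run_pipeline <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  inputs <- c(gtf = cfg$gtf, counts = cfg$counts, totals = cfg$totals,
              ortholog = cfg$ortholog, gene2ensembl = cfg$gene2ensembl,
              gene2go = cfg$gene2go)
  missing <- inputs[!vapply(inputs, file.exists, TRUE)]
  if (length(missing))
    tsr_stop(paste("missing input file(s):",
                   paste(sprintf("%s (%s)", missing, names(missing)),
                         collapse = ", ")),
             "missing_input")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(package = "tsrpipe",
                   version = as.character(utils::packageVersion("tsrpipe")),
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "out_dir")],
                   stages = list())

  say("stage quantify")
  models <- read_gtf_models(cfg$gtf)
  samples <- read_counts_table(cfg$counts, cfg$totals, tissues = cfg$tissues)
  expr <- quantify_samples(models, samples)
  got <- unique(expr$samples$tissue)
  if (length(setdiff(cfg$tissues, got)))
    tsr_stop(paste("counts table lacks tissue(s):",
                   paste(setdiff(cfg$tissues, got), collapse = ", ")),
             "incomplete_design")
  write_rpkm_table(expr, out("rpkm.tsv"))
  manifest$stages$quantify <- list(n_genes = length(expr$genes),
                                   n_samples = nrow(expr$samples))

  say("stage filter")
  per_tissue <- filter_genes(expr, filter_config(cfg$min_rpkm, cfg$min_reads,
                                                 scope = "per-tissue"),
                             tissues = cfg$tissues)
  all_tissue <- filter_genes(expr, filter_config(cfg$min_rpkm, cfg$min_reads,
                                                 scope = "all-tissues"),
                             tissues = cfg$tissues)
  manifest$stages$filter <- list(input = length(expr$genes),
                                 per_tissue = lapply(per_tissue, length),
                                 all_tissues = length(all_tissue))

  say("stage score (%d genes)", length(all_tissue))
  srt <- compute_sr_table(expr, genes = all_tissue, tissues = cfg$tissues)
  write_sr_table(srt, out("sr_table.tsv"))
  manifest$stages$score <- list(input = length(all_tissue),
                                output = length(srt$genes))

  say("stage responders")
  twofold <- do.call(rbind, lapply(cfg$tissues, function(t) {
    g <- per_tissue[[t]]
    sr <- space_responsiveness(expr$rpkm[g, sample_col(expr, t, "SF")],
                               expr$rpkm[g, sample_col(expr, t, "GC")])
    cls <- classify_twofold(sr)
    data.frame(tissue = t, up = sum(cls == "up"), down = sum(cls == "down"),
               total = length(g), stringsAsFactors = FALSE)
  }))
  data.table::fwrite(twofold, out("twofold_counts.tsv"), sep = "\t")
  calls <- rbind(
    multi_tissue_responders(srt, cfg$sr_threshold, cfg$min_tissues)[
      c("gene_id", "class", "tissues", "direction")],
    tissue_specific_responders(srt, cfg$reference_tissue, cfg$min_focal_sr,
                               cfg$dominance_ratio)[
      c("gene_id", "class", "tissues", "direction")])
  data.table::fwrite(calls, out("responder_calls.tsv"), sep = "\t")
  manifest$stages$responders <- list(input = length(srt$genes),
                                     twofold = twofold$up + twofold$down,
                                     calls = nrow(calls))

  say("stage compare")
  fisher <- compare_tissue_proportions(twofold, cfg$reference_tissue)
  data.table::fwrite(fisher, out("fisher.tsv"), sep = "\t")
  manifest$stages$compare <- list(tests = nrow(fisher))

  enr_all <- NULL
  if (!is.null(cfg$ortholog)) {
    say("stage enrich")
    ann <- build_annotation_map(cfg$ortholog, cfg$gene2ensembl, cfg$gene2go,
                                genes = expr$genes)
    enr_all <- do.call(rbind, lapply(cfg$tissues, function(t) {
      g <- per_tissue[[t]]
      sr <- space_responsiveness(expr$rpkm[g, sample_col(expr, t, "SF")],
                                 expr$rpkm[g, sample_col(expr, t, "GC")])
      cls <- classify_twofold(sr)
      do.call(rbind, lapply(c("up", "down"), function(dir) {
        res <- hypergeometric_enrichment(g[cls == dir], g, ann, direction = dir)
        if (nrow(res)) cbind(tissue = t, res) else NULL
      }))
    }))
    if (is.null(enr_all)) enr_all <- cbind(tissue = character(),
                                           empty_enrichment())
    data.table::fwrite(enr_all, out("enrichment.tsv"), sep = "\t")
    sig <- significant_terms(enr_all, cfg$p_cut, cfg$q_cut)
    data.table::fwrite(sig, out("enrichment_significant.tsv"), sep = "\t")
    manifest$stages$enrich <- list(tested = nrow(enr_all),
                                   significant = nrow(sig))
  }

  say("stage cluster")
  top_n <- min(cfg$top_n, length(srt$genes))
  tree <- NULL; clusters <- NULL
  if (top_n >= 2L) {
    top <- rank_top_n(srt, top_n)
    tree <- average_linkage_tree(sr_distance_matrix(srt, top, cfg$metric))
    write_cdt_gtr(srt, tree, out("top_genes.cdt"), out("top_genes.gtr"))
    clusters <- cut_tree(tree, min(cfg$k, top_n))
    data.table::fwrite(data.frame(gene_id = names(clusters),
                                  cluster = unname(clusters)),
                       out("clusters.tsv"), sep = "\t")
    manifest$stages$cluster <- list(input = top_n,
                                    k = length(unique(clusters)))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(expr = expr, per_tissue = per_tissue,
                 all_tissue = all_tissue, srt = srt, twofold = twofold,
                 calls = calls, fisher = fisher, enrichment = enr_all,
                 tree = tree, clusters = clusters, manifest = manifest))
}
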