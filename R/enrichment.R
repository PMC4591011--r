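# GO over-representation: hypergeometric upper tail + Benjamini-Hochberg.

#' Hypergeometric GO over-representation test
#'
#' For every GO category with at least one member in the background, tests
#' whether the study set contains more members than expected when drawing
#' `n` genes without replacement from the background of `N`:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`.
#'
#' The background defaults to the annotated subset of `background` (genes
#' with >= 1 resolved GO ID) — the dominant convention for GO testing, since
#' unannotated genes can never contribute a hit. Set `annotated_only = FALSE`
#' to test against the full background.
#'
#' @param study character vector of study genes (must be a subset of
#'   `background`), e.g. one tissue's upregulated responders.
#' @param background character vector: the analysis universe the study set
#'   was drawn from (e.g. all genes passing filters in that tissue).
#' @param ann an [annotation_map][build_annotation_map].
#' @param direction optional label (`"up"`/`"down"`) carried into the result.
#' @param annotated_only restrict study and background to annotated genes
#'   (default TRUE).
#' @return data.frame: go_id, term_label, direction, k (study hits),
#'   K (category size), n (study size), N (background size), p, q (BH).
#'   Sorted by p ascending, ties by go_id.
#' @export
hypergeometric_enrichment <- function(study, background, ann,
                                      direction = NA_character_,
                                      annotated_only = TRUE) {
  stopifnot(inherits(ann, "annotation_map"))
  if (length(setdiff(study, background)))
    tsr_stop("study set is not a subset of the background", "subset_violation")
  go <- ann$resolved[intersect(names(ann$resolved), background)]
  if (annotated_only) {
    annotated <- names(go)[lengths(go) > 0]
    background <- intersect(background, annotated)
    study <- intersect(study, annotated)
    go <- go[background]
  }
  N <- length(background)
  n <- length(study)
  if (N == 0L || length(go) == 0L)
    return(empty_enrichment())
  bg_pairs <- data.frame(gene = rep(names(go), lengths(go)),
                         go_id = unlist(go, use.names = FALSE),
                         stringsAsFactors = FALSE)
  K_tab <- table(bg_pairs$go_id)
  k_tab <- table(bg_pairs$go_id[bg_pairs$gene %in% study])
  go_ids <- sort(names(K_tab))
  K <- as.integer(K_tab[go_ids])
  k <- as.integer(k_tab[go_ids])
  k[is.na(k)] <- 0L
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(
    go_id = go_ids,
    term_label = unname(ann$terms[go_ids]),
    direction = direction,
    k = k, K = K, n = n, N = N,
    p = p, q = bh_adjust(p),
    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$go_id, method = "radix"), ]
  rownames(res) <- NULL
  res
}

empty_enrichment <- function() {
  data.frame(go_id = character(), term_label = character(),
             direction = character(), k = integer(), K = integer(),
             n = integer(), N = integer(), p = numeric(), q = numeric(),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` over the p-values sorted
#' ascending, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted values (same order as the input).
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    tsr_stop("p-values must lie in [0, 1]", "domain_error")
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(pmin(1, pvalues[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Filter enrichment results to significant terms
#'
#' @param results output of [hypergeometric_enrichment] (rows from several
#'   calls may be concatenated).
#' @param p_cut,q_cut strict upper thresholds on p and BH q (defaults 0.05).
#' @return the significant rows, sorted by p ascending then go_id.
#' @export
significant_terms <- function(results, p_cut = 0.05, q_cut = 0.05) {
  keep <- results$p < p_cut & results$q < q_cut
  out <- results[keep, ]
  out <- out[order(out$p, out$go_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}
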