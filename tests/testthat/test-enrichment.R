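# Annotation chain, hypergeometric over-representation, BH adjustment.

test_that("build_annotation_map composes the three-link chain", {
  ann <- make_ann(list(g1 = list(human = "h1", entrez = 101, go = "GO:0000001")))
  expect_equal(ann$resolved$g1, "GO:0000001")

  # gene with no ortholog resolves to the empty set
  ann2 <- make_ann(list(g1 = list(human = "h1", entrez = 101, go = "GO:0000001")),
                   genes = c("g1", "orphan"))
  expect_equal(ann2$resolved$orphan, character(0))

  # two orthologs sharing a GO ID: the ID appears once (set union)
  orth <- data.frame(species_gene_id = c("g1", "g1"),
                     human_gene_id = c("h1", "h2"))
  g2e <- data.frame(entrez_id = c(101L, 102L), ensembl_gene_id = c("h1", "h2"))
  g2g <- data.frame(entrez_id = c(101L, 102L, 102L),
                    go_id = c("GO:0000001", "GO:0000001", "GO:0000002"),
                    term_label = "t")
  ann3 <- build_annotation_map(orth, g2e, g2g)
  expect_equal(ann3$resolved$g1, c("GO:0000001", "GO:0000002"))
})

test_that("build_annotation_map matches a path-enumeration oracle on random chains", {
  set.seed(12)
  for (rep in 1:10) {
    genes <- sprintf("g%02d", 1:12)
    humans <- sprintf("h%02d", 1:10)
    orth <- data.frame(
      species_gene_id = sample(genes, 15, replace = TRUE),
      human_gene_id = sample(humans, 15, replace = TRUE))
    g2e <- data.frame(entrez_id = sample(100:110, 12, replace = TRUE),
                      ensembl_gene_id = sample(humans, 12, replace = TRUE))
    g2g <- data.frame(entrez_id = sample(100:110, 20, replace = TRUE),
                      go_id = sprintf("GO:%07d", sample(1:6, 20, replace = TRUE)),
                      term_label = "t")
    ann <- build_annotation_map(orth, g2e, g2g, genes = genes)
    for (g in genes) {
      # brute-force: enumerate every ortholog/entrez path
      gos <- character(0)
      for (h in orth$human_gene_id[orth$species_gene_id == g])
        for (e in g2e$entrez_id[g2e$ensembl_gene_id == h])
          gos <- c(gos, g2g$go_id[g2g$entrez_id == e])
      expect_equal(ann$resolved[[g]], sort(unique(gos)))
    }
  }
})

test_that("build_annotation_map flags malformed GO ids and warns on empty maps", {
  orth <- data.frame(species_gene_id = "g1", human_gene_id = "h1")
  g2e <- data.frame(entrez_id = 101L, ensembl_gene_id = "h1")
  bad <- data.frame(entrez_id = 101L, go_id = "GO:123", term_label = "t")
  expect_error(build_annotation_map(orth, g2e, bad), class = "parse_error")
  empty <- data.frame(entrez_id = integer(), go_id = character(),
                      term_label = character())
  expect_warning(build_annotation_map(orth, g2e, empty), "empty mapping")
})

test_that("hypergeometric p matches exhaustive draw enumeration", {
  ann <- ann_from_sets(list(a = "GO:0000001", b = "GO:0000001",
                            c = "GO:0000001", d = "GO:0000002",
                            e = "GO:0000002", f = "GO:0000002",
                            g = "GO:0000002", h = "GO:0000002",
                            i = "GO:0000002", j = "GO:0000002"))
  bg <- letters[1:10]
  # N=10, K=3, n=4, k=2 -> P(X>=2) = 70/210
  res2 <- hypergeometric_enrichment(c("a", "b", "d", "e"), bg, ann)
  r2 <- res2[res2$go_id == "GO:0000001", ]
  expect_equal(r2[, c("k", "K", "n", "N")],
               data.frame(k = 2L, K = 3L, n = 4L, N = 10L),
               ignore_attr = TRUE)
  expect_equal(r2$p, 70 / 210)
  expect_equal(r2$p, hyper_enum(2, 3, 4, 10))
  # k = n = K: single most-extreme-draw probability
  res3 <- hypergeometric_enrichment(c("a", "b", "c"), bg, ann)
  r3 <- res3[res3$go_id == "GO:0000001", ]
  expect_equal(r3$p, hyper_enum(3, 3, 3, 10))
  expect_equal(r3$p, 1 / choose(10, 3))
  # k = 0 -> upper tail is 1
  res4 <- hypergeometric_enrichment(c("d", "e"), bg, ann)
  expect_equal(res4$p[res4$go_id == "GO:0000001"], 1.0)
  # study must be inside the background
  expect_error(hypergeometric_enrichment(c("a", "zz"), bg, ann),
               class = "subset_violation")
})

test_that("enrichment is permutation-deterministic and monotone in annotated additions", {
  set.seed(13)
  genes <- sprintf("g%02d", 1:30)
  sets <- lapply(genes, function(g)
    sprintf("GO:%07d", sample(1:5, sample(0:3, 1))))
  names(sets) <- genes
  ann <- ann_from_sets(sets)
  bg <- genes
  study <- sample(genes, 10)
  res <- hypergeometric_enrichment(study, bg, ann)
  # relabeling/permuting input order changes nothing
  res_perm <- hypergeometric_enrichment(sample(study), sample(bg), ann)
  expect_equal(res, res_perm)
  # adding a gene annotated to a category never increases that category's p
  for (go in res$go_id[1:min(3, nrow(res))]) {
    carriers <- genes[vapply(sets[genes], function(s) go %in% s, TRUE)]
    extra <- setdiff(carriers, study)
    if (!length(extra)) next
    res2 <- hypergeometric_enrichment(c(study, extra[1]), bg, ann)
    expect_lte(res2$p[res2$go_id == go], res$p[res$go_id == go])
  }
})

test_that("bh_adjust implements the step-up definition", {
  expect_equal(bh_adjust(0.037), 0.037)
  # worked example: all four adjust to the largest p * m / rank = 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # order preservation with the input
  p <- c(0.3, 0.001, 0.2, 0.001)
  expect_equal(bh_adjust(p)[2], bh_adjust(p)[4])
  set.seed(14)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"))   # independent implementation
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "domain_error")
  expect_error(bh_adjust(c(-0.1)), class = "domain_error")
})

test_that("significant_terms filters on both p and q and sorts deterministically", {
  expect_equal(nrow(significant_terms(empty <- data.frame(
    go_id = character(), p = numeric(), q = numeric()))), 0)
  one <- data.frame(go_id = "GO:0000001", p = 0.04, q = 0.06)
  expect_equal(nrow(significant_terms(one)), 0)   # q fails
  set.seed(15)
  res <- data.frame(go_id = sprintf("GO:%07d", 1:40),
                    p = runif(40, 0, 0.2))
  res$q <- bh_adjust(res$p)
  got <- significant_terms(res, 0.1, 0.5)
  oracle <- res[res$p < 0.1 & res$q < 0.5, ]
  oracle <- oracle[order(oracle$p, oracle$go_id), ]
  rownames(oracle) <- NULL
  expect_equal(got, oracle)
})
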