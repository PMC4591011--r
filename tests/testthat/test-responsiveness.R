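# Filtering, SR / ||TSR|| scoring, responder classes, Fisher comparisons.

test_that("filter_genes applies inclusive thresholds in both conditions", {
  tissues <- c("brain", "liver")
  rpkm_sf <- rbind(c(1.0, 1.0), c(5, 0.9), c(5, 5))
  rpkm_gc <- rbind(c(1.0, 1.0), c(5, 5), c(0.9, 5))
  # length 5000, total 1e6: count = 5 x RPKM, so RPKM 1.0 sits exactly at
  # the read boundary (5 reads) too
  expr <- expr_from_rpkm(rpkm_sf, rpkm_gc, tissues, length_bp = 5000)
  got <- filter_genes(expr, filter_config(min_rpkm = 1, min_reads = 5))
  expect_equal(got, "g001")   # boundary gene included, 0.9 genes excluded
  per <- filter_genes(expr, filter_config(scope = "per-tissue"))
  expect_equal(per$brain, c("g001", "g002"))
  expect_equal(per$liver, c("g001", "g003"))
})

test_that("filter_genes matches an exhaustive per-gene predicate oracle and is monotone", {
  set.seed(42)
  tissues <- c("brain", "eye", "liver")
  n <- 200
  counts <- matrix(rpois(n * 6, 30), n, 6)
  counts[sample(length(counts), 150)] <- sample(0:6, 150, replace = TRUE)
  csf <- counts[, c(1, 3, 5)]; cgc <- counts[, c(2, 4, 6)]
  L <- 2000; total <- 5e6
  rpkm <- function(cts) cts / ((L / 1000) * (total / 1e6))
  expr <- expr_from_rpkm(rpkm(csf), rpkm(cgc), tissues,
                         counts_sf = csf, counts_gc = cgc,
                         length_bp = L, total = total)
  cfg <- filter_config(min_rpkm = 1, min_reads = 5)
  got <- filter_genes(expr, cfg)
  oracle <- expr$genes[vapply(seq_len(n), function(i)
    all(vapply(tissues, function(t) {
      sf <- which(expr$samples$tissue == t & expr$samples$condition == "SF")
      gc <- which(expr$samples$tissue == t & expr$samples$condition == "GC")
      expr$rpkm[i, sf] >= 1 && expr$rpkm[i, gc] >= 1 &&
        expr$counts[i, sf] >= 5 && expr$counts[i, gc] >= 5
    }, TRUE)), TRUE)]
  expect_equal(got, oracle)
  # monotonicity: raising either threshold never enlarges the set
  for (mr in c(2, 5, 10))
    expect_true(all(filter_genes(expr, filter_config(min_rpkm = mr)) %in% got))
  for (mc in c(10, 30))
    expect_true(all(filter_genes(expr, filter_config(min_reads = mc)) %in% got))
})

test_that("filter_genes demands a complete SF/GC design", {
  lens <- c(g1 = 1000)
  expr <- quantify_samples(lens, list(sample_counts("brain", "SF",
                                                    c(g1 = 100), 1e6)))
  expect_error(filter_genes(expr, filter_config()),
               class = "incomplete_design")
})

test_that("space_responsiveness reproduces every published ovary SR value", {
  tab <- paper_table("ovary_egg_genes.tsv")
  sr <- space_responsiveness(tab$rpkm_sf, tab$rpkm_gc)
  expect_equal(round_half_away(sr, 2), tab$sr_printed)
})

test_that("space_responsiveness is antisymmetric and rejects non-positive input", {
  expect_equal(space_responsiveness(3.7, 3.7), 0)
  set.seed(5)
  a <- runif(50, 0.01, 1e4); b <- runif(50, 0.01, 1e4)
  expect_equal(space_responsiveness(a, b), -space_responsiveness(b, a))
  expect_error(space_responsiveness(0, 1), class = "nonpositive_rpkm")
  expect_error(space_responsiveness(1, 0), class = "nonpositive_rpkm")
})

test_that("total_space_responsiveness reproduces published ||Z|| within rounding", {
  for (f in c("multi_tissue_sr.tsv", "intestine_redox_sr.tsv")) {
    tab <- paper_table(f)
    sr <- as.matrix(tab[grep("^sr_", names(tab))])
    expect_true(all(abs(total_space_responsiveness(sr) - tab$z_printed) <= 0.02),
                info = f)
  }
  expect_equal(total_space_responsiveness(rep(0, 6)), 0)
})

test_that("||TSR|| obeys its norm bounds on random vectors", {
  set.seed(6)
  for (rep in 1:50) {
    T <- sample(2:8, 1)
    v <- rnorm(T, sd = 2)
    tsr <- total_space_responsiveness(v)
    expect_gte(tsr, max(abs(v)))
    expect_lte(tsr, sqrt(T) * max(abs(v)) + 1e-12)
  }
  expect_error(total_space_responsiveness(c(1, NA)), class = "missing_sr")
})

test_that("classify_twofold uses inclusive log2 boundaries", {
  expect_equal(classify_twofold(c(1.0, 0.99, -1.31, -0.99, 0)),
               c("up", "none", "down", "none", "none"))
  # consistency with the RPKM ratio definition, both directions
  set.seed(7)
  sf <- runif(200, 0.1, 100); gc <- runif(200, 0.1, 100)
  cls <- classify_twofold(space_responsiveness(sf, gc))
  expect_equal(cls == "up", sf >= 2 * gc)
  expect_equal(cls == "down", gc >= 2 * sf)
})

test_that("multi_tissue_responders calls the published multi-tissue genes", {
  tab <- paper_table("multi_tissue_sr.tsv")
  sr <- as.matrix(tab[grep("^sr_", names(tab))])
  dimnames(sr) <- list(tab$gene_symbol, sub("^sr_", "", grep("^sr_", names(tab), value = TRUE)))
  calls <- multi_tissue_responders(sr_table(sr))
  # every published row qualifies at >= 4 tissues with the inclusive threshold
  expect_setequal(calls$gene_id, tab$gene_symbol)
  expect_equal(calls$direction[calls$gene_id == "klf9"], "up")
  expect_equal(calls$n_tissues[calls$gene_id == "klf9"], 4)
  expect_equal(calls$direction[calls$gene_id == "keap1a"], "down")
  # all-zero vectors are never called
  z <- sr_table(matrix(0, 2, 6, dimnames = list(c("a", "b"), colnames(sr))))
  expect_equal(nrow(multi_tissue_responders(z)), 0)
})

test_that("tissue_specific_responders implements the dominant-tissue rule", {
  tab <- paper_table("intestine_redox_sr.tsv")
  sr <- as.matrix(tab[grep("^sr_", names(tab))])
  dimnames(sr) <- list(tab$gene_symbol, sub("^sr_", "", grep("^sr_", names(tab), value = TRUE)))
  calls <- tissue_specific_responders(sr_table(sr), "intestine")
  # every published intestine-specific redox gene is recovered, incl. cdo1
  # (ovary -2.12, dominance ratio 2.75) and cyba (ovary -1.29)
  expect_setequal(calls$gene_id, tab$gene_symbol)
  expect_equal(calls$direction[calls$gene_id == "prdx1"], "up")
  expect_equal(calls$direction[calls$gene_id == "cdo1"], "down")
  # two equal large |SR| values fail dominance
  m <- matrix(c(3, 3, 0, 0, 0, 0), 1,
              dimnames = list("tie", colnames(sr)))
  expect_equal(nrow(tissue_specific_responders(sr_table(m), colnames(sr)[1])), 0)
  expect_error(tissue_specific_responders(sr_table(sr), "gill"),
               class = "unknown_tissue")
})

test_that("rank_top_n sorts by ||TSR|| with lexicographic ties", {
  srt <- sr_table(matrix(c(5, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE,
                         dimnames = list(c("b", "a"), c("t1", "t2", "t3"))))
  expect_equal(rank_top_n(srt, 1), "b")
  expect_setequal(rank_top_n(srt, 2), c("a", "b"))
  expect_error(rank_top_n(srt, 3), class = "invalid_config")
  # full-sort oracle on 1000 random genes with planted ties
  set.seed(8)
  srt2 <- rand_sr_table(1000)
  srt2$tsr[2:6] <- srt2$tsr[1]   # forced ties
  got <- rank_top_n(srt2, 400)
  ord <- order(-srt2$tsr, names(srt2$tsr), method = "radix")
  expect_equal(got, srt2$genes[ord][1:400])
})

test_that("fisher_tissue_comparison matches enumeration and is row-symmetric", {
  # identical proportions put all mass at or below the modal table
  expect_equal(fisher_tissue_comparison(5, 50, 10, 100), 1.0)
  # exhaustive enumeration oracle on a small table
  expect_equal(fisher_tissue_comparison(1, 10, 9, 10),
               fisher_enum(1, 9, 9, 1))
  set.seed(9)
  for (rep in 1:20) {
    ta <- sample(5:25, 1); tb <- sample(5:25, 1)
    ca <- sample(0:ta, 1); cb <- sample(0:tb, 1)
    p <- fisher_tissue_comparison(ca, ta, cb, tb)
    expect_equal(p, fisher_enum(ca, ta - ca, cb, tb - cb), tolerance = 1e-9)
    expect_equal(p, fisher_tissue_comparison(cb, tb, ca, ta))
    expect_true(p >= 0 && p <= 1)
  }
  expect_error(fisher_tissue_comparison(11, 10, 1, 10), class = "invalid_table")
  expect_error(fisher_tissue_comparison(-1, 10, 1, 10), class = "invalid_table")
})

test_that("compare_tissue_proportions flags the published brain-vs-intestine contrast", {
  tab <- paper_table("twofold_counts.tsv")
  res <- compare_tissue_proportions(tab, reference = "intestine")
  expect_equal(nrow(res), 10)   # 5 tissues x 2 directions
  brain_up <- res[res$tissue == "brain" & res$direction == "up", ]
  expect_lt(brain_up$p, 1e-4)
  expect_true(brain_up$significant)
  # every non-reference tissue is significant in both directions (the
  # published table stars every cell)
  expect_true(all(res$significant))
  expect_error(compare_tissue_proportions(tab, reference = "gill"),
               class = "unknown_tissue")
})
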