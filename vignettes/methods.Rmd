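---
title: "Methods: scoring multi-tissue transcriptome responses to spaceflight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring multi-tissue transcriptome responses to spaceflight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Small fish such as medaka can be reared aboard the ISS for weeks, giving a
rare whole-organism view of how different tissues respond to the space
environment. The design this package targets is deliberately minimal: six
tissues (brain, eye, ovary, testis, liver, intestine), each with one pooled
spaceflight (SF) RNA library and one pooled ground-control (GC) library.
There are no biological replicates — RNA from siblings is pooled into a
single sample per tissue and condition — so the analysis is descriptive
ranking and categorical testing, not replicate-based differential
expression. `tsrpipe` implements that analysis end to end, plus a simulator
that generates complete synthetic studies so every stage can be validated
offline.

# Quantification

Transcript models of one gene are flattened into *integrated exons*: the
interval union of all exons of all transcripts (1-based, inclusive ends, the
GTF convention). Where two transcripts disagree on an exon boundary the
union keeps the longer extent; we treat the classical "pick the longer
exon" instruction as the boundary-sharing special case of the union, which
is the only interpretation that keeps the exonic length well defined for
arbitrary overlaps. Expression is

$$\mathrm{RPKM} = \frac{\text{reads on the gene}}
{(\text{exonic length}/10^3)\,(\text{total mapped reads}/10^6)}.$$

The total mapped reads of a library are a *supplied* per-sample quantity.
They are never recomputed by summing gene counts: multi-mapped and
intergenic reads make that sum wrong in real data.

# Filtering

SR is a log-ratio, so both libraries of a tissue must show real expression
before the ratio means anything. A gene passes in a tissue when RPKM ≥ 1
**and** reads ≥ 5 in both the SF and the GC sample; thresholds are
inclusive, and both are configurable (`filter_config()`). Two scopes exist:
per-tissue passing sets (used for per-tissue responder counts and
enrichment backgrounds) and the all-tissues intersection (the cross-tissue
analysis set used for ||TSR|| ranking and clustering). The read filter is
applied per sample — whether it should instead apply to the tissue pair is
ambiguous in the source description; per-sample is the stricter and more
defensible reading.

# Space responsiveness

Per tissue, $\mathrm{SR} = \log_2(\mathrm{RPKM}_{SF}/\mathrm{RPKM}_{GC})$.
Across tissues, the composite

$$\lVert \mathrm{TSR} \rVert = \sqrt{\sum_{t \in \text{tissues}} \mathrm{SR}_t^2}$$

(the Euclidean norm of the SR vector; published tables print it as ||Z||)
ranks genes by overall responsiveness regardless of direction or tissue.

Responder classes:

* **Twofold**: |SR| ≥ 1 in a tissue, inclusive. We follow the table
  footnote convention "high (≥ 1) or low (≤ −1)" rather than a strict
  inequality; SR = 1 is exactly a twofold change and belongs in the class.
* **Multi-tissue**: |SR| ≥ 1 in at least 4 tissues (both thresholds
  configurable). The source material titles this "more than four tissues"
  while listing genes with exactly four qualifying tissues, so at-least-4
  is the only reading consistent with the listed genes.
* **Tissue-specific**: no published definition exists, so the package
  states one — a dominant-tissue rule. The focal tissue's |SR| must reach
  2.0, be the gene's maximum, and be at least 2× the second-largest |SR|.
  Both constants are configurable; the defaults are consistent with every
  gene in the published intestine-specific list, including the two genes
  with a sizable secondary ovary response.

Between-tissue comparisons of responder proportions use a two-sided
Fisher's exact test on the 2×2 table of (responders, non-responders) ×
(tissue, reference tissue), separately for up- and downregulated counts.
Sidedness is not stated in the source; two-sided is the conservative
default.

`rank_top_n()` breaks ||TSR|| ties lexicographically by gene id (radix
order, locale-independent) so ranked lists are reproducible.

# GO enrichment

Annotation is borrowed from human through a three-step join: species gene →
human Ensembl ortholog (BioMart-style table), human Ensembl → Entrez
(gene2ensembl), Entrez → GO (gene2go). All links are many-to-many; a gene's
GO set is the union over all paths, and a gene failing any link resolves to
the empty set. No GO-graph ancestor propagation is performed — records are
joined flat, matching the original Perl-join procedure.

For each category, $p = P(X \ge k)$ with
$X \sim \mathrm{Hypergeometric}(N, K, n)$, where $n$ is the study set (one
tissue's up- or downregulated responders, tested separately), $K$ the
category size in the background, and $N$ the background size. The
background is the tissue's filtered gene set restricted to annotated genes
(configurable to all genes). The source never states its background, which
is why published GO p-values are not reproduction targets; the annotated
background is the dominant convention because unannotated genes can never
contribute a hit. Multiplicity is controlled with Benjamini–Hochberg
(step-up, implemented directly and cross-checked against `p.adjust` in the
tests); significant terms require p < 0.05 and q < 0.05.

# Clustering

The top 400 genes by ||TSR|| are clustered with a faithful reimplementation
of the relevant slice of Eisen's Cluster 3.0: uncentered correlation
distance $d = 1 - \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ (the Cluster
3.0 default; centered correlation and Euclidean are options) and
average-linkage agglomeration. Metric and linkage are not stated in the
source, so the tool's defaults are used. Ties in the merge queue are broken
towards the pair containing the smallest original leaf index, making trees
deterministic and order-invariant. The tree is cut into k = 5 flat clusters
by undoing the last k − 1 merges (five clusters were described in the
original analysis). Output is CDT/GTR in the TreeView dialect; GTR stores
1 − height as the joining "similarity", which for correlation metrics is
the joining correlation itself. SR rows are not normalised before
clustering by default (the source does not mention normalisation); the
distance metric itself removes per-gene scale under uncentered correlation.

Zero SR vectors have no direction, so correlation metrics reject them by
name rather than returning NaN distances.

# The synthetic world

`simulate_study()` emulates the stated design: six tissues × SF/GC, one
pooled library each, negative-binomial counts with mean proportional to
(baseline expression) × (tissue factor) × (exonic length) × (library
depth) × $2^{\text{planted log2 effect}}$ in SF. Defaults, and why:

* `library_size = 1e7`, `n_genes = 2000`: the depth/breadth regime at which
  the stated parameter-recovery properties are defined.
* `baseline_log_sd = 1.5`: a realistic ~4-order-of-magnitude dynamic range;
  the low tail deliberately fails the RPKM/read filters (≈ 1–3% of genes at
  defaults), exercising the filter path.
* `nb_dispersion = 0.005`: both libraries of a tissue come from one RNA
  pool, so the dispersion reflects technical variation only. Biological
  replicate-level dispersions (0.05–0.2) would be wrong for this design
  and would make single-sample SR estimation hopeless — which is precisely
  why the real study pooled.
* planted multi-tissue genes: |log2 effect| uniform in [1.5, 3.5] in 4–6
  tissues, one sign per gene; tissue-specific genes: a single focal-tissue
  effect in [2.5, 5] (intestine, upregulated, by default). 30 of each.
* the planted GO category is attached to half the focal upregulated genes
  (`planted_go_overlap_fraction = 0.5`) over a background carrier rate of
  1.5%, alongside a 40-term popularity-weighted background pool.

One scale is shared by the SF and GC libraries of a tissue, so a planted
effect changes only its own gene's expectation and SR estimators are
unbiased; per-sample renormalisation would instead let strongly planted
genes compress every other gene's share (a compositional artifact this
design intentionally excludes). All randomness flows from one seed;
identical configs write byte-identical studies.

What the generator does **not** emulate: biological replicate variability,
batch/lane effects, read-level errors, mappability bias, and compositional
coupling between genes. A green recovery test therefore establishes that
the estimators and classifiers are correct under the stated sampling model
— not that the thresholds are powerful under real biological noise.

# Numerical and interface choices

* Report-boundary rounding is half-away-from-zero at two decimals
  (`round_half_away()`), matching how published tables round; internal
  computation is always full precision.
* Written minus signs are ASCII; readers also accept Unicode minus and
  en-dash, which published tables frequently typeset.
* Pipeline configuration files are JSON (`read_pipeline_config()`), with
  unknown keys rejected before any computation; there is no YAML dependency
  in the supported stack.
* Errors are classed conditions (`malformed_interval`, `incomplete_design`,
  `subset_violation`, ...) so callers can dispatch on failure modes.
* The pipeline writes a `manifest.json` with config, versions and per-stage
  gene counts; reruns on identical inputs are byte-identical (no
  timestamps in outputs).

# Known limitations

* Single-sample SR has no within-condition variance estimate; calls are
  threshold classifications, not hypothesis tests, and should be read as
  descriptive.
* The ortholog chain inherits every bias of human-centric annotation;
  genes without a human ortholog are invisible to enrichment.
* The Cluster 3.0 reimplementation covers hierarchical gene trees only (no
  array trees, k-means or SOM modes).
* Published GO p-values depend on an unrecoverable background set and are
  intentionally not reproduced; the enrichment machinery is instead
  validated by exhaustive enumeration and planted-category recovery.
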