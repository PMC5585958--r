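---
title: "Unbiased miRNA functional enrichment: model, engines and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unbiased miRNA functional enrichment: model, engines and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirset)
```

## The statistical problem

A differential-expression experiment yields a *group* of miRNAs. Each miRNA
represses hundreds of predicted target genes, so the natural question —
which biological processes does this group regulate? — is usually answered
by testing each annotation category (a GO term, KEGG pathway, etc.) for
over-representation among the group's targets.

The classic answer is Fisher's exact test on the 2x2 table of gene
membership, i.e. a hypergeometric tail probability. That test assumes the
observed target set is an exchangeable draw of genes from the universe. It
is not: target-prediction catalogues are strongly structured. Some genes
are targeted by a large share of all miRNAs, target counts per miRNA span
orders of magnitude, and annotation membership correlates with targeting
propensity. The practical consequence is that *randomly assembled* miRNA
groups produce "significant" categories at far above the nominal rate.

The unbiased alternative moves the unit of resampling from the gene to the
miRNA. For a query group $Q$ of $s$ miRNAs with target-union $T(Q)$ and a
category $C$, define the *overlap* $k_C(Q) = |T(Q) \cap C|$ (reported also
as the proportion $k_C(Q)/|C|$). Draw $N$ random groups $R_1, \dots, R_N$,
each a uniform without-replacement sample of $s$ miRNAs, and report the
empirical p-value

$$ p_C \;=\; \frac{1}{N} \, \#\{\, i : k_C(R_i) > k_C(Q) \,\}. $$

Because every group in the null ensemble inherits the real catalogue's
correlation structure, the test is calibrated by construction. Its cost is
the problem: at the accuracy-grade setting of $N = 10^6$ and $s = 10$, the
pool alone requires $10^7$ set unions, and probing every annotated gene of
every tested category against every pool union runs into the billions of
membership tests.

## Bitsets, bit-probing, and the two engines

`mirset` indexes the gene universe once — every distinct gene in the
interaction table, assigned bit positions in sorted identifier order — and
represents every target set as a fixed-width bit vector:

* **Union** of a group's member sets is a fold of bitwise-or over 32-bit
  words; its cost depends only on the universe size, not on how many genes
  are set.
* **Overlap size** is obtained by *bit-probing*: for each gene annotated to
  the category, the corresponding bit of the group bitset is tested and a
  counter incremented. Annotation categories are small (tens of genes), so
  this touches exactly `category_size` bits per group and never
  materializes an intersection set. A popcount-of-bitwise-and
  implementation (`popcount_overlap()`) exists purely as a cross-check
  oracle.

The pool of $N$ union bitsets is materialized once, column-wise in a single
integer matrix, and shared read-only by all workers; parallelism is at the
category level, with categories split into contiguous chunks. Because all
sampling happens before the parallel section and the per-category pass is
deterministic, results are bit-identical for any worker count.

The second engine (`engine = "naive"`) implements the same contract with
R's native hashing: unions via `unique()` on concatenated identifier
vectors, overlap sizes via a single `%in%` hash-join pass per group over
the concatenated category genes — producing only sizes, never intersection
sets. It is a first-class run mode, not test scaffolding: for the same
seed the two engines must (and do) produce byte-identical output files,
so the equivalence claim is user-verifiable. The naive engine computes all
categories in one vectorized pass and therefore ignores `workers`; its
results are deterministic by construction.

Both engines tally the same two run-level operation counters, exposed in
the run report: `union_ops` (one fold step per member folded into an empty
accumulator, hence $N \times s$ for the pool plus $s$ for the query) and
`probe_ops` (one per category gene examined: every category once for the
query pass, tested categories $N$ times).

## Conventions and parameters

* **Strict comparison.** The p-value counts random groups with *strictly
  greater* overlap; `strict_greater = FALSE` switches to `>=`. Counting on
  the count scale equals counting on the proportion scale because $|C|$ is
  fixed within a category. With a discrete overlap distribution the strict
  convention makes $P(p < \alpha)$ land slightly *above* $\alpha$ (by up
  to the tie mass at the critical overlap value); the `>=` convention errs
  the other way. `plus_one_correction = TRUE` reports $(k+1)/(N+1)$, which
  avoids exact zeros.
* **Zero-overlap exclusion.** Categories sharing no gene with the query's
  targets cannot be enriched; they are excluded from testing *and* from
  FDR correction, and reported with overlap 0 and `NA` p-value — `NA` is
  more honest than an untested $p = 1$.
* **Universe membership.** Genes appearing only in the annotation file are
  excluded from the universe by default: they can never be targeted, so
  they affect no overlap count. Including them
  (`include_annotation_only_genes = TRUE`) only enlarges the reported
  `category_size` denominator; the pre-filter size is kept per category as
  `size_prefilter`. The reported `overlap_proportion` uses the post-filter
  size — the one denominator under which count- and proportion-comparisons
  coincide.
* **Sampling frame.** Random groups are drawn from *all* miRNAs in the
  interaction table, query members included; this is the procedure as
  usually stated. `exclude_query_from_sampling = TRUE` is available. A
  query equal to the full miRNA set is legal: every random group then
  equals the query, so every tested category gets $p = 0$ under the strict
  convention.
* **Iterations.** Default 10 000 so the default invocation is desk-fast;
  100 000 and 1 000 000 are the usual higher-accuracy settings. The
  p-value granularity is $1/N$, and output formatting uses seven decimals
  so $1/10^6$ survives a round trip.
* **FDR marking.** Benjamini–Hochberg step-up over the tested categories at
  $\alpha = 0.05$ (`*`) and $0.01$ (`**`), implemented via
  `stats::p.adjust(method = "BH")`; marks are nested, ties at the
  threshold rank share the mark, and $p = 0$ (possible under the strict
  convention) participates without special-casing — the plus-one estimator
  is the remedy for users who object.
* **Determinism.** One RNG stream, seeded from `run_config(seed=)`, drives
  all sampling; identifier ordering uses radix (C-locale) sort so bit
  assignment is independent of both input row order and the session
  locale.

## The synthetic generator

No real prediction catalogue ships with the package; every test and
experiment runs on synthetic data from `generate_scenario()`, which
emulates the statistical regime of real catalogues:

* **Target counts** per miRNA follow a log-normal law truncated to
  `[min_targets, max_targets]` — real catalogues are strongly right-skewed
  (mean well above median), with single miRNAs targeting from tens to
  thousands of genes. Defaults (median 300, range 10–4000 over 5000
  genes) are chosen to sit in that regime. Truncation is by rejection on
  the continuous scale, then rounding, so counts stay in bounds.
* **Target correlation** comes from a shared *hub pool*: a random
  `hub_fraction` (default 10%) of genes from which every miRNA draws
  `shared_pool_fraction` of its targets, the rest drawn uniformly from the
  remaining genes. At 0 the target sets are independent uniform draws; as
  the fraction grows, pairwise target overlap grows monotonically. This is
  the simplest device that reproduces the correlated-targeting premise
  that motivates the unbiased test.
* **Annotation structure.** By default category members are uniform draws
  from the gene pool. That is deliberately neutral — and it is *not*
  enough to make the hypergeometric test anti-conservative for a fixed
  category: with proportional hub content, the gene-level test is actually
  slightly conservative there. The documented real-data bias involves the
  annotation itself: well-annotated genes tend to be the frequently
  predicted targets. `category_hub_bias` encodes this by letting
  categories draw a fraction of their members from the hub pool; the bias
  demonstration below uses 0.3 (category hub share three times the genomic
  share, a moderate tilt).
* **Planting.** An optional planted category makes the query group a
  positive control: the generator samples the query miRNAs, then assigns
  the required `coverage_fraction` of the category's genes to them
  round-robin as extra interaction pairs, guaranteeing the requested
  coverage exactly. Infeasible requests (more query miRNAs than exist,
  etc.) fail at configuration time.
* **Truth.** Every draw (hub pool, per-miRNA target sets, category
  membership, planting) is returned in a `truth` record so tests can
  assert bookkeeping exactly, and `write_scenario()` emits byte-stable
  files for a fixed seed.

What passing tests on this generator do **not** show: fidelity to any
particular prediction algorithm's score distribution, to real miRNA
nomenclature, or to GO's DAG structure (annotations are used exactly as
given, with no term propagation — that is out of scope by design).

## What the verification battery computes

Problem sizes are chosen so the whole battery runs in minutes on one core.

* **Operation accounting.** With 10 000 pool groups of size 10 the union
  counter must equal exactly 100 000 — one bitwise-or fold per member —
  and the same $N \times s$ formula gives $10^7$ at the $10^6$-group
  setting. Probe counts must equal the category-size sums per contract.
* **Engine equivalence.** On 20 random scenarios (up to 200 miRNAs, 2000
  genes, 50 categories, $N = 2000$) the bitset and naive engines must
  agree on every `(exceed_count, p)` pair and produce byte-identical
  output files.
* **Exact enumeration.** With 6 miRNAs and group size 2, all 15 possible
  groups replace sampling and the p-value must equal the brute-force
  exceed fraction computed with plain sets — exactly, not approximately.
* **Probe/popcount identity** on 10 000 random pairs over a 1024-gene
  universe.
* **Null calibration.** 500 null queries (drawn by the run's own sampler)
  against one mid-size category (~150 genes; large enough that the overlap
  distribution is well spread and tie mass is small), each with its own
  pool of 2000: the fraction of $p < 0.05$ must fall inside the exact
  binomial 99% band around 0.05. Note the strict-convention discreteness
  effect above: the true rate sits near the upper half of that band.
* **Bias demonstration.** At `shared_pool_fraction = 0.6` and
  `category_hub_bias = 0.3`, random query groups trip the hypergeometric
  test at many times the rate of the empirical test (measured ratios are
  on the order of 10–30x, far above the 3x qualitative bar).
* **Determinism** across worker counts {1, 2, 4} and reruns, and **BH
  marking** against an independently coded step-up oracle on 1000 random
  p-vectors.

## Known limitations

* The Monte Carlo pool is sampled once per run and shared across
  categories. This makes p-values comparable under a common null sample
  and matches the shared-memory design, but p-values across categories
  are dependent; there is no sequential early-stopping or importance
  sampling.
* The smallest achievable nonzero p-value is $1/N$; at the default
  $N = 10^4$, FDR-corrected discoveries below $10^{-4}$ are
  indistinguishable from 0 (use more iterations or the plus-one
  estimator).
* Bitsets are uncompressed and rebuilt per run; for a human-scale
  catalogue (~20 000 genes, $10^6$ pool groups) the pool occupies roughly
  2.5 GB, which is within reach of contemporary machines but not of small
  containers. Compressed (roaring) bitsets and bitset persistence are
  non-goals.
* Annotation categories are taken verbatim; no identifier mapping between
  nomenclatures and no ontology-aware propagation.
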