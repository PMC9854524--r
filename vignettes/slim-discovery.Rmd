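---
title: "Methods: glocal SLiM scanning, conservation and enrichment profiling"
author: "slimscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glocal SLiM scanning, conservation and enrichment profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimscan)
```

# The problem

Short linear motifs (SLiMs) are 3–10-residue segments that mediate
transient protein interactions. Finding sequences similar to a given
SLiM in a protein database differs from ordinary homology search in two
ways: the query must be matched *in full* (a partial match of a 7-mer
is meaningless), while the target should contribute only the local
region that resembles it; and raw alignment scores of such short
queries need explicit significance calibration, because the usual
database-search statistics are tuned for much longer queries.
`slimscan` packages this analysis end to end for two alpha-fetoprotein
derived query peptides, `LDSYQCT` and `EMTPVNPGV`, and for arbitrary
short queries.

# Glocal alignment

## Model

`alignGlocal()` computes the optimum over all alignments that consume
the entire query against any contiguous substring of the target
("glocal": global in the query, local in the target — the semantics of
GLSEARCH). The recurrence is the standard three-state affine-gap
dynamic program (match state, gap-in-target, gap-in-query) with free
end gaps on the target only: row zero costs nothing at any target
position, and the optimum is read off the last query row at every
target position. A gap run of length $L$ costs
$\mathrm{open} + (L-1)\,\mathrm{extend}$ (FastA convention; defaults
$-10$ and $-2$), and substitution scores come from the canonical NCBI
BLOSUM50 table (via Biostrings), restricted to the 20 standard residues
plus `X`. The ambiguity codes B, Z, U, O are mapped to `X` on input and
score with the BLOSUM50 `X` row.

Numerical choices:

* **Traceback ties** prefer a residue pair, then a gap in the target,
  then a gap in the query; among equal-scoring endpoints the smallest
  target end coordinate wins. This makes the reported alignment (not
  just the score) deterministic.
* Alignments that *end* in gap-in-query columns are excluded from the
  final maximum: trailing target residues aligned to gaps are always
  dominated by shortening the local window, so this changes no score,
  only keeps tracebacks tidy.
* The DP core is compiled (Rcpp). An exhaustive enumeration oracle
  (`enumerateGlocalScore()`, plain recursive walk over every gapped
  alignment of the query against every target substring, no
  memoisation) ships in the package and anchors the test suite; it is
  exponential and refuses queries longer than 6.

## Identity degree

`identityDegree()` is the percentage of alignment columns where query
and target carry the same residue, with gap columns counted in the
denominator, rounded to one decimal. For gap-free alignments this is
$k/L$ — the convention under which the worked 7-mer and 9-mer
alignments (85.7 = 6/7, 77.8 = 7/9, 55.6 = 5/9, …) are reproduced
exactly. The denominator choice matters only for gapped alignments,
where including gap columns gives a defined, conservative value (gaps
dilute identity); the alternative (identical over ungapped columns
only) would let heavily gapped alignments report inflated identity.

# E-value calibration

FastA-style E-value regression is not reproducible outside FastA, so
`calibrateEvd()` fits an explicit empirical null: the query is aligned
against `nSamples` random sequences drawn from a residue composition
(uniform by default; a Swiss-Prot-like table is packaged), and the
score sample is fitted to a Gumbel distribution by the method of
moments,

$$\hat\beta = s\sqrt{6}/\pi, \qquad \hat\mu = \bar{x} - \gamma\hat\beta.$$

`eValue()` converts a score to the expected number of chance hits in a
database of $N$ sequences,
$E = N\,(1 - \exp(-\exp(-(s-\hat\mu)/\hat\beta)))$, clipped to
$[0, N]$. E is strictly decreasing in score and linear in $N$.

Defaults: 500 calibration sequences (the pipeline matches their length
to the mean database sequence length), seed-deterministic. The fit
requires at least 100 samples and rejects degenerate (zero-variance)
score samples. Two caveats are documented rather than hidden: the
method-of-moments fit is anchored by the bulk of the null distribution,
so far-tail E-values are extrapolations; and E-values printed by web
GLSEARCH against UniProtKB depend on that database's size and FastA's
internal regression — they are not comparable to, and not a target
for, this model.

# Search thresholds and deduplication

`scanDatabase()` keeps one best alignment per database record (matching
how one alignment per protein is reported in this kind of analysis),
then applies both cut-offs — E ≤ 0.1 and identity ≥ 57.1% for 7-mer
queries or 55.6% for 9-mers (the majority-of-columns rule
$\lceil L/2\rceil/L$, extended to other lengths) — sorts by ascending
E-value and truncates at 500 hits. All three values are exposed
(`searchThresholds()`).

`dedupMotifs()` collapses hits to unique motif *sequences* (the
ungapped target subsequence), first (best-E) occurrence winning, with
provenance aggregating every contributing accession. Deduplication at
the sequence level rather than the protein level is a deliberate
choice: the downstream conservation statistics count motifs, so the
unit of uniqueness must be the motif string. The operation is
idempotent.

# Conservation statistics

`positionFrequencies()` computes the $L \times 20$ percentage matrix
$N = a/b \times 100\%$ where $a$ counts a residue at a position and $b$
is the motif total. Motifs containing `X` are excluded (with a warning)
because `X` is not one of the 20 residues a logo or consensus can
display; $b$ counts only the motifs used.

`consensusNotation()` emits, per position, the major residue (argmax
frequency, ties broken alphabetically and logged) followed by bracketed
alternates: residues at or above the 5% threshold (inclusive), in
descending frequency. Descending-frequency ordering inside brackets is
our stated rule; observed notations for this motif family are mostly,
but not perfectly, consistent with it, and no grouping rules beyond the
single threshold are applied.

`logoColumns()` reports per-position information content
$IC = \log_2 20 - H - e_n$ (floored at 0) with
$H = -\sum f \log_2 f$ and the WebLogo-style small-sample correction
$e_n = 19/(2 b \ln 2)$, and symbol heights $f \cdot IC$. The correction
defaults ON for logo output (rendering parity with WebLogo) and is
never applied to the PFM/consensus path, whose defining formula has
none.

# Taxonomy and GO enrichment

`taxonProfile()` counts unique genes per taxonomic category over a
fixed 17-label vocabulary (bacteria, viruses, archaea; human, primates,
other mammals; birds, fishes, amphibia; reptiles, insects, nematodes;
higher plants, algae; yeast, fungi, other eukaryotes). A gene counts
once per category it appears in; orthologs in several categories count
in each (a gene present across many species is still one gene within a
category). Zero-count categories are kept so output columns are stable.

`enrichTerms()` tests every GO term carried by at least one study gene
(terms with $k = 0$ cannot be enriched and would only inflate the
number of tests): $p = P[X \ge k]$ with
$X \sim \mathrm{Hypergeom}(N_{bg}, K, n)$ via `stats::phyper`,
Benjamini–Hochberg adjustment via `stats::p.adjust`, fold enrichment
$(k/n)/(K/N_{bg})$, significance flag at FDR ≤ 0.2. The background
defaults to every gene in the annotation table. Annotations are flat:
no GO-DAG ancestor propagation is performed, so a term's count is
exactly the genes directly annotated with it. The g:SCS correction used
by one of the upstream web tools is out of scope; BH matches the other.

# The synthetic generator

`generateDatabase()` emulates the structure of a protein knowledgebase
at desk scale, not its content:

* **Sequences**: lengths $\sim N(300, 80^2)$ rounded and floored at 60,
  residues i.i.d. from the background composition (uniform $1/20$ by
  default; the packaged Swiss-Prot-like table is available). Real
  proteins have local composition structure and repeats; none of that
  is simulated, so passing recovery benchmarks here says nothing about
  low-complexity false positives in real databases.
* **Motifs**: one motif per planted protein (the scan keeps one best
  alignment per record, so multiplicity would be invisible), drawn from
  a `MotifProfile` with independent per-position categorical
  distributions, spliced over a uniform-random window (lengths are
  preserved). Position independence matches what position-marginal
  frequency analysis can see; real motifs may have positional
  covariance the PFM cannot represent either.
* **Packaged profiles** encode the observed conservation of the two
  motif families (`afpMotifProfile()`: invariant C at position 6, D at
  82.9% at position 2, and so on; `gipMotifProfile()` likewise for the
  9-mer). Stated major/alternate frequencies are used as given; the
  unstated residual mass is spread uniformly over the remaining
  residues, deliberately below the 5% consensus threshold so the
  packaged profiles reproduce the documented notations.
* **Benchmark profile** (`benchmarkProfile()`): recovery benchmarks
  need a guaranteed identity floor ("at most 2 of 7 residues
  substituted"), so variable positions split their mass between the
  query residue and one conservative substitute while all other
  positions are degenerate. Defaults vary the first and last query
  positions — for `LDSYQCT` these coincide with the least conserved
  positions of the observed profile — and substitute the
  highest-scoring BLOSUM50 partner (M for L, S for T), mirroring the
  physicochemically similar replacements seen in natural motif
  variants. Harsher substitutes would lower scores toward the
  significance boundary and the benchmark would measure the E-value
  model's tail rather than pipeline recovery.
* **Annotations**: taxon labels from a bacteria-dominated mixture
  (bacteria 60%, the rest spread over the remaining 16 categories),
  GO terms per protein as independent Bernoulli draws from the catalog;
  planted proteins receive each term with probability
  $\min(1, p_{bg} \cdot \mathrm{fold})$. The default catalog plants one
  term at fold 4.
* **Determinism**: everything is drawn under the config seed with the
  RNG state restored afterwards; equal seeds give byte-identical
  FASTA/TSV artifacts. The truth table records planted flags, motif
  sequences and 1-based insertion positions, and the per-term
  configured fold.

# Pipeline and reproducibility

`runPipeline()` chains calibration → scan → dedup → PFM → consensus →
logo → taxonomy → enrichment in fixed order, writes eight artifacts
(TSVs, text files, `manifest.json`), logs per-stage timings to stderr,
and aborts with the stage name on any failure. One master seed drives
the only stochastic stage (calibration). Floats in TSVs are rendered at
6 significant digits, coordinates are 1-based inclusive, and the
manifest records every parameter, so a rerun with an identical config
is byte-identical.

# Problem sizes used in the test suite

The suite exercises the DP-vs-enumeration oracle on 1000+ random
instances (query ≤ 4, target ≤ 7, two gap regimes), the hypergeometric
oracle by explicit subset enumeration up to background size 25,
parameter recovery on 199-motif draws (the documented benchmark draw of
the packaged AFP profile), and end-to-end recovery on 200-protein
simulated databases with 500-sequence calibration — sizes at which the
whole suite runs in well under a minute while every code path is
exercised. Scaling `nProteins` and `nSamples` up changes runtimes, not
code paths.

# Known limitations

* E-values are empirical-fit extrapolations; do not compare them to
  E-values printed by other tools or databases of other sizes.
* No heuristic seeding or banding: the scan is exact DP per record,
  appropriate for desk-scale databases (thousands of records), not for
  full UniProtKB.
* Flat GO annotation counting; no term-ancestor propagation, no live
  ontology.
* No ID mapping to external gene identifier spaces; annotations are
  taken as supplied.
* The generator does not attempt realistic taxonomy abundances or GO
  DAG structure — it provides controlled truth, not realism.
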