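# slimscan

Short linear motifs (SLiMs) are 3–10-residue protein segments that act
through transient interactions and are hard to find precisely because
they are short: a 7-mer query match is rarely distinguishable from
chance without careful alignment semantics and significance
calibration. `slimscan` implements a complete desk-scale SLiM-discovery
pipeline for protein databases, built around two query peptides derived
from human alpha-fetoprotein that ship as packaged defaults — the 7-mer
`LDSYQCT` (AFP_14–20) and the 9-mer `EMTPVNPGV` (GIP-9) — but usable
with any short peptide query.

The pipeline is aimed at computational biologists who want a
reproducible, scriptable alternative to chaining web tools (GLSEARCH,
WebLogo, ShinyGO) for this class of analysis.

## What it computes

**Glocal alignment.** Each database record is aligned with
global-in-query, local-in-target ("glocal") dynamic programming: every
query residue is consumed, the target contributes its best contiguous
substring, and gaps cost `gapOpen + (L-1) * gapExtend` per run
(BLOSUM50, gap open −10, gap extension −2 by default). The *identity
degree* of an alignment is

    identity = 100 × (identical columns) / (alignment columns)

so gap columns dilute identity.

**E-values.** Per-sequence significance comes from an empirical
extreme-value model: query scores against shuffled-composition random
sequences are fitted to a Gumbel distribution by the method of moments
(β = s·√6/π, μ = x̄ − γβ) and

    E(s) = N · (1 − exp(−exp(−(s − μ)/β)))

for a database of N sequences. Hits must pass E ≤ 0.1 and an identity
cut-off of 57.1% (7-mer queries) or 55.6% (9-mers); up to 500
alignments are retained.

**Conservation.** Unique motifs (deduplicated by sequence, best E-value
first) are summarised as a position frequency matrix N = a/b × 100%,
a consensus notation with bracketed ≥5% alternates (e.g.
`L[MIV]D[NE]S[TKE]Y[F]Q[KDR]CT[S]`), and per-position sequence-logo
information content `IC = log2(20) − H` with optional small-sample
correction.

**Profiling.** Hit sets are profiled by taxonomic category (unique
genes per category over a fixed 17-label vocabulary) and by GO-term
enrichment: hypergeometric upper-tail p-values, Benjamini–Hochberg FDR,
and fold enrichment (k/n)/(K/N_bg), flagged at FDR ≤ 0.2.

**Synthetic benchmarks.** A generator plants profile-drawn motifs into
simulated databases with taxon labels and GO annotations carrying a
configurable planted enrichment, and records an exact truth table, so
precision/recall of the whole pipeline can be measured.

## Worked example

```r
library(slimscan)

# a simulated database: 300 proteins, 15% carrying a planted variant of
# the 7-mer query (identity >= 71.4% by profile construction)
cfg <- syntheticConfig(nProteins = 300, plantingRate = 0.15,
                       profile = benchmarkProfile("LDSYQCT"), seed = 42)
sim <- generateDatabase(cfg)

evd  <- calibrateEvd("LDSYQCT", lengths = 300L, nSamples = 500L, seed = 43)
hits <- scanDatabase("LDSYQCT", sim$sequences, evd = evd,
                     annotations = sim$annotations)
nrow(hits)
#> [1] 48

planted <- sim$truth$accession[sim$truth$planted]
c(precision = mean(hits$accession %in% planted),
  recall    = mean(planted %in% hits$accession))
#> precision    recall
#>         1         1

ms <- dedupMotifs(hits)
ms
#> MotifSet for query LDSYQCT with 4 unique motifs
#>   head: LDSYQCT MDSYQCT LDSYQCS MDSYQCS
consensusNotation(positionFrequencies(ms))$notation
#> [1] "L[M]DSYQCS[T]"

enr <- enrichTerms(unique(hits$gene_symbol), annotations = sim$annotations)
head(enr, 3)
#>        term namespace  k  n  K N_bg fold_enrichment p_value    fdr significant
#>  GO:0016491        MF 10 48 26  300            2.40 0.00317 0.0348        TRUE
#>  GO:0005515        MF 10 48 37  300            1.69 0.04887 0.2688       FALSE
#>  GO:0009055        MF  3 48 12  300            1.56 0.29752 0.6545       FALSE
```

All 48 planted proteins are recovered with no false positives; the
deduplicated motif set contains the four variant sequences the
benchmark profile can emit; and the GO term planted at fold 4
(`GO:0016491`) is the only term called significant at FDR ≤ 0.2.

Single alignments work directly:

```r
aln <- alignGlocal("LDSYQCT", "MDSYQCT")
aln
#> GlocalAlignment (query global / target local)
#>   query : LDSYQCT
#>   target: MDSYQCT  [1-7]
#>   score: 49  identity: 85.7%
```

`runPipeline(pipelineConfig(...))` chains all stages and writes
`hits.tsv`, `motifs.txt`, `pfm.tsv`, `consensus.txt`, `logo.tsv`,
`taxonomy.tsv`, `enrich.tsv` and `manifest.json` into an output
directory; reruns with the same configuration are byte-identical. A
thin command-line wrapper with `simulate`, `search`, `conserve`,
`enrich` and `run` subcommands is installed at
`inst/scripts/slimscan.R`.

## See also

The methods vignette (`vignettes/slim-discovery.Rmd`) documents the
model, its assumptions, every tunable parameter, the synthetic
generator's design and the package's known limitations.
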