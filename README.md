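# polyglue

Targeted functional profiling of shotgun metagenomic reads for the genes
behind bacterial **exopolysaccharide (EPS)** and **lipopolysaccharide
(LPS)** production — the polymers that glue soil particles into stable
aggregates. The package is written for soil microbiologists and
metagenomicists who want to quantify a community's *potential* to produce
aggregate-stabilizing agents and test how it responds to management
(tillage intensity) and depth in a strip-split-plot field design
(2 tillage regimes × 3 depth layers × 3 plot replicates).

## The method

A read is counted toward a target gene only when two orthogonal filters
agree:

1. **Profile-HMM domain filter.** Reads are quality-trimmed (terminal
   Phred ≥ 15, length ≥ 50 bp), all six-frame ORFs (≥ 20 aa, stop-free)
   are predicted, and ORFs are scored against position-specific profile
   models of the function-specific conserved domains with a local Viterbi
   kernel. A read passes at `E ≤ 1e-5` (Gumbel calibration, model-scan
   convention).
2. **Translated alignment + top-25 consistency.** Passing reads are
   aligned against a curated KEGG-Orthology reference of 14 EPS/LPS genes
   (*wza, algE, algJ, wcaB, wcaF, wcaK/amsJ, kpsE, epsG, epsA, sacB, wzt,
   lptF, lptG, lptC*) with a seeded banded Smith–Waterman (BLOSUM62, gap
   open 11 / extend 1, Karlin–Altschul E-values). A KO is assigned only
   when **all** of the top 25 hits (lowest E, `E ≤ 0.01`) carry it.

Reads are simultaneously binned taxonomically by a lowest-common-ancestor
rule (MinScore = 50 bits, MaxExpected = 0.01, TopPercent = 10,
MinSupport = 1) and aggregated at family rank. Downstream statistics:
relative abundances in percent of total filtered reads
(`100·count/total`), dominance filters (families > 0.5 %, genes >
0.005 %), Shannon–Wiener diversity, Bray–Curtis NMDS, 2-of-3-replicate
core membership, and per-feature tillage × depth split-plot F tests with
Benjamini–Hochberg correction and the depth contrasts 0–20 vs 20–50 cm
and 0–10 vs 10–20 cm.

Because no raw field data ship with the package, a synthetic
mock-metagenome generator with exact read-level truth (family-structured
communities, depth-shifted guilds, decoy paralogs, Phred-calibrated
substitution errors) provides end-to-end validation; see the methods
vignette (`vignettes/eps-lps-profiling.Rmd`) for the model and its limits.

## A worked example

```r
library(polyglue)
demo <- runDemo(seed = 7, nReads = 2000)
demo$recovery$spearman
#> [1] 1
head(demo$pipeline$summary[, c("sample", "total_filtered",
                               "reads_ko_assigned", "pct_target_genes")], 3)
#>       sample total_filtered reads_ko_assigned pct_target_genes
#> 1 CT_0-10_P1           2000               170             8.50
#> 2 CT_0-10_P2           2000               178             8.90
#> 3 CT_0-10_P3           2000               181             9.05
demo$tables$dominantFamilies[1:4]
#> [1] "Acidobacteriaceae" "Anaerolineaceae"   "Bradyrhizobiaceae"
#> [4] "Chitinophagaceae"
```

`spearman = 1` says the per-gene read counts recovered by the pipeline
rank exactly as planted; `pct_target_genes` is each sample's share of
filtered reads assigned to the 14 target genes (the synthetic study
plants them far denser than a real soil library, where this figure lives
in the hundredths of a percent); dominant families are those whose mean
relative abundance exceeds 0.5 %. With `outDir =` the run writes every
table (QC, KO calls, taxonomy calls, counts, family × gene matrix, core
sets, truth) plus a run-manifest JSON of all parameters and seeds.

A thin CLI with `simulate` / `run` / `demo` subcommands is included at
`inst/scripts/polyglue.R`.

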