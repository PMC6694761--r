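# bltseq

Quantitative analysis of **barcoded libraries of targets (BLT)** — an *in
vitro* sequencing assay that measures the absolute cleavage efficiency of a
Cas9 ribonucleoprotein across hundreds of thousands of randomly mismatched
target sites at once. The package is aimed at nuclease specificity groups
who want to analyze (or simulate and power-check) BLT-style experiments:
it takes single-end FASTQ reads of the barcoded amplicon library through
UMI-level deduplication to per-target cut/uncut counts, and from there to
guide-level specificity metrics and predictive models.

## What it computes

For each target $i$ with cleaved count $C_i$ out of $O_i$ deduplicated
observations, the efficiency normalized to the pooled perfect-match
(on-target) class:

$$\eta_i = \frac{C_i}{O_i}\cdot\frac{O_{\mathrm{on}}}{C_{\mathrm{on}}}$$

From the class means $\bar\eta(N)$ over mismatch counts $N$, the
guide-intrinsic mismatch permissiveness score (high = promiscuous guide):

$$\mathrm{GIMP} = \frac{\sum_{N=j}^{k} \bar\eta(N)}{k-j},\qquad j=1,\ k=4$$

And from a bead pull-down of Cas9-bound molecules, the probability of
cleavage given binding:

$$P_{\mathrm{cut}} = \frac{\text{cleaved bound observations}}
                          {\text{total bound observations}}$$

Around these, the package provides:

* **`synth`** — a full generative simulator (degenerate library, planted
  multiplicative cleavage truth, EcoRV/Cas9 junction chemistry, probe
  ligation, PCR duplication, quality scores, FASTQ output) with exact
  ground-truth tables, so every stage is testable offline;
* **read processing** — anchor-based parsing/demultiplexing, a mean-Q20
  filter over the constant regions, UMI-tuple collapsing, and
  three-uncut-observation target validation with naive spike-in support;
* **quantification** — per-replicate η, replicate averaging,
  reproducibility R², positional/base/epistasis aggregations, GIMP;
* **pull-down analysis** — per-target and per-class P_cut with
  occlusion-risk flagging;
* **modeling** — binary 4×L mismatch encodings (1×84 flat strings for a
  21-nt guide) feeding a 10-neuron single-hidden-layer regression with a
  70/15/15 split and validation-selected quasi-Newton fit;
* **genome scanning** — enumeration of all candidate off-target sites
  within a mismatch budget next to an IUPAC PAM (default `NNGRRT`),
  model scoring, percentile ranking, and cross-genome comparison.

## Worked example

```r
library(bltseq)

g <- guide_spec("VEGFA_like", "GGTGAGTGAGTGTGTGCGTGT")
#> <blt_guide> VEGFA_like: GGTGAGTGAGTGTGTGCGTGT-TTGAAT (L=21, cut 3 bp 5' of PAM)

## simulate a library under a seed-gradient truth model and tabulate it
truth <- cleavage_truth(g, on_target_prob = 0.9)
rec <- simulate_target_records(g, truth, library_params(n_templates = 2000),
                               copies = 80, seed = 101)
eta <- compute_eta(rec, g)

aggregate_by_mismatch(eta, g)$by_count
#>     n_mm mean_eta n_targets
#>  1:    0    1.000       228
#>  2:    1    0.489       526
#>  3:    2    0.245       572
#>  4:    3    0.124       393
#>  5:    4    0.054       188
#>  ...

gimp_score(eta)
#> GIMP = 0.3038 (N = 1..4, mode = literal)
```

The mismatch-count table shows the expected monotone decay of cleavage as
mismatches accumulate (the `n_mm = 0` class is exactly 1 by
construction), and the GIMP score integrates classes 1–4 into a single
promiscuity number: ~0.30 for this moderately specific simulated guide
(empirical guides span roughly 0.08 for a highly specific 19-mer to 0.6
for a promiscuous one).

Cleavage-given-binding from a pull-down's observation counts:

```r
v <- pcut_from_counts(62587, 353065)   # uncleaved / total bound on-targets
#> P_cut = 0.823 (17.7% of bound on-targets uncleaved)
```

A complete FASTQ-level run (simulate → process → quantify → model) is one
call, or one shell command:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "bltseq"),
             out_dir = "demo_run", seed = 42)
```

```sh
Rscript scripts/blt.R --config inst/extdata/demo_config.yaml \
        --out demo_run --seed 42
```

Outputs are plain TSV/JSON per stage (observations, target records, η
tables, GIMP, model weights, ranked sites) plus a provenance block
(config hash + seed); a fixed seed reproduces every file byte for byte.

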