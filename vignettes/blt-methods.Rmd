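---
title: "Measuring Cas9 cleavage efficiency with barcoded libraries of targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Cas9 cleavage efficiency with barcoded libraries of targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bltseq)
library(data.table)
```

## The assay this package models

A barcoded library of targets (BLT) is a synthetic DNA library built around
one guide RNA: every molecule carries a degenerate copy of the guide's
target site (each base mutated independently with 10% probability to a
uniformly chosen non-wild-type base), a constant PAM, and a random template
UMI (`UMI_T`) that uniquely tags the molecule's target sequence. The
library is bottlenecked to a known number of unique templates (500,000 by
default here) and amplified, so each `UMI_T` exists as many physical
copies.

The library is digested with a Cas9 ribonucleoprotein and then with EcoRV.
Cas9 cleaves a target with a sequence-dependent probability, leaving a
blunt end 3 bp 5′ of the PAM; EcoRV linearizes everything Cas9 left
uncut at a constant site (`GAT|ATC`) 5′ of the target. Both cleavage
states therefore expose a ligatable blunt end, and a sequencing probe
(stagger, two anchor sequences flanking a sample barcode, a probe UMI
`UMI_P`) is ligated to whichever end is available. Because the EcoRV end
and the Cas9 end sit at different distances from the PAM, cut- and
uncut-derived reads differ in their junction sequence: uncut reads carry
the EcoRV remnant plus the **full** target; cut reads retain only the 3
PAM-proximal target bases, and the target identity of a cut molecule is
recoverable only through its `UMI_T`. With the default construct the two
insert forms differ by a fixed 25 bp.

Counting deduplicated cut and uncut observations per `UMI_T` yields an
*absolute* per-target cleavage efficiency — both cleavage states are
observed, unlike enrichment- or depletion-based library assays.

## From reads to efficiencies

Read processing follows a fixed contract:

1. **Parse/demultiplex.** The stagger length is inferred by sliding the
   pair of barcode-flanking anchors over the allowed 1–8 bp offsets
   (requiring both anchors makes a chance match in the random stagger
   bases negligible, ~4^-12). Reads are assigned to samples by exact
   barcode match; cut/uncut status comes from the junction context, not
   read length, so the classification is immune to the stagger.
   Unassignable reads are dropped with reason codes and the counts always
   conserve: reads in = parsed + dropped.
2. **Quality filter.** The mean Phred score is computed over the extracted
   constant regions only (`UMI_P`, PAM, `UMI_T`); reads with a mean below
   Q20 are discarded, a read at exactly Q20 is kept. Filtering on the
   constants rather than the whole read keeps long and short read forms
   comparable.
3. **Collapse.** PCR duplicates are removed by collapsing to unique
   (barcode, `UMI_T`, `UMI_P`, status, stagger) tuples — "observations".
   Collapsing is idempotent.
4. **Validate.** A `UMI_T` is trusted only when at least three unique
   uncut observations support a consensus target sequence (strict
   majority; ties are discarded as UMI collisions). Fully cleaved targets
   can never validate on their own, so an undigested naive spike-in
   library may contribute observations toward validation — but not toward
   cut-fraction denominators, because spike-in molecules never saw Cas9.
   A flag (`include_spikein_counts`) exposes the alternative convention.

UMIs are matched exactly; no error correction is attempted. Sequencing
errors inside a UMI therefore surface as unsupported singleton
observations, which the validation threshold removes.

## Efficiency, GIMP, and cleavage-given-binding

For target $i$ with cleaved count $C_i$ out of $O_i$ observations, the
normalized efficiency is

$$\eta_i = \frac{C_i}{O_i}\cdot\frac{O_\mathrm{on}}{C_\mathrm{on}},$$

where the on-target sums pool every validated perfect-match `UMI_T` in
the same replicate. The on-target class has $\eta = 1$ by construction;
mismatched targets may exceed 1 and are deliberately not clipped —
clipping would bias every downstream average. Normalization happens
within each replicate, and per-replicate values are then averaged
unweighted (targets missing from a replicate are averaged over the
replicates where they appear, with the count reported).

The guide-intrinsic mismatch permissiveness score integrates the mean
efficiency $\bar\eta(N)$ over mismatch counts $N$:

$$\mathrm{GIMP} = \frac{\sum_{N=j}^{k}\bar\eta(N)}{k-j},
\qquad j = 1,\ k = 4 .$$

The defining formula is ambiguous about whether the sum is inclusive of
$k$ given the $k-j$ denominator. We implement it **literally** (inclusive
sum, denominator $k-j$), so a constant $\bar\eta = c$ gives $4c/3$; the
plausible alternative — the mean over the four classes — is available as
`gimp_score(mode = "mean")` but is not the default. Because $\eta$ is
normalized to the on-target efficiency, GIMP is invariant to uniform
scaling of absolute cleavage probabilities (e.g. nuclease dose), which the
tests verify on simulated data.

A bead pull-down of Cas9-bound molecules separates binding from cleavage:
within the bound fraction, the probability of cleavage given binding is

$$P_\mathrm{cut} = \frac{\text{cleaved bound observations}}
                        {\text{total bound observations}},$$

computed per target or per mismatch-count class, always alongside the
whole-reaction cut fraction. One published worked-example count pair is
printed with the numerator larger than the denominator; since the
accompanying percentages make the intended orientation unambiguous,
`pcut_from_counts()` swaps such transposed pairs with a loud warning
rather than reporting an impossible fraction. Reported $P_\mathrm{cut}$
"observations" are collapsed observation tuples, the same currency as the
efficiency estimates.

## The synthetic-data generator

Every analysis stage is testable without external data because the
package generates complete experiments with known ground truth:

* **Library**: independent 10% per-base degeneracy; random `UMI_T`
  (12 nt by default, making collisions rare at $5\times10^5$ templates —
  collisions are allowed and handled by the consensus rule downstream).
* **Cleavage truth**: multiplicative — an on-target probability times a
  per-position penalty for each mismatch, with optional per-base
  penalties and pairwise epistasis multipliers, all clamped to $[0,1]$.
  The default position profile is a seed gradient (penalty 0.05 adjacent
  to the PAM rising linearly to 0.95 at the distal end), mirroring the
  canonical seed-region behavior. Positions are numbered PAM-proximally
  (position 1 next to the PAM) everywhere in the package.
* **Pull-down**: binding and cleavage-given-binding are separate
  channels; a molecule is cut only if bound and then cut
  (single-encounter model), so the whole-reaction probability factorizes
  as binding × $P_\mathrm{cut}$. Multi-encounter kinetics and occlusion
  are not simulated; occlusion risk is only *flagged* downstream, as
  targets whose bound-fraction efficiency matches the whole reaction.
* **Sequencing**: one ligation event per molecule (random stagger and
  `UMI_P`), $1+\mathrm{Poisson}$ PCR duplicates, per-base substitution
  errors, and two quality regimes (most reads ~Q36, a small fraction
  ~Q12, error bases ~Q15) so the Q20 filter has real work to do. Exact
  instrument error profiles are out of scope. A fixed seed yields
  byte-identical FASTQ.

What the generator does **not** emulate — chromatin context, indels
(excluded from the assay's scope by design), UMI-specific error hotspots,
amplification bias beyond a duplication count — bounds what passing tests
show: they demonstrate that the estimators recover the truth of this
generative model, not that the model captures every artifact of real
sequencing.

With exact UMI matching, a `UMI_P` collision inside one template's
molecules merges two events into one observation; the simulator therefore
reports its ligation event table, and oracle tests compare collapsed
observations against distinct event tuples, which is exact.

## The guide-specific model

Mismatches are encoded as a binary $4\times L$ matrix — rows are the
observed **target** base (A, C, G, T), columns are positions 1..L — and
flattened row-major to a $1\times4L$ vector (84 entries for a 21-nt
guide). Whether the defining convention intended the target base or the
guide base at a mismatch is ambiguous; we chose the target base and
record the convention in every model's metadata so encodings are never
mixed.

A single-hidden-layer network (10 sigmoid units, linear output) maps the
encoding to $\eta$. Data are split 70/15/15 into train/validation/test; a
small grid of weight decays ($10^{-4}$, $10^{-2}$) and iteration budgets
(150, 400) is fit with a full-batch BFGS quasi-Newton optimizer
(`nnet`), the candidate with the best validation $R^2$ is kept, and the
untouched test split provides the reported $R^2$ (squared Pearson). The
original protocol's Levenberg–Marquardt optimizer is not available in
mainstream R toolkits; any full-batch second-order/quasi-Newton method
converging to a validation plateau fits the model class, and the choice
is recorded in the metadata. Training is bit-reproducible given the seed.
Guides of length 19 simply give width-76 encodings; models are per-guide,
so widths never mix and incompatible widths raise an error.

## Genome scanning

Candidate off-targets are every position, on either strand, whose
adjacent PAM matches an IUPAC pattern (`NNGRRT` by default) and whose
protospacer is within a mismatch budget (default 6) of the spacer. PAM
bases are a hard constraint and are **not** counted against the budget —
the library that trains the model holds the PAM constant, so the model
knows nothing about PAM variants. Coordinates are 0-based half-open
(BED convention); reverse-strand sites are reported in protospacer
orientation; double hits are deduplicated by (sequence, start, strand);
windows containing non-ACGT bases are skipped and counted. Ranking by
predicted efficiency breaks ties by (score, coordinate) so output is
deterministic, and cross-genome comparisons are keyed by protospacer
sequence, the only key that survives a change of coordinate system.

## Numerical and scale choices

Simulated problem sizes in the test-suite and in `scripts/acceptance.R`
were chosen as the smallest that leave the statistical checks comfortably
powered: 100,000 templates for library composition statistics (binomial
moments, $\chi^2$ at $\alpha = 0.01$), 10,000 molecules for the exact
pipeline-vs-truth oracle, 400 templates × ≥100 observations for
efficiency recovery (r ≥ 0.95), 2,000 templates × 50 copies for
$P_\mathrm{cut}$ recovery within 3 binomial SE, 3,000 templates per guide
for GIMP ordering, and 5,000 targets for model training (held-out
$R^2 \ge 0.8$). Degenerate inputs degrade loudly but gracefully: zero
cleaved on-target observations make $\eta$ undefined (error), an empty
mismatch class makes GIMP undefined (error naming the class), an empty
bound class yields `NA` rather than an exception, and a constant
training response returns a constant model with a warning.

## Known limitations

* Exact UMI and barcode matching (no mismatch tolerance): sequencing
  errors inflate unsupported singleton observations; mitigated by the
  Q20 filter and the three-observation validation rule.
* The multiplicative truth model is a stand-in for unknown biochemistry;
  parameter-recovery results certify the estimators, not the biology.
* Occlusion and multi-encounter kinetics are flagged, not modeled.
* PAM-variant off-targets are out of scope by design.
* Published genome-wide off-target counts depend on reference builds and
  exact PAM rules and are not reproduced here.
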