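---
title: "Methods: chain-elongation bioenergetics, regulon scanning and transcriptome summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chain-elongation bioenergetics, regulon scanning and transcriptome summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caproscope)
```

This vignette is the package's account of the models it implements: what is
assumed, which constants matter, where design choices were genuinely open,
and what the synthetic-data tests do and do not demonstrate.

## 1. Exact stoichiometric balancing

A fermentation specification fixes the measured coefficients (reducing
substrate, acetate, caproate, butyrate) and leaves H+, H2O, CO2 and H2
free. Conservation of each element plus total charge gives a linear system
with the free coefficients as unknowns; with the four free species above
the system is square (C, H, O, charge) and uniquely solvable whenever the
fixed species contain carbon.

Coefficients are exact rationals end to end (a small vectorized
numerator/denominator class with gcd reduction; Gauss–Jordan elimination
with exact pivoting). Floats enter only in thermodynamics. Two numerical
guards matter:

* Doubles are converted by continued-fraction expansion, so `1/3` becomes
  the exact fraction 1/3 rather than a 10^9-denominator approximation.
* Noisy measured spectra are snapped to a common decimal denominator
  (default 10^6, i.e. six decimals) before solving. Heterogeneous large
  denominators would otherwise push exact intermediates past 2^53; with a
  common denominator and small-integer element counts the elimination stays
  comfortably representable. An overflow guard fails loudly if a user
  supplies pathological rationals.

Degenerate inputs: duplicate compound ids in a stoichiometry sum (and
cancel — zero coefficients are never stored); an inconsistent or singular
system raises an "unbalanceable" error naming the offending conservation
row; unknown ids are registry errors.

## 2. Transformed reaction energies

`delta_r_g_prime()` sums coefficient-weighted transformed standard
formation energies and divides by the absolute basis coefficient. The
packaged table (`inst/extdata/formation_energies.tsv`, versioned and
swappable) holds ΔfG′° at pH 7.0, ionic strength 0.25 M, 298.15 K for the
ten species of the two caproate fermentations, in the convention that
makes a plain weighted sum correct:

* species are fixed at their pH-7 dominant protonation state (acetate⁻,
  caproate⁻, lactate⁻, …), with protons balanced explicitly via an `H+`
  entry carrying the pH-7 activity term RT ln(10⁻⁷) ≈ −39.96 kJ/mol;
* CO2 and H2 are the aqueous species, which is what an aqueous-phase
  calculator uses (using the gas-phase values instead shifts the glucose
  equation by ~34 kJ/mol — the choice is load-bearing and deliberate).

Uncertainty is the root-sum-square of coefficient-weighted per-compound
standard errors, divided by the basis coefficient. Covariances between the
compound estimates are not available, so this underestimates nothing in
particular but is only an approximation of a full error model; it is
reported, never used as a decision criterion. No pH/ionic-strength
transforms beyond the fixed condition are attempted, and energies are
tabulated, not estimated from group contributions.

The result is invariant to rescaling the whole reaction before
normalization, and reversal negates it exactly — both are tested.

## 3. The cofactor ledger

The ledger turns a product spectrum into mole-for-mole cofactor flows.
Substrate oxidation, per mole:

| substrate | acetyl-CoA | NADH | Fd²⁻ | ATP (SLP) |
|-----------|-----------:|-----:|-----:|----------:|
| glucose   | 2 | 2 | 2 | 2 |
| lactate   | 1 | 2 | 0 | 0 |
| pyruvate  | 1 | 0 | 1 | 0 |

Glucose enters by PTS: the PEP spent on uptake replaces the hexokinase ATP,
leaving the classical net 2 ATP of glycolysis, and pyruvate:ferredoxin
oxidoreductase (Pfor) reduces 2 Fd²⁻. Lactate is oxidized by the
electron-confurcating Ldh/EtfAB complex, which consumes one Fd²⁻ that Pfor
immediately restores — hence net zero ferredoxin and 2 NADH. "Reducing-
equivalent pairs" is implemented as NADH + Fd²⁻ per mole (4, 2, 1 for
glucose, lactate, pyruvate); the source phrasing ("NADH provided") is loose
and this definition is stated openly.

Each reverse β-oxidation cycle (thiolase, Hbd, Crt, bifurcating Bcd/EtfAB)
consumes one acetyl-CoA and 3 NADH and regenerates 1 Fd²⁻; caproate costs
two cycles from its acetate primer, butyrate one, so
`steps = 2·caproate + butyrate`. Acetate consumed enters via CoA
transferase at zero ATP cost; net acetate produced earns 1 ATP by Ack-Pta.

Chemiosmosis closes the ledger. Defaults:

* **Rnf: 2 H+ translocated per Fd²⁻ oxidized** (`rnf_protons_per_2e = 2`).
  This is the unique small-integer stoichiometry that, with the ATPase
  below and all Fd²⁻ routed through Rnf, reproduces both measured yields
  (3.75 ATP per glucose and ≈0.72 per two lactate) simultaneously. It is a
  calibration, exposed as configuration.
* **V-type ATPase: exactly 4 H+ per ATP** (`atpase_protons_per_atp = 4`),
  the value adopted for this organism from the *T. thermophilus* enzyme.
* **H2 is vented from the NADH surplus** after Rnf routing, at 1 NADH : 1
  H2. Net bookkeeping cannot distinguish the physical carrier of the
  hydrogenase; venting from NADH (rather than directly from Fd²⁻) is the
  only routing that simultaneously closes the NADH ledger and reproduces
  the H2 coefficients of both balanced equations (6 per 6 glucose, 12 per
  21 lactate) — an internal cross-check the test suite enforces. The
  alternative routing is available as `hydrogenase_donor = "fd"`.

With these defaults the glucose ledger closes at 2 + 7/4 = 15/4 ATP and
the lactate ledger at 15/2 ATP per 21 lactate = 5/7 per glucose-equivalent.
`redox_feasibility()` reports the NADH deficit of an over-ambitious
spectrum and the maximal elongation the redox budget supports, discharging
the remaining acetyl-CoA as acetate — which is why pyruvate, carrying a
quarter of glucose's reducing power, yields acetate rather than caproate.

Out of scope by design: kinetics, growth yield, flux-balance objectives,
and the partitioning of the proton motive force between ΔΨ and ΔpH.

## 4. Motif scanning

The only motif information available is a degenerate IUPAC seed (Rex
`TTGTTAANNNNTTAACAA`, LldR `TGGTNNNACCA`), so the PWM is built from the
consensus alone: the k allowed bases at a position share `1 − (4 − k)·ε`
equally and each disallowed base receives ε (default 10⁻⁴); log-odds are
log2 against a uniform background (configurable GC). N columns are exactly
neutral; any mismatch at an informative position strictly lowers the score.

**Threshold semantics.** The scan threshold is a fraction of the min–max
score range: a window is reported when
`(score − min) / (max − min) ≥ threshold` (the `matchPWM` "percentage"
convention). With a sharply informative PWM (ε = 10⁻⁴ costs ~13 bits per
mismatch) a threshold on the raw maximum would reject single-mismatch
sites outright, contradicting the intended tolerance of roughly "a few
mismatches"; range normalization makes the default 0.7 admit up to four
mismatches on the 18-mer seed, which is the regime in which known
functional sites (1–3 mismatches from the seed) are recovered. Absolute
FIMO scores and p-values are *not* reproduced — only score orderings are
meaningful here, and the tests assert exactly that (a 1-mismatch site
outscores a 3-mismatch site).

The Rex seed is its own reverse complement, so every true site would be
reported twice; palindromic motifs are therefore scanned on the plus
strand only (minus-strand scores are provably identical), and
strand-symmetry for non-palindromic motifs is property-tested. Offsets are
reported relative to the downstream gene's translation start, negative
upstream (the 5′-UTR convention); when genes flank an interval on both
strands the nearer start codon is used.

Intergenic extraction keeps the maximal CDS-free regions with their
downstream gene on each strand; coordinates are 0-based half-open
internally and converted only at format boundaries (GFF3 in/out is
1-based inclusive).

## 5. Transcriptome summaries

* TPM: `(c/l) / Σ(c/l) · 10⁶`; columns sum to one million by construction.
* Differential filter: strict inequalities exactly as published —
  |log2FC| > 1 *and* padj < 0.05. Boundary genes (log2FC = 1, padj = 0.05)
  are excluded; this matters for reproducing counts and is tested.
* COG enrichment: upper-tail hypergeometric `P(X ≥ k)` per category, no
  multiple-testing correction (matching the single-level asterisk
  convention at 0.05/0.01); `bh = TRUE` adds Benjamini–Hochberg for reuse.
  "Containing more than five genes" is implemented as K > `min_genes` on
  the tested gene universe (the detected-gene table), the more
  conservative reading of an ambiguous criterion.
* `transcript_fraction()` is ΣTPM/10⁶·100; a partition of all genes sums
  to 100%.
* 2^−ΔΔCT with the control sample at exactly 1, and Pearson concordance of
  RNA-seq vs qPCR log2 fold changes.

No differential model is fitted: the pipeline consumes a precomputed table
(log2FC, padj), because the filtering, enrichment and fraction statistics
downstream of the fitted model are the procedure of interest here.

## 6. Synthetic data: what it emulates and what it does not

All generators are deterministic under a fixed seed (R's default
integer-state RNG) and emit machine-readable truth.

**Genomes** (`gen_genome_with_sites`): i.i.d. background of configurable GC
around tiled CDS features, with consensus instances planted in intergenic
gaps — degenerate positions filled uniformly, then up to
⌈mutation_rate·L⌉ substitutions to disallowed bases, so the truth mismatch
count is exact. Background windows within a Hamming radius (default 4,
matching the default scan threshold's mismatch tolerance) of the consensus
are rejection-sampled away on both strands, so every scan hit must overlap
a planted site *by construction* and recovery tests can assert precision 1.
Not emulated: operon structure, codon usage, GC skew, repeats — so planted
-site recall says nothing about false-positive rates on real genomes,
where background is not rejection-sampled.

**Expression** (`gen_expression_dataset`): log-normal baselines (median
~200 counts), negative-binomial counts (default dispersion 0.02, i.e.
clean biological replicates), planted log2 effects of ±Uniform(1.5, 5) —
strong, clearly detectable effects, chosen to test recovery of the filter
rather than the power frontier. The emitted padj comes from a pooled
two-sample binomial count test with BH correction, documented as a simple
stand-in for a DESeq2-style model: the pipeline treats the columns as
given either way. Dispersion, replicate count and effect sizes are
configurable; with the defaults the filter's sensitivity on planted genes
exceeds 0.9 and null datasets produce well under 5% false calls (both
property-tested over seeds).

**Fermentation spectra** (`gen_fermentation_measurements`): truth ± species
-wise Gaussian noise truncated at zero, with the two published equations as
built-in truths. Note that the solved H2 coefficient is the small
difference of large terms (`H2 = 6·lactate + 4·acetate − 16·caproate −
10·butyrate` for the lactate equation), so relative measurement noise is
strongly amplified: 5% noise on 3-replicate means propagates to an sd of
~4.9 around the true 12. The tests assert exactness at zero noise,
truncation, and unbiasedness with the analytically propagated spread —
not a tight recovery that error propagation forbids.

**Problem sizes.** The test suite exercises the balancer on 300 random
spectra, motif recovery on 20 genomes × 50 planted sites (1,000 sites),
strand symmetry and deduplication on 100 random sequences, enrichment
against an exhaustive enumeration oracle for every parameterization with
N ≤ 25, and differential recovery over 100 simulated datasets of 500 genes
— sizes chosen so the full suite runs in well under a minute per module
while still estimating the stochastic properties stably.

## 7. Known limitations

* The formation-energy table covers the ten packaged species; other
  compounds must be supplied with their own ΔfG′° (the registry TSV is the
  extension point). Uncertainties combine without covariances.
* The ledger is steady-state bookkeeping: it cannot distinguish carrier
  assignments with identical net stoichiometry, and its two chemiosmotic
  constants are calibrations, not measurements.
* PWM scores are consensus-derived; without an alignment of verified sites
  the absolute score scale (and hence any p-value) is not meaningful.
* The expression generator's binomial test is anti-conservative under
  strong overdispersion; at the default dispersion this is immaterial, but
  padj columns from the generator should not be treated as a calibrated
  differential analysis for real data.
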