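# caproscope

Tools for analysing anaerobic chain-elongation fermentations of the kind
carried out by *Caproicibacterium lactatifermentans*, a lactate-utilizing
caproate producer. The package answers a concrete physiological question —
why does the same organism grow so much better on glucose than on lactate,
and how is lactate utilization wired transcriptionally? — with four
computational pieces:

1. **Exact fermentation-equation balancing.** Measured substrate and product
   moles (glucose or lactate, acetate, caproate, butyrate) fix part of a
   stoichiometric equation; the coefficients of H+, H2O, CO2 and H2 are
   solved from one conservation equation per element plus one for charge.
   All arithmetic is exact rational, so balanced means exactly balanced.
2. **Transformed reaction Gibbs energies.** ΔrG′° of a balanced equation at
   pH 7.0, I = 0.25 M, 298.15 K from a packaged formation-energy table
   (ΔfG′° per species, aqueous CO2/H2, explicit pH-7 proton), normalized
   per mole of a basis compound: ΔrG′° = Σᵢ νᵢ ΔfG′°ᵢ / |ν_basis|.
3. **A cofactor-ledger model of chain-elongation bioenergetics.** Substrate
   oxidation (glycolysis/PTS + Pfor for glucose; the electron-confurcating
   Ldh/EtfAB + Pfor for lactate) and reverse β-oxidation (3 NADH in, 1
   reduced ferredoxin out per C2 elongation cycle) are tallied per mole.
   All Fd²⁻ passes the Rnf complex (2 H+ translocated per Fd²⁻, 1 NADH
   out); the NADH surplus is vented as H2; a V-type ATPase makes one ATP
   per 4 H+. The ledger closes exactly and yields
   ATP_total = ATP_SLP + H+_translocated / 4.
4. **Regulon and transcriptome summaries.** IUPAC consensus → position
   weight matrix scanning of intergenic regions for Rex/LldR binding sites
   (both strands, palindrome-aware, offsets relative to the downstream
   start codon), TPM normalization, strict differential-expression
   filtering (|log2FC| > 1, padj < 0.05), upper-tail hypergeometric COG
   enrichment, transcript fractions and 2^−ΔΔCT qPCR normalization.

Deterministic synthetic-data generators (genomes with planted motifs,
negative-binomial expression tables with planted differential genes, noisy
fermentation spectra) provide ground truth for every stage, so the whole
pipeline is testable offline.

## Worked example

Balance the glucose fermentation from its measured coefficients, compute
its reaction energy, and run the bioenergetic ledger:

```r
library(caproscope)

eq1 <- balance_fermentation(
  c(glucose = -6, acetate = -2, caproate = 4, butyrate = 1),
  free = c("H+", "H2O", "CO2", "H2"), basis = "glucose")
eq1
#> 6 glucose + 2 acetate -> 4 caproate + butyrate + 3 H+ + 6 H2O + 12 CO2 + 6 H2
#> basis: glucose

delta_r_g_prime(eq1)
#> deltaG'0 = -254.0 +- 2.9 kJ per mol glucose

led <- run_ledger(spectrum_from_equation(eq1))
led
#> cofactor ledger (per mole glucose):
#>   ATP (substrate-level): 2.00
#>   ATP (chemiosmotic):    1.75
#>   ATP total:             3.75
#>   NADH produced/consumed: 5.50 / 5.50
#>   Fd2- through Rnf:      3.50
#>   H+ translocated:       7.00
#>   H2 vented:             1.00

free_energy_per_atp(delta_r_g_prime(eq1)$drg_prime,
                    as.numeric(led$atp_total))
#> [1] 67.73022
```

Reading: fermenting glucose to caproate releases about 254 kJ per mole of
glucose; the reconstructed pathway conserves 3.75 mol ATP of it (2 by
substrate-level phosphorylation, 1.75 chemiosmotically via Rnf + ATPase),
i.e. roughly 68 kJ dissipated per ATP. Running the same ledger on the
lactate equation (`fermentation_equation("eq2")`, normalized per two moles
of lactate — one glucose-equivalent) gives 5/7 ≈ 0.71 ATP, about a fifth of
the glucose yield, which is the bioenergetic reason lactate supports much
weaker growth.

For motif scanning:

```r
g  <- gen_genome_with_sites(seed = 42, n_sites = 5)
iv <- extract_intergenic(g$features, g$genome, min_length = 18)
hits <- scan_sequences("TTGTTAANNNNTTAACAA", iv, threshold = 0.7)
site_report(hits)
```

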