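# bindspec

Information-theoretic and thermodynamic analysis of transcription-factor
binding specificity in R.

`bindspec` is for researchers who measure how a DNA-binding protein — or a
panel of its mutants — distributes binding affinity over sequence space,
and who want the standard information-theoretic readouts of those
measurements. It takes two kinds of input:

* **relative association constants** (Ka) for one protein variant against
  an enumerated site library (e.g. all 64 trinucleotide variants of a
  binding-site core, as produced by microfluidic affinity platforms), and
* **pooled Sanger chromatogram peak heights** from an in vivo
  binding-site selection competition.

and computes, from either or both:

| quantity | function |
|---|---|
| binding free energies ΔG = −RT ln Ka, relative ΔΔG | `free_energy_from_association()`, `relative_binding_energies()` |
| single-mutant energy matrices (consensus anchored at 0) | `energy_matrix_from_single_mutants()` |
| energy logos via Boltzmann conversion f(b,l) ∝ e^(−β·ΔΔG(b,l)) | `boltzmann_frequencies()`, `logo_table()` |
| information content R_seq = Σ\[log₂k − H(l) − e(n)\], with exact small-sample correction | `information_content()`, `small_sample_correction()` |
| individual information site scores Ri = Σ Riw(b,l) | `ri_weights()`, `score_sites()` |
| the specific/non-specific boundary and non-specific binding energy ΔG_ns, from paired OLS fits of ΔΔG on Ri | `specificity_boundary()` |
| symmetrised Kullback–Leibler divergence between motif models (bits, column-averaged) | `matrix_kld()`, `pairwise_kld()` |
| selection logos from chromatogram peaks | `frequencies_from_peaks()`, `selection_logo()` |
| cross-variant site overlap and expression–affinity correlation | `overlap_quadrants()`, `expression_affinity_correlation()` |
| additivity/independence diagnostics | `additive_prediction()`, `additivity_report()` |
| a seeded synthetic generator (additive energy truth, two-state non-specific floor, log-normal Ka noise, Boltzmann selection) | `synthetic_truth()`, `simulate_mitomi()`, `simulate_selection()` |

`run_pipeline()` composes all of it over a multi-variant study and writes
TSV reports with a manifest. The reference system wired into the shipped
data tables is the *E. coli* AraC-family activator MarA and four helix-3
variants (named by residues 42-45-46; wild type = WQR), measured over the
64 trinucleotide variants of the *mar* site core at positions −2..0.

## The model in brief

Specific binding is modelled as independent and additive per position:
ΔΔG(s) = Σ_l ΔΔG(s_l, l). Measured association constants follow a
two-state sum, Ka(s) ∝ e^(−ΔΔG(s)/RT) + e^(−ΔG_ns/RT): once a site is
degenerate enough, its measured energy saturates at the non-specific
floor. Sites are scored by individual information
Riw(b,l) = log₂k + log₂ f(b,l) − e(n); sites with Ri < 0 bits are
predicted to be bound non-specifically. Plotting measured ΔΔG against Ri
separates a sloped specific branch from a flat non-specific branch, and
ΔG_ns is read off where the two regression lines meet (or, optionally,
where the specific line crosses Ri = 0). The methods vignette
(`vignettes/binding-specificity.Rmd`) derives the estimator's intrinsic
RT·ln2 plateau allowance and documents every convention switch.

## Worked example

```r
library(bindspec)

em <- energy_matrix(rbind(c(2.0, 3.5, 0.0, 1.2),
                          c(2.8, 0.0, 1.5, 3.0),
                          c(0.0, 2.2, 3.8, 1.0)), positions = -2:0)
tr <- synthetic_truth(truth_matrix = em, dg_ns_true = 4,
                      noise_sigma = 0.05, seed = 42)
bt <- simulate_mitomi(tr, variant_id = "demo")
a <- analyze_binding(bt)
a
#> Variant demo: consensus GCA, Rseq = 0.30 bits, dGns = 3.09 kJ/mol (intersection)
summary(a$boundary)
#> dGns = 3.087 kJ/mol (intersection)
#> specific:     n = 25, slope = -1.485, r2 = 0.948
#> non-specific: n = 39, slope = -0.566, r2 = 0.830
score_sites(a$ri_model, c("GCA", "TCA", "AAT"))
#>   GCA   TCA   AAT
#>  1.87  1.48 -0.45
```

Read: the fitted boundary puts the non-specific floor 3.09 kJ/mol above
the consensus (the generating truth was 4; noise-free, the estimator
measures the two-state plateau, so agreement within RT·ln2 ≈ 1.7 kJ/mol
is the expected behaviour, and here the noisy estimate is well inside
it). The specific branch slope ≈ −1.5 kJ/mol per bit is close to the
theoretical −RT·ln2 = −1.70 for an additive model, and the three scored
sites rank GCA > TCA > AAT, the last predicted non-specific (Ri < 0).
The soft truth matrix (penalties of a few kJ/mol at 295 K) gives a
diffuse 0.30-bit energy logo — sharp published-style logos correspond to
a larger Boltzmann scale β, which is an explicit argument of
`boltzmann_frequencies()`.

`plot(a$boundary)` draws the two-branch regression; `logo_table()`
exports letter heights for logo rendering.

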