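---
title: "Quantifying transcription-factor binding specificity from affinity and selection data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription-factor binding specificity from affinity and selection data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindspec)
```

## The problem

A DNA-binding protein is characterised by the distribution of its
binding free energies over sequence space. Two summaries of that
distribution matter biologically: how much *information* the protein's
preferred sites carry (how sharply it can single out its targets in a
genome), and how large the energetic gap is between its specific sites
and the *non-specific floor* at which all sufficiently degenerate
sequences are bound equally weakly. bindspec computes both, starting
from either of the two kinds of data such experiments produce:

* **relative association constants** (Ka) measured for one protein
  variant against an enumerated site library, e.g. all 64 trinucleotide
  variants of a binding-site core (microfluidic affinity assays such as
  MITOMI produce exactly this), and
* **pooled selection chromatograms**: a single Sanger read through the
  randomised positions of a site library after an in vivo survival
  competition, where relative peak heights track the surviving
  population's base frequencies.

The worked system behind the package's reference tables is the
*E. coli* AraC-family activator MarA and four helix-3 variants of it,
each named by its residues at positions 42-45-46 (wild type = WQR),
measured against the 64 variants of the three core positions of the
*mar* binding site. Those core positions are labelled −2, −1, 0
throughout.

## From affinities to an energy model

For each variant, `free_energy_from_association()` converts Ka to
$\Delta G = -RT\,\ln K_a$ with $R = 8.314\times10^{-3}$ kJ/(mol·K) and
$T = 295$ K by default (the temperature of the measurements the
package was designed around; every object carries its own temperature,
so nothing is hard-wired). Since Ka is relative, only differences are
meaningful: `relative_binding_energies()` anchors the strongest site at
zero and reports $\Delta\Delta G(s) = \Delta G(s) - \Delta G(s^*)
\ge 0$.

One sign convention deserves emphasis: we define ddG so that **weaker
binders are positive**. The quantity "dGns" below is then the height of
the non-specific plateau *above* the strongest site, a positive number
for any specific binder.

`energy_matrix_from_single_mutants()` reads the per-position penalty
matrix directly off the consensus and its $3L$ single mutants. If a
"single mutant" outranks the nominated consensus (which happens —
one of the reference variants, RQR, binds TCC more tightly than the
site it was selected on), the affected columns are re-anchored with a
warning rather than silently producing negative penalties.

The energy matrix is rendered as a logo via `boltzmann_frequencies()`:
$f(b,l) \propto e^{-\beta\,\Delta\Delta G(b,l)}$ with the
thermodynamic $\beta = 1/RT$ by default. This mapping is monotone in
sharpness — scaling all penalties up can only increase the logo's
information — which is one of the package's property tests. Energy-logo
tools are not unanimous about the scale applied to matrix values before
exponentiating (some treat the entries as unitless), so $\beta$ is an
explicit argument: logos produced under another unit convention can be
matched by calibrating $\beta$ once against a reference logo and
holding it fixed thereafter.

## Information content and the small-sample correction

`information_content()` computes per-position
$R_{seq}(l) = \log_2 k - H(l) - e(n)$ and its total over a position
range. The correction $e(n)$ removes the upward bias of information
estimated from $n$ sites. We compute it **exactly** for $n \le 12$
from the multinomial sampling distribution — the entropy's expectation
decomposes over Binomial marginals, so the exact value is available
even for the 20-letter amino-acid alphabet, where literal enumeration
of outcomes is impossible — and use the standard asymptotic
$(k-1)/(2n\ln 2)$ above. The returned sampling standard deviation
(exact from Binomial/trinomial moments up to $n = 1000$, chi-square
limit beyond) is what "± x bits" totals are built from.

The correction is applied automatically only where a site count
exists. Energy- and chromatogram-derived matrices have no meaningful
$n$; their information is reported uncorrected, which is why a fully
conserved position in an energy logo can reach the full 2 bits.

## Individual information (Ri)

`ri_weights()` converts frequencies to the per-position weights
$Riw(b,l) = \log_2 k + \log_2 f(b,l) - e(n)$; `score_sites()` sums
them. The consensus attains the model maximum, a uniform model scores
everything 0, and sites with $R_i < 0$ bits are predicted to be bound
non-specifically. With `pseudocount = 0` a structurally absent symbol
would be $-\infty$; we substitute −50 bits, which keeps arithmetic
finite while remaining far below any achievable score, so orderings
are unaffected. For count-derived matrices the Laplace-style default
pseudocount $0.5/k$ in `frequency_matrix_from_sites()` avoids such
zeros in the first place.

## The specificity boundary and dGns

`specificity_boundary()` is the package's fitted model. Sites are
partitioned at $R_i = 0$ (ties count as specific, the conventional
"$R_i \ge 0$" rule), a plain OLS line of ddG on Ri is fitted to each
side, and dGns is derived from the pair of lines. Two derivations are
offered because the verbal description of "the intercept of the
positive and negative site regression lines" is genuinely ambiguous:

* `"intersection"` (default): the ddG value at the crossing point of
  the two lines;
* `"ri0-intercept"`: the specific line evaluated at $R_i = 0$.

When the two lines are numerically parallel, the intersection method
falls back to the intercept method with a warning. The fit is flagged
unreliable when the specific branch has fewer than 4 points or
$r^2 < 0.3$ — a nearly non-specific binder (such as the SAR reference
variant) gives no trustworthy boundary, and downstream reports carry
that flag.

Why this estimator recovers the floor: under a two-state model the
measured association constant is
$K_a(s) \propto e^{-\Delta\Delta G_{true}(s)/RT} + e^{-\Delta
G_{ns}/RT}$, so measured energies of weak sites saturate at
$\Delta G_{ns} + RT\ln(1 + e^{-\Delta G_{ns}/RT})$ — within
$RT\ln 2 \approx 1.7$ kJ/mol of the true floor — while specific sites
fall on a line of slope $-RT\ln 2$ per bit against Ri. The
intersection of the two branches therefore sits at the plateau. This
also bounds the accuracy of the estimator itself: even noise-free, the
estimate measures the plateau, not the floor parameter directly, which
is why the synthetic recovery tolerance for dGns is $RT\ln 2$ while
noise-induced *bias* (noisy replicates versus the noise-free estimate
of the same truth) is held to 0.2 kJ/mol.

## Comparing motif models

`column_kld()` implements the symmetrised, base-2 divergence
$\tfrac12[D(p\|q) + D(q\|p)]$ after pseudocount regularisation
($10^{-6}$ by default), and `matrix_kld()` averages it over aligned
columns — this column-averaged symmetrised form, in bits, is the
convention under which the package reports all divergences. Offset
search (`allow_shift`) exists but is off by default, since matrices
produced by this pipeline share the −2..0 frame. `pairwise_kld()`
builds the full symmetric table.

## Selection chromatograms

`frequencies_from_peaks()` divides each base's peak height by the
summed heights at that position; fixed (unrandomised) positions become
probability-1 columns, and `selection_logo()` can leave them blank in
the rendered logo, as is conventional. Peak height tracks population
frequency only semi-quantitatively — neighbouring bases bias peak
intensities — so chromatogram-derived matrices carry a
`semi_quantitative` flag and no site count (hence no small-sample
correction, and Ri models built from them are interpreted
comparatively, not absolutely). The coordinate frame follows the
selection construct: two fixed bases (T, G) 5′ of the −2..0 core
shared with the affinity assay, and two additional randomised
positions 3′ of it.

## The synthetic generator

Because the full wet-lab inputs are external data, every stage is
exercised against `synthetic_truth()`, whose defaults are fixed once
to resemble the reference system: a 3-position additive truth with
Gamma-distributed penalties of mean 2.5 and s.d. 1 kJ/mol (single
mutants mostly cheaper than the floor, multiple mutants mostly
saturated — the regime in which the boundary regression is
meaningful), a non-specific floor 4 kJ/mol above the consensus
(within the 2.4–4.5 kJ/mol range of the reference variants), and 10%
log-normal Ka noise. `simulate_mitomi()` applies the two-state sum
above; `simulate_selection()` keeps sites with
$\Delta\Delta G_{true} \le$ stringency and populates survivors by
Boltzmann weight, so at infinite stringency the selection logo equals
the truth's Boltzmann logo in closed form — an exact end-to-end check.
Neighbour bias on peaks is available (a multiplicative factor indexed
by the preceding position's majority base) but off by default, since
only the existence of the bias, not its form, is established.

What the generator deliberately does not model: growth kinetics,
plasmid copy number, induction dynamics, position-dependent
measurement error, or sequence context outside the enumerated core.
Passing synthetic tests therefore demonstrates correctness of the
estimators under the stated generative assumptions, not robustness to
every artefact of real data.

## Numerical choices and degenerate inputs

* Ties for the strongest site break lexicographically (warned).
* Probabilities must sum to 1 within $10^{-9}$; energy-matrix columns
  must be anchored at 0 within the same tolerance.
* All-zero peak columns, ragged site lists, symbols outside the
  alphabet, non-positive Ka, and degenerate (zero-variance) regressions
  are errors, each naming the offending position, site or row.
* OLS fits go through `stats::lm`; correlations through `stats::cor`;
  $r^2$ is squared Pearson correlation of raw scores (matching the
  linear-fit presentation of the analyses this package reproduces),
  defined as 0 with a warning when a variance is 0.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: 64-site libraries, 100-replicate noise studies, 1000-pair
divergence property checks, and Monte-Carlo oracles of $2\times10^5$
draws for the small-sample correction. These sizes were chosen so the
statistical assertions have comfortable margins while the whole suite
runs in seconds.

## A worked example

```{r example}
tr <- synthetic_truth(seed = 42, dg_ns_true = 4, noise_sigma = 0.05)
bt <- simulate_mitomi(tr, variant_id = "demo")
a <- analyze_binding(bt)
a
summary(a$boundary)
information_content(a$frequencies, apply_correction = FALSE)$total
```

The same composition over several variants, plus pairwise divergences,
quadrant overlaps and TSV reports, is `run_pipeline()` over a
`pipeline_config()`.
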