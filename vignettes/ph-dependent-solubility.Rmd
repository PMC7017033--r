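---
title: "Modelling pH-dependent solubility of disordered proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pH-dependent solubility of disordered proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pHsol)
```

## The model and its assumptions

Intrinsically disordered proteins lack a folded core, so their aggregation
behaviour is encoded directly in the sequence. Two sequence properties
titrate with solution pH and dominate pH-dependent aggregation: the
fractional net charge of the chain and the lipophilicity of its ionizable
side chains. `pHsol` combines them in a bivariate polynomial,

$$S(p) = \alpha\,L(p) + \beta\,|Q(p)|^2 + \gamma\,|Q(p)| + \delta ,$$

which can be read as a Taylor expansion of an unknown solubility surface,
truncated at second order in net charge and first order in lipophilicity.
The quadratic charge term ($\beta < 0$) captures saturation: each further
unit of net charge solubilizes a little less. The shipped coefficients
($\alpha = -97.82$, $\beta = -0.00747$, $\gamma = 0.8770$, $\delta =
38.24$) come from a non-linear least-squares parameterization on a
charge-engineered model IDP; their units — and hence the score's — are
those of that training data. Solubility is therefore *relative*: the
inverse of aggregation propensity under the given conditions, not a
thermodynamic concentration. Only score differences and correlations with
experimental series are meaningful, which is also why the validation
statistics ($R^2$, $p$) are invariant under affine rescaling of the score.

Key assumptions worth keeping in mind:

* the chain is disordered, so residues titrate with model-compound pKa
  values (no structure-induced pKa shifts);
* charge is treated as a global property of the chain; its spatial
  distribution (charge patterning) is ignored;
* temperature, ionic strength and cosolutes are outside the model.

## Net charge and isoelectric point

The fractional net charge is the Henderson–Hasselbalch sum

$$Q(p) = \sum_{\text{bases}} \frac{1}{1+10^{\,p-pK_a}}
       - \sum_{\text{acids}} \frac{1}{1+10^{\,pK_a-p}}$$

over D, E, C, Y, K, R, H and the free termini. Histidine is always
treated as ionizable: its pKa (~6) lies inside every biologically
interesting pH window. Free cysteines titrate as weak acids by default;
`exclude_cys = TRUE` models disulfide-paired constructs. Terminal blocking
(acetylation/amidation) is carried on the `protein` object and removes the
corresponding terminal group — this matters for short peptides, where a
free C-terminal carboxyl can move the pI by more than a unit.

$Q$ is strictly decreasing in pH whenever at least one ionizable group is
present, so the isoelectric point is the unique root of $Q$; it is found
by bisection on $[0.1, 13.9]$ to $|Q| \le 10^{-4}$ (at most 60 halvings).
Sequences with only acidic or only basic groups have no root and raise a
documented error.

Two pKa sets are built in. The default, `"expasy"`, is a
Bjellqvist/ExPASy-style set; `"calculator"` carries the values popularized
by a widely used protein-charge server. With the default set and
unmodified constructs (free termini, titratable Cys), the computed pIs of
three classic amyloidogenic IDPs match conventionally reported values to
two decimals:

```{r}
seqs <- read_fasta(system.file("extdata", "reference_idps.fasta",
                               package = "pHsol"))
round(sapply(seqs, isoelectric_point), 2)
```

The IAPP entry deserves a note: the *physiological* mature peptide is
C-terminally amidated and disulfide-bonded, which would push its computed
pI above 9.5. The reported value of 8.90 corresponds to the unmodified
37-mer treated as a plain calculator input, and that is the construct
stored in `inst/extdata/` (documented in its FASTA header). Computed pI
values are pKa-set dependent; switching among common published sets moves
them by roughly ±0.1–0.3.

## pH-dependent lipophilicity

Each amino acid carries two species-level lipophilicity values, neutral
and charged, and the value at pH $p$ is the population-weighted mixture

$$l(p) = f_n(p)\, l_{\text{neutral}} + (1 - f_n(p))\, l_{\text{charged}},$$

with $f_n$ from the Henderson–Hasselbalch equation. This reproduces the
sigmoid lipophilicity transition of every ionizable residue, centred at
its pKa, with the two species values as asymptotes; at $p = pK_a$ the
value is their arithmetic mean.

The shipped default scale (`"octanol-hh"`) is a constructed table:
neutral-species values in the spirit of octanol/water side-chain
partition scales, with charged-species penalties of roughly 0.7–3 log
units depending on the group. It satisfies the structural invariant
$l_{\text{charged}} \le l_{\text{neutral}}$ for every ionizable residue —
ionization never increases lipophilicity — but its absolute numbers are a
documented default, not a measured consensus. Any published two-species
scale can be dropped in via `read_lipophilicity_scale()`; whether such a
scale should use side-chain or whole-residue values is a genuinely open
choice, and the package is agnostic: the table is data. The per-residue
values are taken as terminus-independent.

### Profiles and the window rule

The per-residue values are averaged over a sliding window and the mean is
assigned to the window's centre residue. The window size follows the
protein length — 5 residues below 75 aa, 7 up to 174, 9 up to 299, 11
from 300 — with the boundaries resolved as half-open intervals (75 gets
7, 175 gets 9, 300 gets 11) in a single rule function, `window_size()`.
Only full windows are scored: a length-$L$ chain yields $L - w + 1$
profile points and the global lipophilicity is the unweighted mean of
those points. Scoring partial terminal windows would require inventing
boundary values and would bias short-peptide averages, so it is not done;
this choice slightly discounts terminal residues in the global mean.

The per-residue *solubility* profile (`residue_solubility_profile()`)
applies the polynomial to each window lipophilicity while keeping the
whole-chain $|Q|$ in the charge terms — charge is global and is
deliberately not localized. It is a region-ranking heuristic: because the
polynomial is linear in $L$, the profile mean equals the whole-protein
score, and the ranking of regions is unaffected by the shared charge
offset.

## Fitting and validation

Although the fitting route is a non-linear least-squares solver
(Levenberg–Marquardt via `minpack.lm`, started from the shipped
coefficients, tolerance $10^{-10}$ on relative parameter and cost change),
the polynomial is *linear* in $(\alpha, \beta, \gamma, \delta)$: when the
design matrix $[L, |Q|^2, |Q|, 1]$ has full column rank the optimum is
unique and initialization-independent. The test suite exploits this by
checking the solver against the closed-form linear solution; the package
itself checks the rank before fitting and names the collinear columns on
failure.

`validate_predictions()` regresses an experimental pH series on the
predicted scores by ordinary least squares and reports slope, intercept,
$R^2$, the two-tailed $p$-value of the slope from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, and the standard
95% confidence-band parameters. The orientation flag of an
`experimental_series` (whether larger values mean more aggregation, as
for an elongation rate constant, or more solubility) sets the *expected*
slope sign, which is reported but never enforced.

## The synthetic-data generator

`simulate_charge_variant_experiment()` emulates the experiment that
motivates the model: take a disordered wild-type chain, build an acidic
variant (every K/R becomes E) and a basic variant (every D/E becomes K)
without touching any other position, "measure" solubility at a grid of pH
values, and re-fit the polynomial. Defaults, chosen once to mirror the
magnitudes of such charge-engineering experiments on a ~230-residue model
IDP: chain length 230; 26% of positions charged with a 60% acidic excess
(so the acidic variant carries ~60 acids and the variant pIs bracket the
wild type's); 10 pH points spanning 2–12; additive homoscedastic Gaussian
noise with $\sigma$ = 2% of the noiseless score range (the simplest
defensible error model for a plate-based solubility readout); true
coefficients equal to the shipped ones. One integer seed fixes the
sequence and the noise. Histidines are left unflipped by default — they
are only weakly basic — with `flip_his = TRUE` available to build fully
acidic, His-free constructs.

What the generator does *not* emulate: real measured solubilities (no
published training values are included), heteroscedastic or correlated
measurement error, compositional biases of any particular protein family,
and charge patterning along the chain (positions are random). Passing
tests therefore demonstrate the internal consistency and statistical
behaviour of the pipeline, not predictive accuracy on laboratory data —
that is what `validate_predictions()` against user-supplied series is for.

### Identifiability of the coefficients

A charge-variant design identifies $\alpha$ and $\delta$ well, but
$|Q|^2$ and $|Q|$ are strongly collinear over the attainable charge range
(all observations lie on three pH-parameterized curves), so $\beta$ — and
to a lesser degree $\gamma$ — carries a large relative standard error at
this noise level: with 3 variants × 10 pH points and 2%-of-range noise,
the reported relative SE on $\beta$ is typically near 15% and no choice
of pH grid in (2, 12) changes that materially. Accurate recovery of
$\beta$ (say, to a few percent) would need either much larger charge
ranges than a ~230-residue chain can reach or substantially lower noise.
The test suite treats this honestly: unit tests assert tight recovery of
$\alpha$ and $\delta$ and statistical consistency (within reported
standard errors) for all four coefficients, and the strict 5%-recovery
check on all four parameters is expected to fail for $\beta$ under these
study conditions. The same caveat applies to any re-parameterization from
real charge-variant data: report the standard errors, not just the point
estimates.

## Numerical choices and degenerate inputs

* pH arguments are validated to the open interval (0, 14); sweeps default
  to a 2–12 grid.
* pI bisection: interval $[0.1, 13.9]$, charge tolerance $10^{-4}$,
  ≤ 60 iterations; the full-precision root is returned and conventionally
  rounded to 2 decimals for display.
* Window sizes must be odd and ≥ 3; sequences shorter than their window
  are rejected rather than padded.
* Ambiguity codes: rejected by default; an opt-in maps `X` to the scale
  average (`allow_x = TRUE`). B/Z/J/U/O are always rejected — silent
  guesses corrupt profiles.
* Rolling means use a cumulative-sum formulation; agreement with naive
  window enumeration is tested to $10^{-12}$.
* The fit refuses rank-deficient designs (e.g. a charge-free dataset,
  where $|Q|^2$, $|Q|$ and the intercept collapse) and fewer than 5
  observations.

Problem sizes used by the test suite — sequences of 40–300 residues,
200-replicate Monte-Carlo recovery runs at $n = 100$, 100-sequence oracle
sweeps — were chosen so the whole suite exercises every contract at
statistically meaningful sizes while remaining quick to run on a laptop.

## Known limitations

* Globular proteins are out of scope: folded structure shifts pKa values
  and buries hydrophobic surface, which a sequence-only model cannot see.
* The default lipophilicity scale is a constructed stand-in; conclusions
  that depend on its absolute numbers (rather than on charge) should be
  re-checked with a measured scale.
* Charge patterning, multimerization, ionic strength and temperature are
  not modelled.
* The per-residue solubility profile shares the global charge term across
  positions; it ranks regions, it does not assign them independent
  solubilities.
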