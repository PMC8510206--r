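---
title: "Methods: virtual screening of anticancer peptides and MTT dose-response analysis"
author: "pepscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual screening of anticancer peptides and MTT dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

## The problem

Anticancer peptides (ACPs) are short (roughly 5-50 residue) peptides that
suppress tumour-cell proliferation, typically by disrupting the negatively
charged cancer-cell membrane. A practical discovery route is biomimetic: take
a food or medicinal organism's proteome, digest it in silico with a gastric
protease (pepsin), and screen the resulting peptidome with machine-learning
ACP predictors before synthesizing and testing a handful of candidates in a
viability assay. `pepscreen` implements that whole loop as tested,
reproducible code: digestion, physicochemical profiling, consensus
screening with mode-of-action stratification, substitution-based redesign,
and MTT dose-response analysis, plus seeded generators that stand in for the
external pieces (the proteome, the predictor servers, the wet-lab plates).

The package deliberately does **not** reimplement the third-party predictors
(AntiCP-, iACP-, MLACP-, ToxinPred-, MLCPP-style models). They are trained
services; the pipeline treats their outputs as a pluggable score table, which
also keeps every run reproducible offline.

## In silico pepsin digestion

Pepsin specificity is broad and context-dependent; published digest tools
reduce it to preference tables. `pepscreen` uses a transparent two-part
grammar: a set of P1 residues whose C-terminal bond is cut, and a set of P1'
residues that veto the cut when they sit immediately after the bond. The
defaults are the classic simplification

* `pepsin_pH1.3`: cut after Phe or Leu, blocked by a following Pro;
* `pepsin_pH2`: additionally cut after Trp and Tyr.

Full P4-P2' context tables are out of scope, but any rule expressible in the
grammar can be supplied from YAML (`load_cleavage_rules()`), so the choice is
user-overridable rather than baked in. Missed cleavages default to 0; with
`missed_cleavages = k` every concatenation of up to `k + 1` adjacent
fragments is also emitted, and with `c` internal cut sites the fragment
count is exactly `sum_{j=0}^{min(k,c)} (c + 1 - j)` — a closed form the test
suite checks against brute-force enumeration.

Coordinates are reported 1-based inclusive (the usual convention in peptide
tables); internally everything is slice arithmetic on the parent string, and
a reconstruction invariant (0-missed fragments concatenate to the parent)
is property-tested. Unknown residues (`X`) are tolerated on load, never act
as cut sites, and peptides containing them are dropped before scoring
because hydropathy and charge are undefined for `X`.

After digestion, peptides are length-filtered to 5-50 residues and
deduplicated globally by sequence (first occurrence wins), mirroring how a
screening campaign counts *unique* peptides. Length distributions are
reported over the conventional bins 5-20, 21-35 and 36-50 residues, with
percentages rounded to one decimal.

```{r digestion}
digest("AAFAAALAA")$peptide
digest("AAFPAA")$peptide   # proline vetoes the cut after F
```

## Physicochemical profile

Four descriptors drive candidate characterization:

* **Net charge** — integer side-chain model at neutral pH: Lys, Arg +1;
  Asp, Glu -1; His 0; termini ignored. This reproduces the qualitative
  cationic/anionic/neutral labels used in screening summaries. A
  Henderson-Hasselbalch fractional model (side chains plus termini) is
  available via the `pH` argument for users who need pH dependence.
* **GRAVY** — mean per-residue hydropathy, Kyte-Doolittle by default, with
  `hydrophobic` defined as GRAVY > 0. Hopp-Woods and Eisenberg scales (or a
  custom named vector) are pluggable because no single scale is canonical.
* **Hydrophobic moment** — Eisenberg's mean-vector magnitude at 100 degrees
  per residue (the alpha-helical period). A peptide is called amphipathic at
  `mu_H >= 0.2`, a conventional helical-wheel cutoff; both angle and
  threshold are arguments.
* **Residue composition** — exact counts over the 20-letter alphabet.

One caveat worth stating: qualitative labels in the literature do not always
agree with any fixed scale (a peptide called "hydrophilic" can have positive
Kyte-Doolittle GRAVY — TTMICLTCAR is an example). The package therefore
always reports the scale it used and never forces agreement with an external
label.

```{r properties}
peptide_properties(c("VTFVLIAAK", "TTMICLTCAR"))[,
  c("peptide", "net_charge", "charge_class", "gravy", "hydro_class",
    "hydrophobic_moment")]
```

## Consensus screening and mode of action

Screening consumes a TSV of per-peptide predictor outputs: an AntiCP-style
SVM score, an iACP-style probability, and MLACP-style random-forest and SVM
probabilities, plus binary toxicity and cell-penetration flags. The
consensus call requires **all three predictors positive** under strict
thresholds: SVM score over 1.00, and each probability over 0.5. "Over" is
strict — a score exactly at the cutoff is negative. The mapping of table
columns to predictors is overridable (`read_scores(column_map = ...)`)
because published score tables are not always labelled unambiguously.

Consensus ACPs are stratified by mode of action into four *exclusive*
categories — `toxic_only`, `cpp_only`, `both`, `none` — which partition the
consensus set; overlapping totals (toxic = toxic_only + both, and likewise
for cpp) are reported alongside, since published screens often quote the
overlapping counts. Candidates are ranked within a category by SVM score,
with ties broken by the mean of the other three scores and then
lexicographically, making the order a reproducible total order.

`venn_counts()` reports the seven predictor-agreement regions and satisfies
inclusion-exclusion by construction; the tests verify it against explicit
set algebra on randomized tables.

## Substitution redesign

The redesign step emulates a "peptide design" service: starting from a
candidate, find a few substitutions that increase a score. Because the
internals of such services are not published, `pepscreen` uses the simplest
defensible search — greedy hill-climbing, one substitution per round, over
all `19 x length` single mutants, with deterministic tie-breaking (lowest
position, then alphabetical residue), stopping at `max_rounds` (default 2,
matching the two-substitution redesigns typically reported) or when no
mutant improves the score. An exhaustive `<= k`-substitution search is
provided as an oracle for small `k`, and the suite checks greedy equals the
exhaustive argmax at one round. The scorer is a user-supplied function; the
built-in additive per-residue scorer exists only so the search is testable
without fabricating an ACP model.

## MTT viability and the four-parameter logistic fit

Viability from a plate of 570 nm absorbances is
\[
\%V = 100 \times \frac{A_{\text{treated}} - A_{\text{blank}}}
{A_{\text{control}} - A_{\text{blank}}},
\]
with blank correction by the per-plate mean blank (standard MTT practice)
and the mean corrected control as denominator. The identity is affine
invariant: rescaling all absorbances leaves viability unchanged.

Dose-response is modelled with the four-parameter logistic
\[
V(d) = \text{bottom} + \frac{\text{top} - \text{bottom}}
{1 + (d/\text{ic50})^{\text{hill}}},
\]
which is defined at `d = 0` (`V(0) = top`), so zero doses are *fitted*, not
dropped; log-dose is used only for display. Fitting is bounded
Levenberg-Marquardt (`minpack.lm::nls.lm` — the raw optimizer, which unlike
the `nls` wrapper also handles the zero-residual perfect-fit case) with a
deterministic initializer: top and bottom from the extreme dose-mean
viabilities, ic50 at the dose nearest the midpoint response, hill = 1;
bounds are bottom >= 0, top <= 120, hill in [0.1, 10]. No random restarts:
the same data always give the same fit. Standard errors come from the
curvature at the optimum.

### Which IC50 is reported, and why

Two quantities both get called "IC50":

* the **curve midpoint parameter** `ic50` — the dose halfway between the
  *fitted* top and bottom plateaus ("relative IC50");
* the **absolute IC50** `ic50_abs` — the dose at which the fitted curve
  crosses 50% viability, i.e. half-maximal inhibition relative to the
  untreated control.

They coincide when top = 100 and bottom = 0. When the tested dose range does
not reach the lower plateau (common at 0-400 uM designs where viability only
falls to ~15%), `bottom` is weakly identified and trades off against the
midpoint parameter; with the bottom >= 0 bound this truncation biases the
midpoint estimate several percent low and inflates its variance. The
absolute IC50 is determined by the part of the curve the data actually
constrain and is the conventional summary for control-normalized viability,
so `pepscreen` reports both but treats `ic50_abs` as the headline estimate.
In a 100-plate simulation at the peptide monotherapy scenario the absolute
IC50's median error is about 0.2% against a nominal 4% for the midpoint
parameter (the calibration test in the suite enforces < 2% median error and
a spread within three times the delta-method noise-propagated SD).

Uncertainty on both IC50s is summarized by a within-dose case-resampling
bootstrap (199 resamples, fixed internal seed), which mirrors the
"mean +/- variation" style of published IC50s without assuming which
convention a given study used.

Profiles whose dose-mean response never drops 15 viability points below its
maximum are flagged `no_inhibition` and not fitted: a flat curve carries no
information about an IC50, and fitting one would only produce
pseudo-numbers. Non-convergence likewise returns a flagged result with
diagnostics, never silent values.

```{r fit}
plate <- gen_mtt(mtt_scenario("C_ORI"), seed = 1)
fit <- fit_4pl(viability ~ dose, plate_viability(plate))
fit
```

## Group comparisons

`compare_conditions()` runs one-way ANOVA followed by Dunnett's many-to-one
comparisons against the shared control, with single-step multivariate-t
adjustment (via `multcomp::glht`, which integrates the exact many-to-one
multivariate t). Flags follow the usual `*` p < 0.05 / `**` p < 0.01
convention, and adjusted p-values are never reported below the raw ones. A
1,000-replicate null simulation in the test suite checks the family-wise
error rate lands in [0.04, 0.06].

`combination_analysis()` handles two-compound factorial grids: per-cell
mean +/- SD, and for every true combination cell a contrast against the
untreated control and against each monotherapy margin (missing margins are
an error, not a silent skip), again with single-step multivariate-t
adjustment across all contrasts, reporting the direction of each difference
on the viability scale. Formal synergy indices (Bliss, Loewe,
Chou-Talalay) are out of scope — the analysis states whether a combination
differs from its margins, not why.

## The synthetic-data generators

The generators exist so the whole pipeline is testable offline; their
defaults are fixed study conditions, not tuning knobs.

* `gen_proteome()` draws i.i.d. sequences from a UniProt-like background
  residue frequency vector, lengths gamma-distributed around 400 residues
  (CV 0.3, floor 50). With F + L at ~13.5%, pepsin fragments have mean
  length ~7 and a tail that populates all three screening bins at
  100 proteins.
* `gen_scores()` draws a latent "true ACP" label (prevalence 0.015) and
  then conditionally independent predictor scores: Gaussian for the SVM
  score (positives N(1.70, 0.25), negatives N(1.47, 0.25)) and Beta for the
  probability columns. These were calibrated once so the *marginal* call
  rates resemble a real consensus screen — one permissive predictor calling
  ~97% positive, the others far stricter, consensus ~1.5% — and so the
  implied recall (~0.67) and precision (~0.73) are computable in closed
  form from exceedance probabilities (`consensus_rates()`), which is what
  the acceptance property tests check observed rates against.
  Mode-of-action flags are Bernoulli with P(toxic | ACP) = 19/316 and
  P(cpp | ACP) = 247/316, taken from the category proportions of a
  published 316-ACP consensus screen, with background rates 0.05/0.30.
* `gen_mtt()` simulates plates: per timepoint, 4 blank wells, 4 untreated
  control wells and 4 replicate wells per positive dose, with absorbance
  `blank_od + control_od * V(d)/100` plus Gaussian noise mapped from the
  viability scale (SD 5 points by default; control OD 1.0, blank OD 0.05).
  A zero-noise plate round-trips exactly through `plate_viability()` and
  `fit_4pl()`. The `C_ORI` scenario (true IC50 114.9 uM, top 100, bottom 0,
  hill 1.5, doses 0/25/50/100/200/400 uM, 4 replicates, 72 h) encodes the
  peptide monotherapy design; `DOX` a doxorubicin monotherapy with two-fold
  doses 0-0.25 uM and a point IC50 of 0.12 uM chosen inside the broad
  literature bracket; `FLAT` an inactive compound (top = bottom = 100).
  Hill slope, noise SD and OD levels are declared design choices — the
  monotherapy designs state doses and replicate counts but not these.

One global seed expands into per-stage seeds by a fixed affine rule modulo
2^31 - 1 (`stage_seed()`), so stages never share RNG streams, and every
generator restores the caller's RNG state.

What the generators deliberately do **not** emulate: real predictor decision
surfaces (scores are conditionally independent given the label, which real
ensembles are not), sequence-dependent activity, plate-position effects,
and between-day drift. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and calibrated under its stated observation
model — not that any particular proteome will yield active peptides.

## Problem sizes and numerical choices

The test suite runs at desk scale by choice: 1,000 random proteins for the
digestion invariants, a 5 x 5 (hill, IC50) grid for noiseless 4PL recovery
(relative error < 1e-6), 100 plates for IC50 calibration, 20 plates for the
scenario recovery check, 10,000 peptides for screening recall/precision
bands, and 1,000 replicates for the Dunnett null simulation. Corpus-scale
published numbers (tens of thousands of peptides against live predictor
servers) are intentionally not reproduced: they depend on an unversioned
proteome build and third-party services, which is exactly the
irreproducibility this package is designed to avoid.

Other numerical decisions, collected: strict threshold comparisons;
first-occurrence deduplication; position-major alphabetical tie-break in
redesign; LM tolerances 1e-15 with at most 500 iterations; no-inhibition
span threshold 15 viability points; bootstrap 199 resamples with fixed seed
19; IC50-in-range flag when the midpoint parameter leaves the tested dose
interval.

## Limitations

* Cleavage rules are P1/P1'-only; genuine pepsin context effects (P4-P2')
  are not modelled.
* The charge model ignores termini by default and treats His as neutral;
  use the pH mode where that matters.
* The consensus screen is only as good as the score tables fed to it; the
  package makes no activity predictions of its own.
* Dose-response inference assumes Gaussian, homoscedastic viability noise;
  strongly heteroscedastic plates deserve weighting the package does not
  currently provide.
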