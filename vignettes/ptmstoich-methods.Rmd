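---
title: "Methods and models in ptmstoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models in ptmstoich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmstoich)
```

ptmstoich implements the quantitative layer of a targeted/label-based
proteomics workflow built around histone post-translational modification
(PTM) stoichiometry in yeast: mass calculus for chemically derivatized
peptides, parallel-reaction-monitoring (PRM) target generation,
occupancy and stoichiometry estimation from extracted-ion-chromatogram
(XIC) areas, SILAC label-swap differential abundance, microplate
doubling-time estimation, and the downstream enrichment and ordinal
statistics. This vignette explains each model, its assumptions and
tunable parameters, the numerical choices made where the design was
open, and what the synthetic-data generators do and do not emulate.

## Peptide mass calculus and the propionylation model

All masses are monoisotopic. A peptide's neutral mass is the sum of its
residue masses plus one water; a precursor's m/z at charge $z$ is
$(M + z \cdot m_p)/z$ with proton mass $m_p = 1.007276$ Da and water
$18.010565$ Da. Modification shifts are full-precision Unimod
monoisotopic values (propionyl $+56.026215$, methyl $+14.015650$,
dimethyl $+28.031300$, trimethyl $+42.046950$, phospho $+79.966331$,
Arg10 $+10.008269$, Lys8 $+8.014199$, Pro6 $+6.013809$). The compact
tags used in peptidoform notation ("Pr/56.03", "Me/14.012") are display
labels only — five-decimal m/z agreement is only achievable with the
full-precision shifts, so the parser resolves tags by *name* and
ignores the printed number.

Propionylation (propionic anhydride derivatization) converts every
unmodified lysine $\varepsilon$-amine to propionyl-lysine and every
monomethyl-lysine to the composite propionyl-methyl-lysine
($+70.041865$, one residue, one modification key); di- and tri-methyl
lysines have no reactive $\varepsilon$-proton and are untouched. This
equalizes peptide chemistry across methylation states and blocks
tryptic cleavage at the derivatized lysine, which is what yields a
single quantifiable peptide (H3 residues 27–40, KSAPSTGGVKKPHR)
spanning K36 regardless of methylation state. The N-terminal
$\alpha$-amine is derivatized only on request (`derivatize_nterm`):
the default models a single pre-digestion derivatization round, which
is the arithmetic consistent with three propionyl groups on the
unmethylated form of the 27–40 peptide. A second, post-digestion round
remains selectable for workflows that use it.

Digestion follows strict trypsin with two dialect rules: no cleavage
before proline, and no cleavage after a lysine whose side chain carries
any blocking modification (propionyl, propionyl-methyl, methyl,
dimethyl, trimethyl by default). Coordinates are 1-based throughout,
with `"N-term"`/`"C-term"` sentinels, so peptide positions can be read
as biological residue numbers.

## The H3K36 PRM inclusion list

One methylation site expands to five chemical forms: me0 (propionyl at
the site), me1 in two forms (underivatized monomethyl, and the
propionyl-methyl composite — incomplete derivatization of monomethyl
lysine is routine, so both are monitored), me2 and me3. With charges
2+ and 3+ this gives the ten-target inclusion list produced by
`h3k36_inclusion_list()`. Within a charge column the m/z order follows
total modification mass: me1-free < me2 < me3 < me0 <
me1-propionylated. The CSV writer prints m/z to five decimals; the
packaged reference copy of the list (`inst/extdata/`) is the golden
file for regression tests. The list schema (label, sequence,
modifications, charge, m/z) is deliberately vendor-neutral; retention
time windows and collision energies are acquisition-side concerns out
of scope here.

## Occupancy and stoichiometry from XIC areas

Both estimators are composition ratios of integrated peak areas within
a *quantification group* (one backbone sequence and missed-cleavage
form). Key rules:

* Single phospho form: occupancy $= A_p / (A_p + A_u)$.
* Several distinct singly-phosphorylated forms: each form's occupancy
  uses the shared denominator $A_u + \sum_i A_{p_i}$, so the fractions
  plus the unmodified complement close to 1.
* Forms whose sites cannot be resolved (ambiguous localization or
  chromatographic co-elution) arrive as one record carrying the union
  of candidate site labels and are reported as one pooled result.
* Missed-cleavage variants are independent groups, never pooled —
  they are chemically distinct analytes with their own response
  factors.
* Multiply-phosphorylated forms are excluded from the singly-phospho
  denominator (the grouping rule speaks only of singly phosphorylated
  versions) and reported as their own pooled class against the
  unmodified baseline, flagged `form_class = "multi"`.
* A group whose areas are all zero yields an explicit missing value,
  not 0: absence of signal is not evidence of zero occupancy. Missing
  replicates are excluded from replicate means and from `n`.

Methyl stoichiometry sums the two me1 chemical forms into one me1
state and divides each state's area by the five-form total, so the
four state fractions always sum to 1 when any signal is present. By
default only triply charged areas are used (the charge state used for
quantification in this workflow); 2+ areas can be included by flag.
Both estimators are invariant to rescaling all areas by a positive
constant, which is what makes them robust to injection-amount and
instrument-response differences between runs but *not* to
form-specific ionization differences — a known, unavoidable assumption
of label-free PTM stoichiometry.

## SILAC label-swap differential abundance

The pipeline consumes protein-level median log2 heavy/light ratios
(one row per protein per replicate), as produced by an MS1
quantification tool. Filtering removes contaminants, decoys, any
protein with fewer than two peptides in either replicate (strictly
fewer — two peptides is retained), and proteins lacking a ratio in
either replicate. "Normalization" is per-replicate median-centring of
the log2 ratios: it is the minimal convention consistent with working
on median log2 H/L ratios, and it exactly removes a global mixing
offset (unequal total protein in the heavy/light mix). Alternative
centring schemes were considered (mean-centring, global centring
across replicates) but median-centring is robust to the small shifted
fraction and is applied per replicate because mixing error is a
per-mix property. Reverse-orientation replicates (wildtype heavy) are
then multiplied by $-1$, putting every value on the mutant:wildtype
log2 scale.

Per protein, a two-sided one-sample t-test against 0 is BH-corrected
across all tested proteins; calls use an inclusive fold-change
threshold ($|\bar{x}| \ge 0.8$ log2) and a strict q threshold
($q < 0.05$). Zero-variance proteins have no distributional basis for
t with two replicates; their p is set missing and they are excluded
from the BH family rather than given a fabricated value. With one
label swap (two replicates) the test has a single degree of freedom,
and the pipeline warns that power is minimal: in simulation, even a
planted 1.5 log2 shift at replicate noise 0.2 is essentially never
called at $q<0.05$ across 3000 proteins, while the planted effect size
itself is recovered to within two standard errors. A null experiment
yields zero calls — which is also the biologically expected behaviour
of this stage in the motivating application.

Two label-accuracy estimators are included: incorporation
($\mathrm{mean}_i\, H_i/(H_i+L_i)$ over K/R-containing peptides of a
fully heavy sample) and arginine-to-proline conversion
($\mathrm{mean}_i\, P6_i/(P6_i+P0_i)$ over proline-containing
peptides). Zero-total peptides are skipped.

## Doubling times from microplate curves

The doubling time is $\log_{10}(2)/s$, where $s$ is the maximum OLS
slope of $\log_{10}(\mathrm{OD600})$ versus time over all contiguous
windows of `window` points whose ODs all exceed `od_floor` (default
0.02 above blank; log of blank-level signal is excluded, not clipped,
to avoid fabricating structure). The default window is 6 points. On
noise-free exponential data the estimate is exact for any window; a
window that never sees positive slope flags the curve non-growing.

Two opposing biases deserve note, and are why replicate means — the
quantity actually reported in growth experiments — are the right level
for accuracy claims. First, taking the *maximum* over many overlapping
windows is an extreme-value statistic: under multiplicative read noise
$\sigma$, the selected slope overshoots by roughly 1–2 window slope
standard errors, shortening the estimated doubling time (for a 90-min
culture read every 10 min at $\sigma = 0.02$, single wells scatter by
up to ~10 min). Second, on a logistic curve the instantaneous log-slope
is attenuated by $(1 - \mathrm{OD}/K)$, so inoculation at a
non-negligible fraction of the carrying capacity lengthens the
estimate. Widening the window shrinks the first bias at the cost of
averaging over more of the second. At the defaults and the study-like
conditions simulated here (inoculation 0.1 OD600, plateau ~1.2, reads
every 10 min), the six-replicate mean recovers a 90-min doubling time
within ±5 min.

## Statistical kernels

* **BH q-values** use the standard cumulative-minimum step-up
  formulation (via `p.adjust`), verified in the test suite against a
  brute-force implementation of the definition
  $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$.
* **Hypergeometric enrichment** is one-sided over-representation,
  $P(X \ge k)$, with the *quantified* gene set as the background —
  using the whole genome instead would overstate enrichment of any
  expression-biased category. Terms with no study hit are skipped;
  annotations outside the background are dropped; a study gene absent
  from the background is an error, not silently ignored. The tail
  probability is verified against exhaustive enumeration.
* **DE classification** applies inclusive $\pm 0.8$ log2 fold-change
  and strict adjusted-p thresholds; genes with missing adjusted p are
  `unchanged` with a warning. Genes whose summed read count across
  samples is at most 1 are removed before modelling.
* **Proportional-odds regression**
  ($P(Y \le j \mid x) = \mathrm{logistic}(c_j - \beta^\top x)$) is
  fitted by Newton ascent on the reparameterized vector
  $(c_1, \log\Delta_2, \dots, \log\Delta_{J-1}, \beta)$, which keeps
  cutpoints strictly ordered by construction. The Hessian is obtained
  by central finite differences of the analytic gradient; steps are
  halved until the likelihood increases; convergence is declared at
  gradient norm $< 10^{-8}$ or 100 iterations. Standard errors come
  from the observed information in the natural parameterization, and a
  Wald test on $\beta$ is reported. Observations carry non-negative
  real weights so the four methyl-state fractions can enter directly
  as weighted rows — the general-purpose formulation adopted here
  because the exact covariate coding and replicate handling of the
  motivating analysis is not fully specified; integer-count expansion
  is the special case of integer weights. Complete separation shows up
  as a flat likelihood ridge; it is diagnosed post hoc by an unbounded
  Wald standard error and reported as `converged = FALSE` with a
  warning, never silently. With two response states the model reduces
  exactly (to $10^{-6}$) to logistic regression, which the test suite
  checks against `glm`, and the full fit is cross-checked against an
  independent implementation (`MASS::polr`).

## Synthetic data: what it emulates and what it does not

Every input the pipeline consumes can be generated with known ground
truth, and each generator persists its truth beside the data
(`write_scenario()`). A single root seed fans out to per-scenario
child seeds through a fixed multiplicative counter
(`child_seed(seed, k)`, kept below $2^{31}$), so regeneration is
byte-identical and partial re-runs agree with full runs.

* XIC tables: per-group lognormal base abundance split by the true
  occupancy, times i.i.d. lognormal noise (multiplicative, because
  intensities are positive and noise scales with signal); optional
  two-site groups, co-eluting pooled forms, and missed-cleavage
  duplicate groups. Default conditions: 4 replicates, $\sigma = 0.2$.
* Methyl profiles: five chemical forms from a state distribution with
  a stated me1 split (default 50/50), 3 replicates, $\sigma = 0.2$.
* SILAC experiments: 3000 proteins, 50 shifted at $|\Delta| = 1.5$
  log2 (half up, half down), replicate noise 0.2, injected mixing
  offsets $\pm 0.3$, planted contaminants/decoys and single-peptide
  rows.
* Growth curves: logistic solutions with specified exponential-phase
  doubling times, inoculation 0.1 OD600, plateau 1.2, 10-min sampling,
  optional lag and multiplicative noise.
* Enrichment universes: uniform random term assignments with planted
  terms over-represented in the study set by a sampling-weight odds
  ratio.

These generators deliberately omit several features of real data:
form-specific ionization efficiencies (XIC ratios are treated as
unbiased), retention-time structure and integration error, ratio
compression from co-isolation, peptide-to-protein roll-up (protein
medians are generated directly), non-logistic growth phenomena
(diauxie, flocculation), and correlated annotation structure in GO.
Passing the recovery tests therefore demonstrates that the estimators
are correct *given* correctly integrated, unbiased areas and ratios —
not that those upstream steps are error-free.

## Problem sizes and runtime choices

The test suite and the acceptance script use 200 quantification groups
× 4 replicates for occupancy recovery, 3000-protein experiments (20
seeds for the FDR check), 200 ordinal simulations at $n = 500$, and
six-replicate growth simulations of 1200 min — sizes at which every
recovery claim is stable across seeds while the whole suite runs in
well under a minute on one core.

## Known limitations

* The mass table covers the 20 standard residues and the listed
  modifications; average masses, isotope envelopes, and fragment-ion
  m/z are out of scope.
* Occupancy estimation assumes equal response factors across forms
  within a group (inherent to label-free stoichiometry).
* The differential-abundance test with one label swap has 1 df;
  the pipeline is honest about this rather than borrowing variance
  across proteins (no moderation is implemented).
* The steepest-slope doubling-time estimator is an extreme-value
  statistic; single-well estimates under read noise carry a
  selection bias that only widening the window or replication
  averages out.
* The ordinal model's weighted likelihood treats fractional weights
  as exact replication weights; standard errors do not account for
  the compositional dependence among the four state fractions of one
  replicate.
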