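---
title: "Methods: NO donor kinetics, demethylase inhibition, and oxRRBS differential methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NO donor kinetics, demethylase inhibition, and oxRRBS differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notet)
library(dplyr)
```

`notet` models the chain of reasoning that links a dose of a NONOate NO
donor in a demethylase assay to a genome-wide differential-methylation
readout: donor decomposition sets a free-NO concentration, free NO
reversibly inhibits Fe(II)/2-oxoglutarate-dependent DNA demethylases (TET,
ALKBH2), chronic inhibition shifts 5mC/5hmC levels, and an oxRRBS
experiment measures those shifts site by site. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## The donor/NO/O2 kinetic model

Diazeniumdiolate donors decompose first order with rate constant
$k_1 = \ln 2 / t_{1/2}$, releasing $e_\mathrm{NO}$ moles of NO per mole of
donor. In aerated buffer the dominant sink for free NO is autooxidation,
$4\,\mathrm{NO} + \mathrm{O_2} \rightarrow 4\,\mathrm{NO_2^-}$, third order
overall with the termolecular rate $k\,[\mathrm{NO}]^2[\mathrm{O_2}]$. The
state equations integrated by `simulate_no()` are

$$
\frac{d[D]}{dt} = -k_1 [D], \qquad
\frac{d[\mathrm{NO}]}{dt} = k_1 [D]\, e_\mathrm{NO}
  - s\,k\,[\mathrm{O_2}][\mathrm{NO}]^2, \qquad
\frac{d[\mathrm{O_2}]}{dt} = -k\,[\mathrm{O_2}][\mathrm{NO}]^2,
$$

with $s$ the NO:O2 consumption stoichiometry. O2 is a dynamic state, not a
fixed constant; oxidised NO is accumulated as a fourth state so mass
balance is checkable at every output time.

**Stoichiometry choice.** Writing the NO sink as $k[\mathrm{O_2}][\mathrm{NO}]^2$
with no stoichiometric factor ($s = 1$) is a common shorthand, but with the
literature rate constant $k = 2\times10^{6}\ \mathrm{M^{-2}s^{-1}}$ and
air-saturated O2 (220 uM) only $s = 4$ — the textbook autooxidation
stoichiometry, four NO consumed per termolecular event — reproduces the
steady-state values these donor protocols are known for (about 3 uM at
165 uM Sper/NO over 3 h; about 0.6 uM sustained by 100 uM DETA/NO). The
default is therefore `no_per_o2 = 4`, configurable in `kinetic_params()`.

**Donor table.** Built-in half-lives and stoichiometries: DEA/NO 16 min and
1.5 NO; Sper/NO 230 min and 2 NO; DETA/NO 57 h and 2 NO. DETA/NO half-lives
between roughly 20 h and 57 h are quoted in the literature depending on
temperature and buffer; 57 h is the value under which the 0.6 uM plateau
figure arises, so it is the default, and `donor_spec()` accepts any
override. Half-lives are used as configured, with no Arrhenius correction.

**Units and integration.** Internal units are uM and seconds (so
$k = 2\times10^{-6}\ \mathrm{uM^{-2}s^{-1}}$), which keeps all states within
a few orders of magnitude of unity. The integrator is `deSolve::lsoda`
(adaptive, stiff-capable) at relative tolerance $10^{-8}$ and absolute
tolerance $10^{-6}$ uM. Negative excursions within the absolute tolerance
are clipped to zero; anything larger aborts with a diagnostic rather than
being silently repaired.

**The quasi-steady-state oracle.** Balancing release against consumption
gives the closed form

$$[\mathrm{NO}]_{qss} = \sqrt{\frac{k_1 [D]\, e_\mathrm{NO}}
  {s\,k\,[\mathrm{O_2}]}},$$

implemented independently of the ODE path in `quasi_steady_state_no()`.
For slow donors the full solution must track this expression evaluated
along $[D](t)$, $[\mathrm{O_2}](t)$ once the NO pool has relaxed
(relaxation time $\approx 1/(2sk[\mathrm{O_2}][\mathrm{NO}]_{ss})$, a few
hundred seconds at these concentrations); the test suite enforces agreement
within 10% after ten relaxation times. This dual route — numerical
integration checked against an analytic limit — is the package's main
defence against silent solver misconfiguration.

**What "steady-state NO" means here.** Reported steady-state values could
be time-averages, plateaus, or single-time readouts; the package defines
the quantity operationally as the trapezoidal time-average over the assay
window (`summarize_steady_state()`), with the peak reported alongside. The
time-average reproduces both reference conversions (Sper/NO 165 uM, 3 h
window: 2.77 uM; DETA/NO 100 uM, 12 h window: 0.59 uM), which is why it is
the default; assays that read out at a single time can pass an explicit
window instead.

## NO-coupled enzyme activity

`inhibition_fraction()` maps free NO to an inhibited fraction through a
Hill logistic on the log-concentration axis — the same functional form as
the four-parameter logistic used for dose-response fitting, with asymptotes
pinned at 0 and 1:

$$f([\mathrm{NO}]) = \frac{1}{1 + 10^{(\log_{10} IC_{50} -
  \log_{10}[\mathrm{NO}])\,h}}.$$

Defaults are $IC_{50} = 1$ uM and $h = 4$: a steep, threshold-like
response centred inside the 0.6-1.65 uM bracket through which simulated NO
falls, between hours one and two, in the burst protocol where enzymatic
recovery is observed. Both are configurable; neither is fitted to data by
the package.

Product formation follows
$dP/dt = k_\mathrm{conv}\,(1 - f([\mathrm{NO}](t)))\,(1 - P)$: inhibition
scales the instantaneous rate, never the accumulated product, so a
reversible inhibitor pauses conversion without undoing it and $P$ is
monotone by construction. The step update is exact for piecewise-linear
$f(t)$ (exponential survival of substrate under the trapezoid-integrated
available rate), so no separate ODE solve is needed. The uninhibited rate
default $k_\mathrm{conv} = 1.28\times10^{-3}\ \mathrm{s^{-1}}$ is
calibrated to one observable: at least 99% conversion within the first
hour of an uninhibited assay.

`classify_regime()` reduces a product trajectory at checkpoint times
(default 1, 2, 3 h) to one of three labels: `full_activity` (>= 0.95 at
the first checkpoint), `full_inhibition` (below 0.95 and gaining < 0.02
between later checkpoints — a plateau), `inhibition_recovery` (suppressed
early, >= 0.95 by the last checkpoint). A trajectory still climbing but
unfinished at the last checkpoint is reported as `full_inhibition`; only a
completed recovery earns the recovery label. The absolute plateau level
under sustained NO depends on unmodelled enzyme kinetics (binding rates,
substrate affinity) and is deliberately not asserted anywhere.

## Assay quantification

**4PL fitting.** `fit_4pl()` performs bounded Levenberg-Marquardt least
squares (via `minpack.lm`) on
$Y = \mathrm{Bottom} + (\mathrm{Top} - \mathrm{Bottom}) / (1 +
10^{(\mathrm{LogIC_{50}} - X)\,\mathrm{Hill}})$ with $X = \log_{10}$ dose.
Starting values come from the data: asymptotes from the response extremes,
LogIC50 from the dose nearest mid-response, Hill $\pm 1$ by the sign of the
dose-response covariance. Hill is bounded to $[-10, 10]$ and the asymptotes
to within two response spans of their starts; LogIC50 may roam three
decades beyond the dose range, at which point the IC50 is effectively
unidentified and the residual diagnostics say so. Decreasing responses are
coded with negative Hill, the same sign convention the inhibition model
round-trips. Constant responses and fewer than five distinct doses are
refused outright rather than returned as degenerate fits.

**MALDI fractions.** Each cytosine adduct (5mC, 5hmC, 5fC, 5caC) is
quantified as its integrated peak intensity over the summed intensity of
all adducts — scale-invariant by construction. Raw spectrum processing
(baselining, centroiding, peak annotation) is upstream vendor-software
territory and out of scope.

**Linear calibration.** Standard-curve inversion (e.g. nitrite standards in
a Griess assay) is ordinary least squares with inverted unknowns; negative
inverted concentrations are clipped to zero and flagged `below_range`
rather than reported as physically meaningless negatives.

## The oxRRBS differential-methylation stage

**Beta arithmetic.** BS libraries read 5mC + 5hmC; oxBS libraries read 5mC
alone. Per site, condition and replicate, `compute_betas()` sets
$\beta_{5mC} = \mathrm{oxBS\ meth/total}$ and
$\beta_{5hmC} = \max(0, \beta_{BS} - \beta_{oxBS})$, the standard oxBS
subtraction convention; the clip rate is carried as a QC flag since a high
rate signals assay trouble. Sites with either assay under `min_coverage`
(default 10) are masked, not dropped.

**Calling.** A site is `hyper` when $p < \alpha$ and $\Delta\beta > \delta$,
`hypo` when $p < \alpha$ and $\Delta\beta < -\delta$
($\alpha = 0.05$, $\delta = 0.1$ by default). No multiple-testing
correction enters the call — the definition is a raw-p plus effect-size
rule — but a Benjamini-Hochberg FDR column is emitted for transparency.

**Test choice.** Three tests are offered. The default, `limma`, fits
per-site linear models on replicate beta-values and shrinks the residual
variances across sites with empirical Bayes (`eBayes(trend = TRUE)`; the
trend term absorbs the binomial mean-variance relation of beta-values,
which peaks at $\beta = 0.5$). This hierarchical treatment is what
established methylation pipelines use, and it is the reason two replicates
per condition suffice: an unmoderated Welch t-test at $n = 2$ per group has
only one or two effective degrees of freedom and, by direct simulation at
coverage 50, recovers under half of genuinely shifted sites
($\Delta\beta = 0.3$) — the moderated test recovers essentially all of
them while keeping the null call rate near 4%. The unmoderated `welch`
test remains available (and is cross-checked against `stats::t.test` in
the suite) for the strictly-per-site analysis, and `fisher_pooled` pools
counts across replicates into a 2x2 table for designs with a single
replicate. For the 5hmC mark under pooled Fisher, the hydroxymethylated
count is reconstructed as `round(pooled beta_5hmC x pooled BS total)` — an
approximation, noted because oxBS chemistry defines 5hmC only as a beta
difference, never as a directly sequenced count.

**Annotation.** CpG class by distance to the nearest island: `island`
inside one, `shore` within 2 kb, `shelf` 2-4 kb, `open_sea` beyond — the
community convention, since annotation category lists are usually quoted
without distances. Functional elements resolve by precedence
promoter > 5'UTR > 3'UTR > exon > intron > enhancer > super-enhancer, with
enhancer overlaps also kept as independent flags. When only TSS positions
are available, `promoters_from_tss()` builds the standard −1500/+500 bp
strand-aware window. All coordinates are 0-based half-open (BED), strand
ignored at CpG level (sites treated as strand-symmetric units). Interval
arithmetic is delegated to `GenomicRanges`.

## What the synthetic data emulate — and what they do not

`synth_oxrrbs()` places one CpG site per 20-kb island slot so the
generating CpG class is recoverable exactly by the annotation rules, draws
class-dependent baselines (islands hypomethylated at
$\beta_{5mC} \approx 0.1$, open sea high at $\approx 0.7$, 5hmC a minor
mark throughout, 0.03-0.10), and simulates Poisson coverage (default mean
50) with binomial methylated counts per assay. Planted treatment effects
(default: 5% of sites hyper, 2.5% hypo, $\Delta\beta = 0.3$, a modest
hyper excess mimicking a net gain of both marks under chronic NO) are
recorded with the delta actually applied, since a +0.3 shift cannot be
fully applied to a site whose baseline is already near the feasible
ceiling. Class proportions default to open-sea-dominant (60%), structurally
resembling genome-wide CpG distributions. `synth_dose_response()` uses
Gaussian response noise at two replicates per dose — matching the replicate
level of the assays this machinery models — and `synth_expression()`
couples log-expression linearly to promoter beta with negative slope. All
generators are pure functions of their arguments and a seed.

Deliberately not emulated: RRBS fragment-level coverage structure (MspI
digestion, fragment-size selection), spatial correlation of methylation
along the genome, biological replicate variance beyond binomial sampling,
cell-line-specific methylome differences, and any read-level artefacts
(alignment, bisulfite conversion inefficiency). Consequently, passing
tests demonstrate that the calling machinery has its stated operating
characteristics under idealised sampling noise — they do not certify
performance on real oxRRBS libraries, where extra-binomial dispersion will
reduce sensitivity at fixed thresholds.

## Problem sizes and numerical conventions

The test suite and the acceptance script run kinetic simulations at 10-60 s
output resolution over 3-12 h spans, 4PL recovery over 100 simulated
experiments of 8 doses x 2 replicates, and methylomes of 1000 sites with
2 + 2 replicates at coverage 50 — sizes chosen so the full suite completes
in well under a minute while leaving every estimate comfortably inside its
tolerance. Writers serialise floats at 9 significant digits, which keeps
write/read round trips stable to far better than $10^{-9}$ and repeated
runs byte-identical.

## Known limitations

- The kinetic model covers release and autooxidation only: no
  S-nitrosation, metal-nitrosyl side reactions, cellular NO consumption, or
  diffusion; it applies to well-stirred aqueous assays.
- The inhibition coupling treats nitrosylation as instantaneous and
  paralogs (TET1/2/3, ALKBH2) as a single effective enzyme; the three
  successive TET oxidation steps are not modelled separately.
- DMP calling operates on raw per-site betas; smoothed or regional
  approaches (and their different power profiles) are out of scope.
- Enhancer and super-enhancer tracks are taken as supplied; the package has
  no opinion on how they were derived.
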