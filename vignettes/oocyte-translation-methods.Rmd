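---
title: "Methods: dissecting dual translational control of maternal mRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting dual translational control of maternal mRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oomat)
```

## The biological question

Fully grown mouse oocytes are transcriptionally silent: progression through
meiotic maturation (germinal-vesicle breakdown, GVBD, then meiosis I and II)
is driven entirely by regulated translation of stored maternal mRNAs.
RNA-binding proteins such as DAZL and CPEB1 dock on 3'UTR cis-elements and
either repress a transcript (typically by keeping its poly(A) tail short) or
activate it (by promoting cytoplasmic polyadenylation around GVBD). A single
RBP can do both, depending on the 3'UTR context.

`oomat` implements the computational arm of the experimental designs used to
dissect such dual regulation:

1. **RiboTag IP / input RNA-seq** — ribosome-associated (IP) and total
   (input) counts per gene, in control vs RBP-depleted oocytes, before and
   after meiotic reentry. Differential *ribosome loading* between conditions
   identifies transcripts whose translation depends on the RBP.
2. **3'UTR element scanning and mutagenesis design** — where are the
   DAZL (UU[G/C]UU), CPE (CPEB1) and PAS elements, and which affected
   transcripts carry none (the null subset that bounds indirect effects)?
3. **Dual-channel reporter kinetics** — YFP-3'UTR reporters co-injected with
   a polyadenylated mCherry control, recorded by time-lapse microscopy;
   windowed regression slopes are per-oocyte translation rates, and
   oligo- vs poly-adenylated reporter pairs turn rate changes into an
   adenylation readout.
4. **RIP enrichment** — antibody vs IgG recovery classifies physical binding
   targets; joined with the translation classes it yields the target
   quadrants (bound-activated, bound-repressed, ...).

Because the original raw data live in a sequencing archive, every analysis
here is exercised against a first-class synthetic-data module that plants
known structure; planted truth is the acceptance surface throughout.

## Count model and the differential ribosome-loading test

Counts are modelled as negative binomial with mean--dispersion
parameterisation, $\mathrm{Var} = \mu + \phi\mu^2$; $\phi = 0$ recovers
Poisson. Experiments of this design are conventionally analysed with a
packaged GLM framework; here the statistic is implemented transparently
instead, and validated on planted-truth recovery rather than on reproducing
any particular tool's output:

* **Normalization.** `compute_cpm()` is plain counts-per-million (columns sum
  to $10^6$). For testing, effective library sizes come from
  *median-of-ratios* size factors: when a minority of genes shifts
  asymmetrically (the interesting case), total-count scaling would displace
  every null gene's fold change, while the median ratio to a geometric-mean
  reference stays put.
* **Dispersion.** `estimate_dispersion()` computes the per-gene
  method-of-moments estimate $(\hat v - \hat\mu)/\hat\mu^2$ within each
  replicate group, pools groups by degrees of freedom, and shrinks toward a
  lowess mean--dispersion trend (weight 0.8, floor $10^{-4}$). The lowess is
  run with `iter = 0`: the robust iterations would systematically
  down-weight the long right tail of the (very skewed) two-replicate moment
  estimates and bias the trend low, which makes the downstream test
  anti-conservative. With two replicates per arm the trend carries most of
  the information; the 0.2 weight on the per-gene residual keeps genuinely
  hypervariable genes from being over-trusted.
* **Exact test.** `exact_nb_test()` conditions on the sum of the
  (quantile-equalized) group totals. Counts are mapped to a common library
  size through the NB mid-probability transform
  $y' = Q\left(F(y-1) + \tfrac12 f(y)\right)$, group sums $a + b = s$ are
  formed, and the two-sided p-value is the total null probability of all
  splits of $s$ no more likely than the observed one, with the group sums
  distributed as NB$(n_g\hat\mu,\ \phi/n_g)$. At $\phi = 0$ the conditional
  law is exactly Binomial$(s, n_a/(n_a+n_b))$, which the test suite checks
  against an independent binomial enumeration to $10^{-9}$.
* **Classification.** BH-adjusted p-values (`bh_adjust()`, verified against
  the brute-force step-up definition) with the experiment's thresholds:
  `up` when $\log_2\mathrm{FC} \ge \log_2 2$ and FDR $< 0.05$, `down`
  symmetrically. Genes with fewer than 10 summed counts across the tested
  samples are excluded from testing and flagged (`filtered`); the count
  threshold is a conventional default, the source analyses do not state one.

Translational efficiency (`compute_te()`) is the IP CPM over the matching
input CPM per replicate pair, then the arithmetic mean of per-replicate
ratios. The alternative order (ratio of replicate means) is not used because
the per-replicate ratio respects the replicate pairing of IP and input
libraries; with two well-behaved replicates the difference is negligible,
and the choice is localized in one function should a user prefer the other.
Zero-input genes are flagged `undefined`, never dropped silently.

## Motif scanning and mutagenesis design

`scan_sequence()` does exhaustive IUPAC-degenerate window matching on the
sense strand (3'UTRs arrive in sense orientation), reporting *every* match
including overlaps — presence of at least one consensus is the readout the
coverage analyses need, so no greedy masking is applied. Coordinates are
0-based half-open throughout. DNA input is tolerated (T→U, logged);
non-nucleotide characters fail with the offending position named.

The default motif set is deliberately minimal: DAZL `UUSUU` (the element
targeted by mutagenesis), CPE `UUUUAU`/`UUUUAAU`, PAS `AAUAAA`/`AUUAAA`.
Published consensus catalogues (SELEX, crystal structure, CLIP) differ in
breadth and are not printed in full anywhere authoritative, so the set is
config-driven (`read_motif_yaml()`) and the defaults are documented as a
working set, not a reconstruction.

`mutate_element()` designs the standard adenosine-replacement mutant: every
U in the hit window becomes A (`UUGUU` → `AAGAA`), which destroys any
U-dependent element while preserving length and flanks. The mutant is
re-scanned and the function refuses to return a design that leaves a
same-class match overlapping the window — an ineffective policy is an error,
not a silent no-op.

## Reporter kinetics model

The simulator and the analysis share one kinetic picture. The instantaneous
translation rate of a reporter is

$$ r(t) = r_{\mathrm{base}}(t)\cdot\min\!\left(\frac{A(t)}{A_{\mathrm{ref}}},\ 1\right),
\qquad A(t) = \max(A_0 + a\,t,\ 0), $$

with $r_{\mathrm{base}}$ switching from `rate_pre` to `rate_post` at GVBD
and $a$ the net adenylation rate (negative for deadenylation). The
saturating-linear poly(A) coupling encodes the qualitative contract —
adenylation increases translation until the tail is "long enough" — with the
simplest form that has a controllable saturation point; the real coupling is
not known quantitatively. Defaults: oligo reporters start at $A_0 = 20$ A
(the synthesized oligo(A) stretch), poly reporters at $A_0 = 150$ A,
$A_{\mathrm{ref}} = 75$ A, so a poly reporter stays saturated over a 10 h
recording for $|a| \le 7.5$ A/h — which is exactly why the poly reporter
serves as the "no change" control in the decision table below.

YFP accumulates as the exact time-integral of $r(t)$ (trapezoidal on a grid
refined with every breakpoint, so piecewise-linear segments integrate
exactly); mCherry is constant at its plateau because recordings begin after
overnight pre-incubation, which is what the experimental protocol arranges.
A per-oocyte lognormal scale (CV 0.2) multiplies both channels jointly
(injection volume), a mean-corrected lognormal (CV 0.1) jitters each
oocyte's base rate, and each observation carries multiplicative lognormal
measurement noise (CV 0.05 by default) — fluorescence noise scales with
signal. All lognormals are mean-corrected so group means sit at the planted
values.

Analysis mirrors the experimental calculations:

* `normalize_trajectory()` — YFP/mCherry, either relative to the first
  recording (`"first-point"`, the display normalization) or to the fitted
  mCherry plateau (`"plateau"`, which keeps slopes in absolute ratio units
  and is what the rate analyses use). The plateau estimate is the mean
  mCherry over the last quarter of timepoints, robust at the 2–5% noise
  levels of these recordings.
* `fit_window_rate()` — OLS slope over a *closed* time window;
  maturation designs use [0, 2] h (pre-GVBD) and [4, 8] h (post-GVBD),
  GV-arrest designs [0, 3] and [7, 10] h. Windows are fixed by design;
  no automatic GVBD changepoint detection is attempted because the
  experiments define the windows, not the data.
* `rate_pair_test()` — Welch t-test on per-oocyte slopes. The Welch
  statistic is computed from its closed form (and checked against
  `stats::t.test` in the suite) so that degenerate zero-variance groups
  return defined p-values instead of erroring.
* `linearity_check()` — full-span $r^2 \ge 0.95$ plus, when group context is
  available, no significant early/late rate difference. The 0.95 default is
  chosen so that a cleanly accelerating trajectory (e.g. a sampled quadratic
  over 0–10 h, $r^2 \approx 0.94$) is called nonlinear while 2–5%
  measurement noise on a true line is not.
* `infer_adenylation()` — per-oocyte $\log_2(\text{late}/\text{early})$ on
  the oligo reporter; the group is called **adenylation** when the oligo mean
  exceeds $+\delta$ while the matched poly reporter stays within
  $\pm\delta$, **deadenylation** symmetrically, otherwise **stable**.
  $\delta = 0.5$ (a 1.4-fold rate change) is a design choice: the source
  logic is sign-based only, and 0.5 sits well above the ratio noise of
  clean recordings while well below the ~1.2 log2 units a planted
  de-repression produces. Oocytes with non-positive early rates have no
  defined ratio; they are excluded per-metric with a warning and a count,
  never dropped from the whole experiment.

## Synthetic data: what it emulates, what it does not

The generators emulate the *design* of each experiment: NB counts with
planted ≥2-fold loading shifts in a controllable fraction of genes (input
means identical across conditions — knockdowns here act on translation, not
transcript levels); UTR populations with controllable element carriage,
whose backgrounds are scrubbed so scanning reproduces the planted table
*exactly* (this is what makes the null-subset analysis exactly testable);
trajectories from the kinetic model above; RIP tables with lognormal
replicate noise around a planted separation.

They do not emulate: read-level artifacts (the pipeline starts at count
matrices), gene length or GC biases, correlated gene modules, alternative
polyadenylation isoforms, imaging artifacts (bleaching, focus drift,
segmentation error), or oocyte death. Passing tests therefore demonstrate
that the statistics recover what they claim *under their own model
assumptions* — calibration on real data would additionally face dispersion
misspecification and normalization stress that these simulations only probe
through the planted asymmetric-effect scenarios.

Default simulation sizes (2,000 genes × 16 samples for count experiments,
500 UTRs, 30 oocytes per group, the demo pipeline at 1,200 genes) are the
scale of the corresponding oocyte experiments and keep a full run in the
minutes range on a single core.

The demo pipeline configuration (`default_pipeline_config()`) uses 6-fold
planted effects at dispersion 0.02 — a deliberately well-separated "smoke"
regime in which classification is essentially error-free, so the end-to-end
run can assert *exact* recovery of planted quadrant counts. The statistical
acceptance checks (type-I error, sensitivity, FDR) run at the harder
standard conditions (4-fold, dispersion 0.05) instead.

## Numerical and degenerate-input choices

* Seeds: every simulator takes an explicit seed and restores the caller's
  RNG state; sub-seeds are derived arithmetically from one master seed and
  stay below $2^{31}$.
* Exact-test enumeration is done in log space and normalized before summing;
  ties in the "as extreme" comparison use a $1+10^{-7}$ relative tolerance
  (the standard guard against floating-point equality).
* An all-zero gene yields p = 1; a constant gene yields the dispersion floor,
  never NaN.
* `fit_window_rate()` on a constant series returns slope 0 with
  $r^2 = 1$ (a constant is a perfect line); 2-point windows are allowed for
  rate fitting but `linearity_check()` requires ≥ 3 points.
* UTR generation resamples backgrounds (bounded retries) until a re-scan
  reproduces the planted table exactly; infeasible plans (motif longer than
  the UTR, irreconcilable placement) fail with the constraint named.

## Known limitations

* The NB exact test conditions on estimated quantities ($\hat\mu$, shrunk
  $\hat\phi$); with two replicates per arm its p-values are mildly
  anti-conservative in the far tail, which the classification thresholds
  (fold gate + BH) absorb — the all-null classified fraction stays near zero
  in the acceptance checks, but individual raw p-values should not be
  over-interpreted.
* Gene ids are joined by exact string match; real-data use requires upstream
  id harmonization.
* The kinetics model has no oocyte random-effects structure; group inference
  is a two-sample Welch test on per-oocyte slopes, matching the original
  analysis rather than a mixed model.
* No batch correction, covariates, or transcript-level quantification.
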