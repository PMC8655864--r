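---
title: "Inferring dominant-negative subunit stoichiometry from oocyte voltage-clamp currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dominant-negative subunit stoichiometry from oocyte voltage-clamp currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirstoich)
```

## The question

Kir2.1 inward-rectifier potassium channels are tetramers. When a
loss-of-function mutant subunit is co-expressed with wild type (WT), the two
co-assemble at random, and the current produced by a mixed pool tells us how
many mutant subunits it takes to silence a channel. If one mutant subunit is
enough — the dominant-negative case — current collapses far faster than the
injected WT fraction; if mutant subunits were merely inert and never
co-assembled, current would fall linearly with the WT fraction.

`kirstoich` implements the full analysis chain for two-electrode voltage
clamp (TEVC) experiments in *Xenopus* oocytes: extraction of the
Kir-specific current from a three-bath protocol, quality control, batch
normalization, and ranking of a binomial subunit-assembly model family
against the normalized dose–response in the WT fraction *p*.

## The model family

With random assembly from a subunit pool containing WT fraction $p$, the
number of WT subunits in an $N$-mer is binomial:

$$P_n(p) = \binom{N}{n} p^n (1-p)^{N-n}, \qquad N = 4 .$$

Each candidate rule declares which compositions conduct:

* **exactly_n** — only channels with exactly $n$ WT subunits conduct
  (with $n = N = 4$: any mutant subunit silences the channel, the
  dominant-negative hypothesis);
* **at_least_n** — channels with $n$ or more WT subunits conduct,
  $\sum_{k=n}^{N} P_k(p)$;
* **no_mixing** — WT and mutant subunits form separate homotetramers, so
  normalized current is the straight line $p$.

Channels failing the rule may retain a mutant residual activity
$r \in [0,1]$ (default 0), giving the predicted normalized current
$f(p) + (1 - f(p))\,r$. The residual term covers partial loss-of-function
homotetramers; with $r = 0$ the curves are the pure composition
probabilities. Per-composition conductance is binary (a channel either meets
the rule or conducts at $r$); graded intermediate conductances are outside
the family. $N$ is a parameter for generality, but 4 is the tested default.

At the 4:1 WT:mutant co-injection ($p = 0.8$) the dominant-negative rule
predicts $0.8^4 = 0.4096$ of the WT current — a $59.04\%$ decrease, i.e.
$60\%$ to the nearest ten percent; at the heterozygote-mimicking 1:1 mix it
predicts $0.5^4 = 6.25\%$ remaining current.

```{r curves, fig.width = 6, fig.height = 4}
fit <- fit_stoichiometry(data.frame(p = c(1, 0.8, 0.5, 0),
                                    y = c(1, 0.40, 0.05, 0)))
plot(fit, main = "model family vs normalized current")
```

## From raw currents to normalized points

**Extraction.** Oocytes are held at −50 mV and bathed sequentially in low-K⁺,
high-K⁺ and Ba²⁺ solutions. The Kir-specific current is the difference
`i_high_k − i_low_k`: leak and K⁺-independent components cancel. Currents are
stored signed (inward negative, µA) throughout; magnitudes are taken only at
reporting time, because sign conventions are the dominant bug class in
electrophysiology pipelines. The Ba²⁺-sensitive fraction
`(i_high_k − i_ba)/(i_high_k − i_low_k)` is reported as a specificity check —
Ba²⁺ occludes Kir channels — but is not an exclusion criterion by default,
since the Ba²⁺ bath is a verification step rather than a stated filter.

**Quality control.** Two checks on the −50…+50 mV voltage ramps:

* *Leak*: an oocyte showing outward current above 1 µA at positive
  potentials, in any solution, is discarded as too leaky. The threshold is
  strict (exactly 1 µA passes).
* *Rectification*: the Ba²⁺-sensitive ramp component (high-K⁺ minus Ba²⁺,
  pointwise) must be inwardly rectifying: its inward magnitude at −50 mV
  must exceed `r_min = 5` times its outward value at +50 mV. The ratio has
  no published value; 5 is this package's choice, exposed in the run
  configuration and logged in every report. Oocytes whose Ba²⁺-sensitive
  outward component sits below a noise floor (default 0.05 µA) pass
  vacuously — mutant-only groups legitimately produce no current and must
  not be excluded for it. Endogenous outward currents unaffected by Ba²⁺
  cancel in the subtraction by construction.

Oocytes without ramps are retained with a warning: the three-bath protocol
alone determines the difference current. QC never reads the injected WT
fraction, so exclusions cannot bias groups differentially (a property the
test suite checks by permuting group labels).

**Normalization.** Oocyte batches vary strongly in expression, so each
oocyte's |Kir current| is divided by the arithmetic mean |Kir current| of the
QC-passed WT-only ($p = 1$) oocytes *of its own batch*; normalized values are
then pooled across batches per design point and summarized as mean ± s.e.m.
(sample SD/√n). Dividing per oocyte — rather than normalizing group means
post hoc — preserves per-oocyte dispersion for the s.e.m. and for the
bootstrap. Batches without a usable WT control cannot be anchored and are
dropped with a logged reason. The injected mRNA mass fraction is taken as the
subunit fraction $p$ directly, assuming equal translation efficiency and
random co-assembly; no expression correction is applied to the x-axis.

## Model ranking

For each candidate, the root-mean-square deviation between the normalized
points and the predicted curve is computed (unweighted by default; `1/sem²`
weighting by flag) and expressed as a **percent deviation**,
$100 \cdot \mathrm{rmsd} / \mathrm{RMS}(y)$. The RMS normalizer makes the
quantity scale-free and nearly equal to $100\cdot\mathrm{rmsd}$ for data
normalized to a maximum of 1; because the convention is not universal,
`mean` and `max` normalizers are available and the choice is recorded in
every report. The normalizer is shared by all candidates, so the *ranking*
is identical under any of them. Ties are broken deterministically: fewer
fitted parameters first, then lexicographic label.

The optional residual fit minimizes the RMSD over $r \in [0,1]$ by bounded
one-dimensional minimization (tolerance $10^{-9}$), with both interval
endpoints evaluated explicitly so boundary optima are returned exactly.

Uncertainty in the winner is quantified by a bootstrap that resamples
oocytes with replacement *within each (batch, design point) cell* and reruns
normalization and ranking; resampling across batches would mix normalization
denominators. Selection frequencies are deterministic given the seed.

## The synthetic-data generator

No public dataset accompanies this assay, so the generator is a first-class,
tested module with known ground truth. Per oocyte, the Kir current magnitude
is

$$|I_\mathrm{Kir}| = s_\mathrm{batch}\, s_\mathrm{oocyte}\,
  I_\mathrm{WT} \cdot \mathbb{E}[\mathrm{activity}](p, \text{truth rule}),$$

with $s$ lognormal of mean 1 (expression is positive and right-skewed):
default CV 0.3 across oocytes and 0.5 across batches, the latter larger
because batch-to-batch variability is what motivates the normalization.
Steady −50 mV currents are $I_{\mathrm{low K}} = -\mathrm{leak}$,
$I_{\mathrm{high K}} = I_{\mathrm{low K}} - |I_\mathrm{Kir}|$, and
$I_{\mathrm{Ba}} = I_{\mathrm{low K}}$: Ba²⁺ block is modelled as complete,
matching its role as a specificity control. Ramps are built from an ohmic
leak through the origin, a strongly rectifying Kir component (reversal 0 mV
in high K⁺, sigmoidal gate of slope 10 mV, scaled so the −50 mV value equals
the configured current exactly), and an endogenous outward component at
positive potentials present in **all** solutions including Ba²⁺. A
configurable fraction of oocytes (default 10%) is "too leaky": their leak is
redrawn at 1.5–3 µA so they trip the 1 µA QC threshold. Channel-count
sampling noise is ignored — an oocyte expresses millions of channels, so
composition noise is negligible against expression noise — and only the
binomial expectation enters. Defaults place the pure-WT current at 5 µA with
design points $p \in \{1, 0.8, 0.5, 0\}$, ten oocytes per batch and group,
and three batches.

What the generator deliberately does **not** emulate: raw time series and
solution-exchange kinetics (only steady-state endpoints), partial Ba²⁺
block, voltage-dependent endogenous conductance families, or translation
differences between WT and mutant mRNA. Passing tests therefore demonstrate
correctness of the reduction/normalization/ranking chain under realistic
expression noise — not robustness to every artifact of real recordings.

## Numerical and design choices

* Binomial masses use the explicit closed form $\binom{N}{n}p^n(1-p)^{N-n}$;
  `0^0 = 1` makes the endpoints exact. The suite verifies exact agreement
  with enumeration over all ordered subunit tuples for $N \le 6$ at rational
  $p$, probability conservation on a 101-point grid at $10^{-12}$, and
  tail monotonicity.
* RMSD and percent deviation are checked to $10^{-12}$ against an
  independent direct-summation oracle on random instances.
* Dataset CSVs are written at 17 significant digits and round-trip exactly;
  `truth.json` records seed and configuration, from which the whole dataset
  regenerates byte-identically.
* Degenerate inputs: zero Kir current yields an `NA` Ba²⁺-sensitive fraction
  (flagged, not an error); an all-zero dataset makes the percent-deviation
  normalizer undefined and errors; single-oocyte groups report s.e.m. 0.

**Problem sizes in the test suite.** Statistical checks run at sizes chosen
to make their acceptance bands sharp but cheap: Monte-Carlo consistency at
200 oocytes, leak-QC rate calibration at 500 oocytes against binomial 95%
bounds, and model recovery at 200 simulated experiments per ground-truth
rule under the generator defaults with `oocytes_per_group = 10` and
expression CV 0.3 (three batches, so 30 oocytes pool into each design
point). Under those conditions the suite requires the dominant-negative and
no-mixing truths to be recovered in at least 90% of replicates and the
closer-curved at-least-2/at-least-3 truths in at least 75%; with only a
single batch of ten oocytes per point, recovery of adjacent rules degrades
substantially because the WT-denominator noise (~9.5% relative SE) is shared
by every point — worth remembering when designing real experiments with few
batches.

## Known limitations

* The percent-deviation normalizer convention is a package choice; absolute
  percent-deviation values are comparable only within one convention, though
  rankings are invariant.
* The model family assumes random assembly and equal mRNA-to-subunit
  translation for WT and mutant; systematic translation or trafficking
  differences would shift the effective $p$.
* The rectification criterion summarizes a ramp by its ±50 mV endpoints; it
  is a guardrail, not a biophysical fit of the rectification curve.
* Bootstrap frequencies quantify resampling stability, not posterior model
  probabilities.
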