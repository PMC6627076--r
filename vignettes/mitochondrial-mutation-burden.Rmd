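---
title: "Modeling the somatic mtDNA mutation burden with age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the somatic mtDNA mutation burden with age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoburden)
```

## The model

Every cell carries hundreds to thousands of copies of the 16,569 bp
mitochondrial genome, and every one of those copies is recopied many
times over a lifetime: during development, continuously through
relaxed-replication turnover (mtDNA is degraded and resynthesized even
in post-mitotic cells), and, in proliferating lineages, once more per
stem-cell self-renewal cycle. Each round of copying is performed by the
mitochondrial polymerase POLG, whose proofread error rate is uncertain
over more than an order of magnitude. The per-cell de novo mutation
burden at a given age is modeled as

$$B \;=\; G \cdot Z \cdot (X_1 + X_2 + X_3)\cdot \frac{\mu}{2},$$

where

| symbol | meaning | default at age 70 |
|---|---|---|
| $G$ | mtDNA genome length (bp) | 16,569 (fixed) |
| $Z$ | mtDNA copies per cell | $\log_{10} Z \sim$ Unif(2, 4) |
| $\mu$ | POLG error rate (per base per replication) | Unif($2.8\times10^{-8}$, $5.6\times10^{-7}$) |
| $X_1$ | developmental replication rounds | Unif(10, 80), mean 45 |
| $X_2$ | turnover replication rounds | Unif(180, 380), mean 280 |
| $X_3$ | extra rounds from proliferation | Unif(81, 101), mean 91 (0 if non-proliferating) |

The divisor 2 (the `halvingFactor`) converts the raw polymerase error
rate into an *effective* mutation rate: a newly created mutant molecule
has an even chance of being lost — segregated into the other daughter
cell at division, or degraded within one half-life in a non-dividing
cell. The halving applies to the burden model only; the per-division
mutation counts from `perDivisionMutationCount()` and
`birthBurdenRange()` are deliberately pre-segregation totals (mutations
*created*, before any loss), which is the convention behind the
familiar "0.5–9.2 new mutations per division" and "22–414 mutations at
birth" arithmetic.

### Where the replication counts come from

All round counts are exposed as plain arithmetic so they can be
re-derived for any age or assumption:

* `divisionsToCellCount(n)` = $\lfloor \log_2 n \rfloor$, the complete
  population doublings needed to grow one zygote into $n$ cells. For the
  adult estimate $3.72\times10^{13}$ this is 45. The floor is the
  conservative "at least" convention: $2^{45} \approx 3.52\times10^{13}$
  falls one doubling short of the target, so the true count is
  understated by at most one round. Developmental apoptosis is ignored;
  even 50% cell loss would add only about one round.
* `turnoverRounds(age, halfLife)` = age $\times$ 365.25 / half-life
  (days): one population-doubling-equivalent of resynthesis per elapsed
  half-life. The default half-life of 3 months (91.3125 days) gives
  280 rounds by age 70; the literature extremes of 12 days and
  12 months give 2131 and 70.
* `hscExtraRounds(age, cycle)` = age $\times$ 52.18 / cycle (weeks):
  hematopoietic stem cells self-renew roughly every 40 weeks, adding
  91 rounds by age 70.

The calendar constants (365.25 days/year, 52.18 weeks/year, 3 months =
91.3125 days) were fixed once so that all four headline counts — 280,
2131, 70 and 91 — emerge simultaneously under nearest-integer rounding;
they are ordinary conventions, not tuned quantities.

For ages other than 70, `BurdenModel(ageYears =)` scales the default
$X_2$ and $X_3$ intervals linearly (both bounds multiplied by
age/70). This recovers the age-70 intervals exactly, keeps each
interval's coefficient of variation constant, and makes the interval
midpoints track `turnoverRounds()` and `hscExtraRounds()`; $X_1$ is
developmental and does not scale. Explicitly supplied distributions are
never rescaled.

## Closed form versus simulation: the two means of Z

The closed-form expectation uses the **geometric mean** of the
copy-number distribution,

$$E(B) = G \cdot \tilde{Z}\cdot \frac{E(\mu)}{2}\cdot
\left(E(X_1)+E(X_2)+E(X_3)\right),$$

with $\tilde Z = 10^{(2+4)/2} = 1000$ — the representative "typical
cell". With the defaults this gives 1013 mutations per proliferating
cell at age 70 (and 792 for a non-proliferating cell; fixing $\mu$ at
its bounds gives 96.5 and 1930). The Monte Carlo sample mean from
`sampleBurden()` instead tracks the **arithmetic** mean of
$Z = 10^L$, which for a log10-uniform exponent is
$(10^4-10^2)/(2\ln 10) \approx 2150$, so the sample mean is about 2178
— more than twice the closed-form headline. Both are correct answers to
different questions; the package exposes `geometricMean()` and
`arithMean()` so the distinction stays visible, and
`expectedBurden()` refuses a plain-uniform copy number, for which no
geometric-mean convention is defined.

One consequence of exact arithmetic is worth flagging: with $\mu$ fixed
at its low bound, $16{,}569 \times 1000 \times 1.4\times10^{-8} \times
416 = 96.498$, which rounds to 96, not the 97 often quoted; the 97
arises from rounding the intermediate product to three digits
($0.232 \times 416 = 96.5$). The package returns the exact value.

Similarly, `birthBurdenRange()` offers a `mode = "display"` that
reproduces the headline integers 22 and 414 by following the display
arithmetic (per-division rate rounded to one decimal, multiplied by 45,
truncated); its default error-rate bounds are the raw fidelity
estimates of one error per $3.6\times10^7$ and per $1.8\times10^6$
bases synthesized, because those — not the one-significant-figure
interval bounds — are what put the per-division rate at 0.46 and 9.21
and hence the display chain at 0.5 and 9.2. The default `mode = "raw"`
keeps full precision.

## Monte Carlo design

`sampleBurden()` draws each cell's $L = \log_{10} Z$, $\mu$, $X_1$,
$X_2$, $X_3$ independently and evaluates $B$ per cell. Choices that
matter:

* **$Z$ is redrawn per cell.** The sample describes a heterogeneous
  population of cells spanning tissue types, which is what the wide
  copy-number distribution encodes; fixing one $Z$ per run would model
  a single tissue instead.
* **$B$ stays continuous.** The tail tables act on the expected burden
  as a continuous quantity. An optional `poisson = TRUE` layer draws
  integer counts $\sim$ Poisson($B$) for users who want realized-count
  noise; it is off by default.
* **Determinism.** A single generator is seeded once per call and the
  variable blocks are drawn in a documented order (all $L$, then $\mu$,
  $x_1$, $x_2$, $x_3$), so identical `(model, nSamples, seed)` give
  bit-identical samples, and a port in another language can match at
  the distribution level.
* **Sample size.** The default $n = 10^6$ puts the standard error of
  any tail probability at or below $0.0005$, comfortably inside the
  $\pm 0.01$ at which the published table is reported. Tests use
  $10^4$–$10^6$ depending on what they measure.
* **Tie handling.** A draw exactly at a threshold counts toward both
  $P(B \le x)$ and $P(B \ge x)$. For the continuous model ties have
  probability zero; for degenerate (all-fixed) configurations this
  convention makes both directions return 1 at the closed-form value,
  which is also why `sampleBurden()` multiplies its factors in the same
  order as `expectedBurden()` — so the degenerate sample equals the
  closed form to the last bit.

The empirical tails are cross-checked in the test suite against an
independent semi-analytic oracle: conditional on $(L, Y)$ the
$\mu$-integral is a clamped linear CDF in closed form, the density of
$Y = X_1+X_2+X_3$ is obtained by numeric convolution of the uniform
components, and $L$ is integrated by a fine midpoint rule. The oracle
is accurate to about $10^{-7}$, so the comparison is limited only by
Monte Carlo error.

## Heteroplasmy projection and the advantage convention

A variant with per-round effective replicative advantage $a$ multiplies
its odds by $(1+a)$ each round:

$$h_n = \frac{o_n}{1+o_n},\qquad
  o_n = \frac{h_0}{1-h_0}\,(1+a)^n .$$

The published projection scenarios never state the functional form, so
the mapping from the *stated* advantage $s$ to $a$ had to be decided.
The **halved** convention $a = s/2$ — half of each round's replicative
edge is dissipated by the same random-loss processes that motivate the
burden model's halving factor — reproduces every published outcome
simultaneously (1% at a 2% advantage reaches 14.1% after 280 rounds and
28.8% after 371; 10% reaches 64.3%, printed as ">60%"; 5% at 20%
reaches 79.3%, printed ">70%"; 1% at 5% reaches 91.0%, printed ">90%").
The **full** convention $a = s$ over-predicts drastically (72% instead
of 14% in the first scenario). Halved is therefore the default;
`convention = "full"` is retained for sensitivity analysis, and the
identity halved($s$) $\equiv$ full($s/2$) is tested exactly.
Projections are computed on the log-odds scale with `log1p`, so very
long horizons neither overflow nor lose precision, and $h_0 \in
\{0,1\}$ are honored as absorbing states. `roundsToThreshold()` inverts
the projection in closed form and then verifies the neighbouring
integers, making it immune to floating-point edge cases at the
threshold.

`segregateStochastic()` is a deliberately minimal neutral counterpart:
at each division a daughter's mutant count is Binomial($Z$, $h$) at
constant copy number. Heteroplasmy is then a bounded martingale — the
mean is conserved while variance grows and lineages absorb at 0 or 1 —
which is exactly what the tests assert. It is an illustrative
extension, not part of the published projections: real segregation
involves organelle-level packaging, copy-number fluctuation and
selection, none of which are modeled.

## What the simulator does and does not show

The generator's defaults *are* the published study conditions: all
acceptance-bearing numbers (the 1013/97/1930 expectations, the
ten-row tail table, the projection scenarios) are recomputed from those
conditions at run time by `scripts/acceptance.R` and the test suite,
with $n = 10^6$ cells per class for the tail table. Passing these
checks shows the arithmetic and sampling are right; it says nothing
about whether the assumptions describe real tissues. In particular:
parameters are independent (in reality copy number, turnover and error
rate co-vary by tissue and age); uniform and log-uniform intervals are
maximum-ignorance choices, not fitted distributions; the model counts
expected point mutations and ignores deletions, clonal expansion,
selection against dysfunctional cells, and the germline bottleneck. The
mutation burden here is a per-cell expectation — it should not be read
as the heteroplasmy of any single variant.

## Configuration and outputs

`runBurdenReport()` (and the `inst/scripts/mitoburden` command-line
wrapper) resolves a JSON configuration mirroring the model fields,
computes the expectation report, tail table, reversed CDF, histogram
and drift projections, and writes them as TSV/JSON with the seed and an
md5 of the resolved configuration in every header, plus a manifest.
Validation happens before anything touches the filesystem, so a failed
run writes nothing; re-running from a written `config.json` at the same
seed reproduces every output byte for byte.
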