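---
title: "Topological asymmetry of paired images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological asymmetry of paired images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revasym)
```

## The measurement model

`revasym` treats a greyscale image as a field $z(i,j)$ on an $N \times M$
pixel lattice and filters it by sublevel sets: at threshold $l$ the cubical
complex contains every pixel with $z \le l$, every 4-neighbour edge at the
maximum of its endpoints, and every unit square at the maximum of its four
corners (the vertex construction). This family is nested and non-decreasing
in $l$, which is the property persistence needs; the package resolves the
choice between "remove pixels below $l$" and a growing family in favour of
the latter, since only it yields a filtration. Dark structures — vessels on
a bright fundus background — therefore appear first and drive the early
topology.

Persistent homology in dimension 0 (components) and 1 (loops) yields
diagrams of (birth, death) pairs. Three conventions make the downstream
summary well defined:

* **Essential class.** The one component that never dies is assigned
  death = the image's maximum pixel value, so all lifetimes are finite and
  summable. Any global convention adds the same constant to both sides of a
  pair comparison, so the asymmetry statistic is insensitive to it.
* **Zero-lifetime points.** Pairs with birth = death carry no persistent
  information and contribute nothing to the summary; they are dropped by
  default (`drop_zero = TRUE`), which also keeps degenerate inputs tidy — a
  constant image has exactly one diagram point in dimension 0 and none in
  dimension 1. They can be retained for bookkeeping.
* **Intensity transform.** Images are put on a common scale before
  filtration: `unit` (min–max to $[0,1]$, the default) or `z` (global
  standardisation). Both are tagged on every diagram; a constant image maps
  to all zeros under either (with a warning for `z`, whose denominator is
  then undefined).

Each diagram is re-expressed as mean-age/lifetime pairs
$m_i = (b_i + d_i)/2$, $l_i = d_i - b_i$ and summarised by the accumulative
persistence function $\mathrm{APF}_k(m) = \sum_i l_i \, 1(m_i \le m)$, a
right-continuous non-decreasing step function stored by its breakpoints.
The asymmetry of a pair is the signed value of
$D(m) = \mathrm{APF}_{k,R}(m) - \mathrm{APF}_{k,L}(m)$ at the location of
its largest magnitude. Because $D$ is piecewise constant, the supremum is
attained on the union of the two breakpoint sets — no grid approximation is
needed — and ties are broken toward the smallest $m$ for determinism. The
argmax is taken over $|D(m)|$ rather than $D(m)$: this makes the measure
symmetric between left-dominant and right-dominant asymmetry and negate
exactly under argument swap, while still reporting a signed value. For
identical inputs the statistic is exactly zero, by construction rather than
by numerical tolerance.

## Algorithms and their verification

Dimension 0 is computed by a union-find sweep over edges in increasing
filtration order with the elder rule (ties broken by cell index, so the
pairing is deterministic; the resulting diagram is invariant to such
choices). Dimension 1 uses the dual graph: on a planar grid no set of
squares has empty boundary, so every square kills a loop, and sweeping the
faces-plus-outer-node graph in *decreasing* order pairs each loop's edge
birth with the value of the oldest face of the complement region it
bounds. Both sweeps are $O(n\,\alpha(n))$ in compiled code.

Correctness is checked against an independent oracle written in plain R:
flood-fill component counting plus the Euler characteristic
($b_1 = b_0 - (V - E + F)$) on the explicitly materialised complex. The
test suite verifies, on random integer-valued images, that the Betti
counts implied by the diagrams match the oracle at every threshold in both
dimensions, along with shift-equivariance (adding a constant shifts all
births and deaths by it) and invariance under grid reflections. The oracle
deliberately refuses images above 10,000 pixels — it exists to be obviously
correct, not fast.

## What the synthetic data emulate

The image generator draws a stylised retinal vasculature: bright
background (0.85) with Gaussian pixel noise (sd 0.02), a brighter optic
disc, and a dark recursive bifurcation tree whose branch length, width and
contrast decay geometrically with depth (defaults: 3 trunks, 5
generations, first-generation contrast 0.55). These defaults were chosen
once to give images rich component and loop structure at 64×64 and are
not tuned further. A left/right pair shares one node-indexed matrix of
random draws; the right image regrows the tree from those draws perturbed
by independent zero-mean noise of scale $a$, so geometry diverges
coherently down the tree while pixel noise stays shared. At $a = 0$ the
two fields are bit-identical — the zero law then follows analytically —
and larger $a$ yields progressively different vasculature, which is the
behaviour the monotone-response test quantifies.

The cohort generator encodes the study conditions the downstream stages
assume: three sub-cohorts sampled 617 : 470 : 786 with cohort-specific age
distributions, 60.5% women, a comorbidity count 0–5, and a 3.15% fraction
excluded from audiometry for unilateral hearing loss. A log-normal latent
propensity $u$ (sdlog 0.4) scales every trait's signed left–right
difference, which is split symmetrically around the trait's base value —
fluctuating asymmetry, mean zero by construction. The two retinal scores
are driven by $u$ through strongly correlated latent draws, as two
homology dimensions of one vasculature would be. ROH segment counts are
Poisson with rate linear in $u$; the slope
$b = r\sqrt{\mu_c/(1-r^2)}/\mathrm{sd}(u)$ makes the propensity–count
correlation equal the target $r$ (default 0.229) in expectation — a
closed-form calibration with no fitting loop. Survival times are
exponential with log hazard ratios 0.0953 per year of age, −0.635 for
women and 0.182 per comorbidity, under independent exponential censoring
that leaves roughly 40% of subjects with events.

What the generator does *not* emulate: optical distortions, illumination
gradients, registration error between eyes, vessel calibre physiology,
genotype-level structure behind the ROH summaries, or non-proportional
hazards. Passing tests therefore demonstrate the pipeline's internal
correctness and statistical calibration under its stated model, not
robustness to real acquisition artefacts.

## Downstream conventions

Signed residuals are `left − right`; the alternative reading
(deviation from the midpoint) differs by a factor of 2 that the
max-normalisation cancels, so the choice is observationally neutral
downstream. Normalisation divides each trait's absolute residuals by the
trait maximum, so values lie in $[0,1]$ and exactly one subject (barring
ties) attains 1; an all-zero trait stays at zero with a warning. Group
means average the normalised values within retina, ophthalmic,
ankle–brachial and audiometry groups; a subject missing every trait in a
group has no mean there and cannot be flagged for that group. Top-decile
flags use the type-7 empirical quantile with a `>=` rule, so threshold
ties are all flagged and the classification is order-independent;
classification refuses groups with fewer than 10 subjects. Under
independent group asymmetries the expected multi-asymmetry fraction has
the closed form $1 - 0.9^4 - 4(0.1)(0.9^3) \approx 0.0523$, which the
suite verifies by simulation at $n = 10{,}000$; a shared propensity
raises it.

The correlation and survival stages call the standard routines
(`cor.test`, `t.test`, `aov`, `chisq.test`, `survival::coxph`) behind
stable tidy contracts; no multiple-testing correction is applied by
default (a `BH` option exists). Cox models use men, the `Vis` sub-cohort
and "no multiple asymmetries" as reference levels, enter comorbidity as a
numeric 0–5 count, drop incomplete records listwise (logged), and refuse
fits with fewer than 10 events.

## Problem sizes and determinism

The validation suite runs the oracle comparison on 100 random images up
to 12×12, the zero law on 20 generated images, antisymmetry on 50 pairs
at 48×48, the monotone response over 50 seeds per asymmetry level
$\{0, 0.1, 0.3, 0.5\}$ at 64×64, the overlap closed form at
$n = 10{,}000$, and Cox coverage over 100 cohorts of $n = 1800$ — sizes
chosen so each property is measured with useful Monte-Carlo precision
while the whole suite stays quick on one core. Every stochastic function
takes an explicit seed, restores the caller's RNG state, and one pipeline
seed fans out to fixed per-stage child seeds, so full runs are
byte-reproducible.

## Known limitations

Dimension-1 persistence relies on planarity and 4-connectivity; other
connectivities or 3-D stacks would need a different killing-cell argument.
The supremum statistic compares accumulated persistence, not feature
correspondence: two images with equal APFs but differently placed features
score zero. The max-normalisation makes asymmetry estimates
cohort-relative — adding a subject with extreme asymmetry rescales
everyone — which is faithful to the analysis design but means values are
not comparable across cohorts. The vessel generator is a topological
stand-in, not a vascular growth model.
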