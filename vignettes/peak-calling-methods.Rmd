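---
title: "Control-free peak calling from three lines of evidence: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-free peak calling from three lines of evidence: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaktriad)
```

# The problem

A transcription-factor (TF) ChIP-Seq experiment sequences the two ends
of immunoprecipitated DNA fragments; mapping those short reads gives a
set of *tags*, each reduced here to a chromosome, a 0-based 5'
position, and a strand. Enriched tag counts can arise from four
mechanisms: true TF binding, focal amplification of genomic segments,
nonspecific protein–DNA binding, and random procedural noise. Input
controls cannot subtract nonspecific binding — a TF spends most of its
time diffusing along DNA — and in the dataset family this method was
designed for, the ChIP and input samples share well under 1% of their
fragments, so the input is not a representative local control anyway.
`peaktriad` therefore works from the ChIP sample alone and
discriminates the mechanisms by *shape* and *sequence*, not only by
*amount*.

The one experimental parameter the method leans on is `d`, the maximum
fragment size selected during library preparation (default 250 bp). It
is known, not estimated: a fragment spanning a binding site has its
forward 5' end at most `d` bp upstream of the site and its reverse 5'
end at most `d` bp downstream. `d` is used as both the genome bin
width and the sliding-window width.

# Count model and empirical FDR

Window counts of unique tags are modelled by a Gamma-Poisson mixture —
a Poisson rate with Gamma variation across windows, i.e. the negative
binomial

$$P(X = x) = \binom{x+r-1}{x} p^r (1-p)^x,\qquad
  \mathrm{E}[X] = \frac{r(1-p)}{p},\quad
  \text{dispersion } \frac{r(1-p)}{p^2},$$

zero-truncated to `x ≥ 1` (division by `1 − p^r`) because zero counts
confound true emptiness with non-mappability. The maximum-likelihood
fit uses BFGS on `(log r, logit p)` — both parameters unconstrained on
that scale — initialized from method-of-moments on the truncated
sample, with a `1e-10` relative tolerance on the likelihood; a
zero-truncated Poisson is fitted alongside for comparison (AICs are in
the fit report). The last, partial window of each chromosome is kept;
at `d = 250` the bias is negligible.

For each count threshold `k` the *empirical FDR* is the theoretical
number of windows exceeding `k` under the fitted background,
`N_total · Pr(X > k)`, over the observed number exceeding `k`, clipped
to `[0, 1]`. `Pr(X > k)` uses the truncated distribution, so
`Pr(X > 0) = 1` (the truncated support starts at 1) — the one place
the truncation convention matters. The selected threshold is the
smallest `k` with `eFDR(k) ≤ α` (default `α = 0.5`: deliberately
permissive, because the candidate set is re-ranked afterwards and the
final cut restores the FDR). Above-threshold windows that share a
boundary merge into potential binding regions (PBRs).

# Peak evidence

Each PBR, extended by `d` bp per side (a site near a PBR edge has
informative tags up to `d` bp away), is scanned base pair by base pair
with a window of width `d`, counting forward and reverse tags
separately. The count evidence `p_c` is the truncated upper-tail
probability `Pr(X ≥ peak count)` of the combined (F + R) peak. The
binding-site coordinate is estimated as the midpoint between the
downstream edge of the forward-peak window and the start of the
reverse-peak window; argmax ties break leftmost. With ~25 tags per
strand this estimate is typically within ±25 bp of the true site,
which is why the motif stage extracts ±20 bp and not less.

# Pattern evidence

For a true site the difference `S = F − R` rises to a positive lobe
upstream of the site, crosses zero at it, and falls to a negative lobe
downstream. The reference shape is *simulated*, not learned: 3×10⁶
fragments of length uniform on [150, 250] bp uniformly placed on a
1 kb region with one central site, retained with probability 0.1% when
they span the site and 0.005% otherwise, each sequenced from a random
end. Both the reference and every observed pattern are denoised by a
maximal overlap discrete wavelet transform with the 8-tap
least-asymmetric (la8) filter and hard thresholding. Numerical
choices, none of which the transform's definition fixes: reflection
boundary handling (the signal is mirrored before the circular
transform), decomposition depth `min(4, ⌊log2 n⌋)`, and the universal
threshold `σ̂·sqrt(2 ln n)` with `σ̂ = MAD(finest detail)/0.6745` —
the standard companion of hard thresholding. The MODWT is implemented
in the package (pure R); its perfect-reconstruction property is
verified in the test suite.

The dissimilarity `d_p` amplitude-normalizes both patterns to
`max |S| = 1`, maps the observed global peak and trough onto the
reference's by an affine position transform, resamples by linear
interpolation at the `n` reference positions (constant extrapolation
beyond the ends — `n` is fixed, so scores are comparable across
regions), and sums absolute differences. A flat pattern, or one whose
trough does not follow its peak, is not a binding-site shape and
receives the cap `2n`, the supremum of the sum for amplitude-bounded
patterns. Focal amplification enriches both strands symmetrically, so
its `S` hovers around zero and scores near the cap — this is the
stage that removes count-strong confounders.

# Motif evidence

Candidate regions strong on both previous scores provide ±20 bp
sequences around their site estimates (at most 500; each ~41 bp, so a
zero-or-one-occurrence assumption per sequence is reasonable). The
in-package ZOOPS EM treats the occurrence (position × strand, or
absence) as the hidden variable: the E-step computes its posterior
under the current matrix, site prior γ, and 0-order background
estimated from the input; the M-step re-estimates the matrix with a
0.1 pseudocount per cell and γ. Iteration stops at `|Δ log L| < 1e-6`
or 200 iterations; the best of several starts wins, each start seeded
from a randomly chosen w-mer (match probability 0.5). The default
width 9 suits GAS-like TF motifs; both strands are searched since TF
motifs are strand-agnostic. A motif is accepted when at least 25% of
input sequences contain it (posterior > 0.5) — inclusive at the
boundary.

Scanning computes the log-odds score of the matrix against the 0-order
background at every position and strand of each PBR sequence. The
best-hit p-value `p₁` comes from the *exact* null distribution of the
per-window score, computed by dynamic-programming convolution of the
per-column score distributions discretized at 1e-3; the region-level
`p_m = 1 − (1 − p₁)^m` corrects for the `m` scanned windows. The DP
distribution is validated against exhaustive enumeration of all `4^w`
words in the tests.

# Integration and the two-step FDR

Scales differ by orders of magnitude (`p_c` can reach 1e-30, `p_m`
rarely passes 1e-5), so `ln d_p` (with ε = 1e-6, since `d_p` can be 0)
and `ln p_m` are rescaled to the level of `ln p_c` by
quantile-matching ordinary least squares: regress the sorted `ln p_c`
vector on each sorted score vector and apply the fitted affine map
per region. This was a genuinely open design point; quantile OLS was
chosen because it aligns location and scale while preserving each
score's internal ranking, and it is exactly invariant under affine
transforms of a log score (not under arbitrary monotone transforms —
no averaging scheme is). When the log-score distributions have
comparable shapes the rescaled mean matches exactly and the variance
within a few percent. The combined score is the mean of the three
(or of two, with a prominent log message, when no motif was
accepted), ranked ascending with ties broken by `p_c` then genomic
order.

The final cut takes the top `(1 − α) · N` regions. Because the
candidate pool was assembled at eFDR α and re-ranking is a
permutation, the expected true-positive fraction of the pool — and
hence the FDR of the final set — is unchanged by the re-ordering; the
re-ranking only decides *which* regions occupy the accepted slots.
Both `floor` and half-away-from-zero rounding of `(1 − α) · N` are
supported (configurable; default half-away-from-zero) because either
convention is defensible and published analyses have used both.

# The synthetic-data generator

`generate_dataset()` emulates all four enrichment mechanisms so that
every stage has labelled truth to be tested against:

* **Sites.** A uniform i.i.d. ACGT genome with a consensus motif
  (default `TTCCGGGAA`, per-base mutation rate 0.1) written at
  non-overlapping positions kept clear of confounder intervals.
  Fragments spanning a site are retained with probability 1e-3.
* **Amplifications.** Intervals whose overlap multiplies the
  background retention (default fold 10) on both strands
  symmetrically — strong counts, no strand shift, no motif.
* **Nonspecific/artifact hotspots.** The same mechanism (default fold
  12) but present on *every* chromosome, including the decoy: real
  data shows apparent enrichment even on chromosomes absent from the
  sample, from mapping artifacts and nonspecific pull-down. These are
  the regions a count-only ranking cannot reject.
* **Background.** Fragment starts at base retention 5e-5, modulated by
  a piecewise-constant Gamma rate field (mean 1, shape 5, 250-bp
  tiles). The field matters: nonspecific binding makes real ChIP-Seq
  background overdispersed — that is why the background model is
  Gamma-Poisson and not Poisson — and without it the fitted
  dispersion would have nothing to describe but the signal itself.
  Setting the shape to `Inf` gives a homogeneous Poisson background
  (the fitted excess dispersion then collapses toward zero, which the
  tests assert).

Default problem size: three 500 kb chromosomes plus a 500 kb decoy
(8,000 windows at `d = 250`), 10 sites, 5e8 nominal fragments. These
sizes were chosen to reproduce, at desk scale, the operating regime
the method assumes on real data: ~3 background tags per window
(typical TF ChIP-Seq coverage), ~95% of windows with six or fewer
tags, enriched windows confined to the right tail at well under 1% of
nonzero windows, and ~50 tags per site. Materially smaller genomes do
not merely weaken the test — they change the statistics: with
enrichment in more than a few percent of windows, the ML fit absorbs
the signal tail into the background and the empirical FDR loses its
meaning. Retention is simulated by its thinned equivalent (binomial
retained counts per probability class, placed from the
class-conditional law), which coincides with per-fragment thinning in
the Poisson limit that holds at these retention probabilities and
makes generation effectively instantaneous; the reference-pattern
simulation keeps the direct per-fragment form.

What the generator does **not** emulate: realistic base composition
(motif scanning on real genomes faces repeat-driven false hits),
sequencing errors, paired-end structure, mappability gaps, and
copy-number structure more complex than a flat fold. Passing tests
therefore demonstrate the algorithmic machinery under the model's own
assumptions, not performance on any particular organism.

# Degenerate inputs and numerical conventions

* Histograms with fewer than two distinct positive counts refuse to
  fit; thresholds that no `k` attains raise an error suggesting a
  larger α.
* Regions shorter than `d` after extension yield degenerate profiles;
  patterns shorter than 16 positions skip wavelet smoothing and are
  compared raw; all-zero patterns take the `2n` penalty.
* With fewer than 3 regions the integration falls back to ranking by
  `p_c`; with fewer than 10 regions the high-quality selection uses
  everything, with warnings.
* All interval arithmetic is 0-based half-open (BED-native); reverse-
  strand 5' ends are `end − 1`. Duplicate tags are removed exactly by
  (chromosome, position, strand).
* Every stochastic step is driven by one integer seed; same-seed runs
  are byte-identical, which the acceptance checks verify with file
  checksums.

# Known limitations

In-pipeline motif discovery needs tens of clean input sequences;
below that, ZOOPS EM can converge to an overfit motif that all
sequences "contain" (the acceptance threshold of 25% then does not
filter). On real-scale data the high-quality set has hundreds of
sequences and the published workflow reported motif occupancy around
59%; at desk scale the pattern score carries most of the
confounder-rejection burden, and the tests reflect that. The
two-parameter background cannot represent chromosome-specific rates
(a deliberate non-goal), and the reference pattern assumes one site
per region — closely spaced sites produce composite shapes that score
poorly.
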