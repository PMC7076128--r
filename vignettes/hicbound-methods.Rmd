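---
title: "Spectral boundary scores and differential TAD boundary analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral boundary scores and differential TAD boundary analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicbound)
```

## The model

A chromosome's Hi-C contact matrix $C$ records interaction counts between
pairs of fixed-size genomic bins. Topologically associated domains (TADs)
appear as diagonal blocks: bins inside a domain interact with each other
much more than with bins outside. `hicbound` treats $C$ as the weighted
adjacency matrix of a contact graph and locates domain *boundaries* — the
junction bins between blocks — from the spectrum of the normalized form

$$\bar L = D^{-1/2}\, C\, D^{-1/2}, \qquad D = \mathrm{diag}(\mathbf 1^{T} C).$$

The two eigenvectors of $\bar L$ with the largest absolute eigenvalues,
collected as the $n\times 2$ matrix $\bar V$, summarize each bin's contact
pattern. After scaling the columns of $\bar V$ to unit norm and projecting
each row onto the unit circle, the **eigenvector gap**

$$ D_i = \lVert \tilde Z_{i\cdot} - \tilde Z_{(i-1)\cdot} \rVert_2 \in [0, 2] $$

measures how abruptly the contact pattern changes between neighbouring
bins. Inside a domain consecutive rows are nearly parallel and the gap is
small; at a domain junction the projected rows swing apart and the gap
spikes. The first bin has no left neighbour and carries a placeholder
(`NA`), so an $n$-bin matrix yields $n-1$ gaps.

Gap magnitudes are well approximated by a log-normal distribution, so gaps
are standardized on the log scale into **boundary scores**

$$ B_i = \frac{\ln D_i - \mu}{\sigma}, $$

with $\mu,\sigma$ fitted on the profile itself. A bin is called a boundary
when $B_i \ge t_b$ (default $t_b = 3$); the call is one-sided, since a
boundary is by definition a large gap. The score's magnitude is directly
interpretable as boundary strength.

### Sliding windows

Long-range contacts decay as a power law and contribute mostly noise, so
the spectrum is computed in windows sliding along the diagonal. The window
parameter $w$ (default 15 bins) is a *radius*: only matrix values within
$w$ bins of the diagonal enter the calculation, i.e. each spectral window
spans $\min(2w+1, m)$ consecutive retained bins. Windows overlap by half
their span, the final window is right-aligned, and each bin takes its gap
from the window whose centre is nearest (earlier window on ties). With the
radius covering all retained bins the profile equals a single dense
decomposition — the anchor property the test suite checks to $10^{-10}$.

We note the window parameter is sometimes paraphrased as a window of $w$
consecutive bins. That reading makes the absolute cutoff $t_b = 3$
essentially unreachable (see *Limitations*); the band-radius reading is
the one under which the default thresholds behave as documented.

### Non-informative bins

Bins with fewer than 20% non-zero interactions within the window band are
unstable in the spectral step and are masked before analysis. When two or
more matrices are compared the masks are combined with a logical AND
(`harmonize_masks()`), so bins compare one-to-one.

## Differential boundary score

For matrices $P$ (of interest) and $R$ (reference), with
$\ln D_P \sim N(\mu_P, \sigma_P^2)$ and $\ln D_R \sim N(\mu_R, \sigma_R^2)$,
the per-bin difference of log gaps is normal, giving the standardized
**differential boundary score**

$$ DB_i = \frac{(\ln D_{P,i} - \ln D_{R,i}) - (\mu_P - \mu_R)}
               {\sqrt{\sigma_P^2 + \sigma_R^2}} \sim N(0, 1) $$

under no change. $DB$ is antisymmetric in its arguments. Bins with
$|DB_i| \ge t_d$ (default 2, two-sided nominal rate
$2\,(1-\Phi(2)) \approx 0.0455 < 0.05$) are differential. An equivalent
algebraic form writes $DB$ in terms of boundary scores defined with a
*variance* denominator; the test suite verifies both forms agree to
$10^{-12}$. For reporting, boundary scores use the standard-deviation
denominator, which is what makes them unit-variance Z-scores.

### Change taxonomy

Each retained bin is classified from the two boundary flags and $DB$:

1. no boundary in either matrix → `NonBoundary`;
2. boundary in both → `StrengthChange` if differential, else
   `NonDifferential`;
3. boundary in exactly one matrix, not differential → `NonDifferential`;
4. boundary in exactly one matrix, differential:
   a. the other matrix has a boundary at a different bin within $s$ bins
      (default 5) → `Shifted`;
   b. otherwise, if the nearest called boundaries on both sides are
      *shared, non-differential* boundaries (present in both matrices) —
      i.e. the changed bin lies inside a conserved domain — the bin is
      `Merge` when its boundary exists only in $R$ (it disappeared in $P$,
      merging $P$'s domains) and `Split` when it exists only in $P$;
   c. otherwise → `Complex`.

Two choices here were genuinely open. First, proximity (`Shifted`) takes
precedence over `Merge`/`Split`/`Complex`: a nearby boundary in the other
matrix is the cheapest, most specific explanation of a one-sided call.
Second, the merge/split orientation is fixed by declaring the first
argument the matrix of interest; swapping the arguments exchanges the two
labels exactly and fixes all others, a symmetry the tests enforce.

## Consensus and group comparison

Across replicates, the **consensus boundary score** of a bin is the median
of its replicate scores (midpoint median for even counts). A *union*
boundary is called in at least one replicate; a *consensus* boundary has
median score $\ge t_b$. Consensus boundaries are always a subset of the
union and filter out single-replicate noise; on noisy replicate
simulations the suite checks consensus precision strictly exceeds union
precision at a matched threshold.

Group comparison (`compare_groups()`) aggregates on the *gap* scale: the
per-bin median of log gaps within each group forms a consensus pseudo-gap
profile, and $\mu, \sigma$ are refitted on that profile before computing
$DB$. Aggregating gaps rather than Z-scores keeps the $DB$ formula
well-defined on the aggregated object; a score-scale alternative is
available via `aggregate = "score"`. With single-matrix groups the result
reduces exactly to `tad_compare()`.

## Time courses

With at least three ordered time points (each possibly replicated),
per-time-point consensus scores yield a presence vector per bin
(presence = score $\ge t_b$). Union boundaries (present at $\ge 1$ time
point) are classified into six patterns. For exactly four time points an
exact lookup is used: 1111 and 1011 are `HighlyCommon`; 0111
`EarlyAppearing`; 1000 `EarlyDisappearing`; 0011 and 0001 `LateAppearing`;
1100 and 1110 `LateDisappearing`; everything else — including 1101, which
a "present in three of four" rule would call common — is `Dynamic`, the
published lookup being authoritative. For other lengths, rule-based
analogues apply (see `?classify_temporal`). Only presence vectors drive
the classification; full score trajectories are returned so users can
apply their own baseline-deviation analyses.

## Colocalization testing

Boundary sets are tested for enrichment in annotation tracks (CTCF, RAD21
and similar marks co-locate with TAD boundaries) by permutation. Each
boundary bin is flanked by 50 kb on both sides (clipped at zero) and the
observed statistic is the difference between the mean per-region peak
count over the flanked targets and over the flanked complement. Each of
`n_perm` permutations (default 10,000) redraws a target-sized bin set
without replacement and recomputes the same statistic. The p-value uses
the add-one convention $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}} + 1)$,
which keeps $p \in (0,1]$ and counts ties conservatively against
significance. Depletion is flagged when the observed statistic falls below
the permutation median. All randomness flows through an explicit seed.

## The synthetic generator

`simulation_spec()` plants domain structure explicitly: expected counts

$$ E[C_{ij}] = \text{base} \cdot (|i-j|+1)^{-\alpha} \cdot
   \prod_{b \text{ crossed}} \beta_b, $$

where $\alpha > 0$ is the distance-decay exponent (default 1, the
canonical Hi-C decay), and each planted boundary $b$ attenuates contacts
crossing it by $\beta_b \in (0,1)$. Optional Poisson sampling and a
sparsity knob (a fraction of off-diagonal bin pairs zeroed symmetrically)
emulate finite and shallow sequencing. The generator reproduces the two
features the boundary score keys on — block contrast and distance decay —
but *not* several features of real Hi-C: no nested sub-domains or loops,
no correlated (over-dispersed) noise, no coverage biases that matrix
balancing would normally remove, and chromosome lengths far below real
ones. Passing tests therefore demonstrate correctness of the machinery
and recoverability of planted structure at desk scale, not performance on
real chromosomes.

Validation problem sizes: the recovery study uses $n \in \{60, 100, 150\}$
bins with boundaries at interior quarter positions over
$\alpha \in \{0.8, 1.0, 1.2\}$ and $\beta \in \{0.2, 0.3\}$ — the
strong-insulation regime (≥ 70% depletion of cross-boundary contact)
typical of clearly resolved TAD boundaries. The change-scenario and
time-course studies use $n = 150$ with 15-bin domains ($\approx 600$ kb at
40 kb resolution) and $\beta = 0.15$. Null calibrations use 200 seeded
permutation runs and eight independent same-specification simulation
pairs under Poisson noise with 10% sparsity.

## Numerical choices

* **SD convention.** $\mu, \sigma$ use the population (divide-by-$N$)
  convention: scores are descriptive standardizations of the observed
  profile, not inferential estimates. `sd_type = "sample"` is available.
* **Zero gaps.** Identical consecutive projected rows give $D_i = 0$,
  whose log is undefined; such gaps are floored to the smallest positive
  gap in the profile, with a warning. An all-constant profile
  ($\sigma = 0$) is an error.
* **Eigenvector sign.** Gaps are invariant to global sign flips of either
  eigenvector column; signs are nevertheless fixed deterministically
  (largest-magnitude entry positive, earliest index on ties) so serialized
  spectra are reproducible.
* **Degenerate spectra.** Matrices with exactly repeated eigenvalues
  (e.g. a perfectly uniform matrix) have no preferred eigenbasis; gap
  profiles on such inputs are basis-dependent and not meaningful. Real
  and simulated decay matrices are not degenerate.
* **Ties in window assignment** go to the earlier window; the final
  window is right-aligned so every retained bin is covered.

## Limitations

* **Score ceiling at small $n$.** The eigenvector gap is bounded by 2, and
  the junction chord between two connected blocks is near $\sqrt 2$, so
  $B_i \le (\ln\sqrt 2 - \mu)/\sigma$. On short matrices (tens to a
  couple of hundred bins) with a handful of boundaries this ceiling sits
  near 3–3.5: weakly insulated boundaries ($\beta \gtrsim 0.5$) fall
  below the default cutoff even at zero noise, although they remain the
  top-ranked bins with no interior false positives. Users analysing short
  regions should interpret scores relative to their profile, or lower
  $t_b$, rather than treat 3 as universal.
* **Strength changes need headroom.** A bin called a boundary in *both*
  matrices is confined to the narrow log-gap band between the cutoff and
  the ceiling, so $|DB| \ge 2$ for a strength change requires the ceiling
  to sit well above $t_b$ — i.e. chromosome-scale data. At desk scale the
  `StrengthChange` label is effectively unreachable (its negative
  control — no false strength calls — is what the suite verifies), and on
  real data it is expected to be the rarest category.
* **Absolute thresholds under noise.** Poisson noise broadens the gap
  bulk and lowers all Z-scores; at desk scale noisy simulations rarely
  reach $B \ge 3$. Noisy validation studies therefore use matched lower
  thresholds; threshold-free quantities ($DB$ calibration, rankings) are
  unaffected.
* **Boundary-level, not domain-level.** The package scores and compares
  *boundaries*; it does not assemble boundaries into TAD calls, handle
  nested hierarchy, or normalize matrices (ICE/KR should be applied
  upstream if desired — the method accepts non-integer counts).
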