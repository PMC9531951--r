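---
title: "Classifying and identifying membrane proteins from SMFS force-distance curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and identifying membrane proteins from SMFS force-distance curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfsid)
```

## The setting

Single-molecule force spectroscopy on a native membrane patch produces
thousands of retraction force-distance curves, of which only a small
fraction record the unfolding of a single membrane protein. Each genuine
unfolding trace is a sawtooth: a ladder of worm-like-chain (WLC) branches,
one per metastable intermediate, each ending in a rupture. The analysis
problem is threefold: recognise the physically meaningful traces, group
recurrent unfolding patterns into clusters without knowing how many proteins
are present, and attach a molecular identity to each cluster using only
desk-side information (a mass-spectrometry proteome with topology
annotations).

`smfsid` implements that pipeline as five processing blocks plus a Bayesian
identification stage, with a synthetic-data generator that stands in for the
instrument.

## The WLC transformation and its assumptions

The backbone of the quality assessment is the interpolation form of the WLC
model,

$$F(x) = \frac{k_B T}{l_p}\left[\frac{1}{4}\left(1 -
\frac{x}{L_c}\right)^{-2} - \frac{1}{4} + \frac{x}{L_c}\right],$$

with persistence length $l_p = 0.4$ nm for unfolded polypeptide and
$T = 297$ K. We use the standard form whose constant term is $-\tfrac14$, so
that $F(0) = 0$; the $+\tfrac14$ variant occasionally seen in print (which
has a spurious nonzero force at zero extension) is available through
`wlc_params(constant_term = 0.25)` for comparison. The model is trusted only
between 30 and 500 pN; outside that window no contour length is computed and
the point simply drops out of the histograms. Inversion to $L_c$ is done by
Brent root finding on the relative extension $t = x/L_c$, which is monotone,
bracketed and converges to machine precision (the suite checks a round-trip
residual below $10^{-6}$ nm on $10^4$ random points).

## Preprocessing choices

* **Tail definition.** Baseline statistics use the final 20 % of each trace
  (at least 50 points). This is a compromise for typical 1000–3000-point
  acquisitions: enough points for a stable standard deviation, far enough
  from the unfolding region.
* **Contact point.** We take the negative-to-positive zero crossing at the
  *smallest* separation whose whole negative segment dips below
  $-\min(\max(2\sigma, 5), 30)$ pN. The depth requirement separates the
  adhesion excursion at contact from baseline-noise crossings; the depth cap
  matters for wavy-tailed traces whose inflated noise estimate would
  otherwise mask a genuine 45-pN adhesion dip; and taking the smallest
  separation matters because rupture valleys inside the sawtooth also cross
  zero from below. Traces without such a crossing are rejected as
  `no_contact`.
* **Grid.** Forces are linearly interpolated on a 1-nm grid; the grid is
  fine relative to instrument sampling, and the 8-nm histogram bin is the
  actual smoother in the chain. The force-range filter (5000 pN) is applied
  to the raw points rather than the grid, because interpolation dilutes
  single-point excursions.
* **Trace length.** Wherever a per-length normalisation appears (the quality
  ratio, the alignment prefilter), length means grid points from contact to
  the last point above 30 pN. Including the unfolding-free tail would dilute
  every quality ratio below the 0.5 cut.

## Quality scoring

Contour-length histograms use 8-nm bins anchored at zero. Local maxima are
meaningful when they hold more than five points and more than 1 % of the
trace's valid force measures. Flanking minima are found by walking outward
until the counts rise; the histogram edge counts as a zero-density flank, so
a boundary peak can still score 1. The peak score $W = e^{-2f^2}$, with $f$
the mean flank-to-peak density ratio, is assigned to all points under the
peak; sub-30-pN points (where no contour length exists) inherit the score of
the next point above 30 pN when it lies within 75 nm. Valley bins between
two peaks belong to neither peak and score zero. A trace is kept when its
summed score divided by its length reaches 0.5.

## Distances, clustering

Pairs of traces are aligned by global dynamic programming on the 1-nm force
profiles with match score $1 - \Delta/F_\mathrm{scoring}$ (mismatch branch
$-\Delta/F_\mathrm{scoring}$) and a zero gap penalty; the distance is
$d_{ab} = 1 - SD/N_\mathrm{max}$. Zero gap cost keeps $SD \le N_\mathrm{max}$
for genuinely similar traces while length mismatch is still penalised
through $N_\mathrm{max}$; the DP kernel is the one compiled routine in the
package. Distances are only computed for pairs differing by at most two
meaningful peaks *and* at most 20 % in trace length. We read the
either/or phrasing of that prefilter as a conjunction — a disjunction would
exclude almost no pair and defeat its purpose — and expose
`prefilter = "or"` for the literal reading. Distances are not clamped at 1;
grossly dissimilar computed pairs may exceed it, which the log-density
handles naturally.

Density-peak clustering uses $\rho_i = -\log r_{k,i}$, a monotone transform
of the k-NN density estimate that avoids estimating the intrinsic dimension,
weighted by the trace quality ratio. The neighbour count defaults to
$k = \max(10, \lceil\sqrt{N}\rceil)$, a standard bias–variance compromise at
desk-scale $N$; it is configurable. $\delta$ is the minimum distance to a
denser trace, with density ties broken by trace order; the global maximum —
and any trace whose component contains nothing denser — takes the maximum
computed distance, so each connected component can surface a center.
Centers are accepted in descending $\gamma = \rho\delta$ order iff they are
at least $r_\mathrm{cut} = 0.3$ from every accepted center; we read the
published center rule this way because its literal wording for the third
candidate contradicts the rule for the second. Non-computed pairs are
treated as infinitely distant throughout, which is what automatically
excludes statistically isolated traces.

## Refinement

Around each center, the union of 5 nm × 5 pN cells stamped by the center and
its two nearest neighbours (points above 30 pN, before the center's last
peak) forms the area of similarity. Candidate curves whose final peak lies
outside $[0.7L, 1.3L]$ of the center length are excluded; the rest are
scored by how many of their points fall into occupied cells. "Last peak"
means the last local maximum above 30 pN after a 5-point running mean —
without the smoothing, baseline noise in the post-detachment tail fakes a
final peak on a sizeable fraction of traces and corrupts the length filter.

The sorted score curve is thresholded at its slope change. We fit the
two-segment piecewise-linear breakpoint, but accept it as a threshold only
when the second slope is at least three times the first: the knee is a
*change of slope*, and on a homogeneous candidate population (every curve
one pattern — the typical situation after the length filter in small
simulations) the unconditional breakpoint would land mid-population and
halve every cluster. With no genuine slope change the threshold falls back
to a quarter of the 90th-percentile score, i.e. membership requires sharing
at least a quarter of the pattern envelope. Clusters sharing more than 40 %
of their above-threshold members (relative to the smaller set, so a small
cluster engulfed by a large one merges) are merged largest-first, with the
published stopping rule (four consecutive merges and all remaining clusters
under 3 traces) applied literally; sub-3 residues are reported as dropped,
not silently lost.

Cluster observables feed the identification: `lc_max` is the contour length
of the rightmost meaningful peak of the pooled member histogram;
`mean_force` averages the rupture force of each member's Lc peaks (the force
maximum among each peak's points — robust at 1-nm noise, where raw local
maxima would be dominated by noise wiggles); the peak profile is the pooled
histogram restricted to 40–100 pN, normalised to unit area.

## Bayesian identification

The prior is the normalised product of mass-spectrometry abundance and the
binary membrane flag; the proteome table is assumed to use one abundance
scheme per run (emPAI preferred, spectral counts or coverage otherwise).
The length likelihood is Gaussian, centred at $0.89\,L_\mathrm{prot}$
($L_\mathrm{prot}$ = residues × 0.4 nm) with relative width
$\sqrt{0.05^2 + 0.07^2 + 0.05^2} \approx 0.10$ — the empirical spread of
effective unfolding lengths, the persistence-length uncertainty and the
measurement error combined in quadrature. For proteins whose terminal
soluble domain exceeds twice that width the pinning point is undetermined
within the domain, so the Gaussian is replaced by a uniform over
$(L - L_\mathrm{domain}, L)$. Both branches are proper densities in
nm$^{-1}$, so they are commensurable inside one normalisation.

The force likelihood is a per-secondary-structure-class lognormal; the
shipped locations (helix ≈ 110 pN, sheet ≈ 190 pN, mixed ≈ 150 pN, all with
broad widths) are calibration values meant to be refit from literature
unfolding-force tables — the mechanism (a per-class smooth density, flat for
unknown structure) is the design, the numbers are replaceable via
`likelihood_config()`. The barrier-profile likelihood cross-correlates the
cluster's unit-area peak profile with Gaussian bells (FWHM 15 nm) at the
protein's loop centers, maximised over integer-nm lags within ±15 nm; the
8-nm histogram is linearly upsampled to 1 nm first because the lag freedom
is sub-bin. The correlation enters as a raw nonnegative factor — any common
scaling cancels in the posterior normalisation. With no loop annotation a
flat line over the cluster support is used.

## What the generator emulates — and what it does not

`simulate_curve()` produces piecewise-WLC sawtooths from a template (barrier
contour lengths + rupture forces), with Gaussian force noise (default sd
10 pN, typical AFM thermal noise), a random ±20 pN baseline offset, a 45-pN
adhesion dip at contact, the cantilever bending term folded into the piezo
coordinate (spring constant 840 pN/nm), 0.5-nm raw sampling and an 80-nm
post-detachment tail. Premature detachment truncates a pull at a uniformly
chosen intermediate with probability 0.23 (the reported fraction of
incomplete unfolds). Spurious traces are sums of 1–3 unrelated WLC branches
(multiple attachments — hard negatives, not white noise); tethers are
constant-force plateaus. Rupture is instantaneous to baseline: the analysis
never uses the drop shape, so cantilever relaxation dynamics are not
modelled. Also not emulated: force-dependent loading-rate effects,
persistence-length heterogeneity along a single trace, instrument drift, and
curves that attach mid-loop. Passing tests on this generator therefore
demonstrates the pipeline's logic and its noise robustness at realistic
amplitudes, not performance on every instrument artefact class.

The `smfs_templates()` preset contains three templates with last barriers at
130, 219 and 310 nm — far enough apart that the 20 % length prefilter keeps
the patterns disjoint, analogous to mixing three well-characterised
proteins. `synth_templates(n)` spreads n templates over 70–280 nm with
secondary-structure classes cycling and rupture forces near the class level,
and `synth_proteome()` derives the matching table (residues from the last
barrier through the 0.89 × 0.4 relations, loops at interior barriers),
optionally with decoys kept three likelihood widths away from every
template.

## Numerical and scale choices

Test and example simulations run at 100–300 curves — cluster recovery with
three templates is stable from roughly 40 curves per template — and the
identification checks use 20 clusters of 12 curves each against a 20-protein
table; a full run at 150 curves takes a few seconds on one core, dominated
by the alignment kernel. Degenerate inputs are handled explicitly: duplicate
traces (zero k-NN radius) get a flagged floor of $10^{-3}$ times the
smallest positive distance; centers without two computed neighbours build a
flagged single-trace envelope; fewer than three eligible candidates skip the
knee and keep everything; clusters with no meaningful pooled peak fall back
to the 95th percentile of member final-peak lengths, flagged. With
truncation events enabled, prematurely detached pulls form genuine shorter
recurrent patterns; depending on the mixture they either merge into their
parent cluster through the shared-member rule or survive as small clusters —
that is method behaviour, not an artefact, and balanced-mixture checks are
therefore run with truncation off.

## Known limitations

The force-model defaults are calibration placeholders, not fitted values;
identification accuracy on real data hinges on refitting them. The Lc
likelihood assumes the 0.89 effective-length ratio holds across families,
which published pulls support for polytopic proteins without large terminal
domains. The merge order (largest first) makes the final cluster count
weakly dependent on threshold noise when two clusters sit near the 40 %
overlap boundary. And the pipeline is single-process by design; at the
10^5-curve scale of a full instrument campaign the pairwise alignment stage
would need batching beyond the prefilter.
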