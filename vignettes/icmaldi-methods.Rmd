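---
title: "Consensus fingerprints, shared-peak similarity and peak assignment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus fingerprints, shared-peak similarity and peak assignment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmaldi)
```

## The problem

Intact-cell MALDI-TOF mass spectrometry records peptide/protein profile
spectra directly from whole microbial cells over roughly m/z 1000–20,000.
Because the dominant ions come from abundant, well-ionizing proteins
(ribosomal proteins, and in photosynthetic organisms the photosystem and
electron-carrier proteins), the peak pattern is a reproducible strain
fingerprint. Two analyses hang off such fingerprints:

* **typing** — compare the fingerprints of many strains to each other and
  cluster them into a similarity tree, and
* **assignment** — explain individual fingerprint peaks by candidate
  proteins whose sequence-derived masses agree with the observed m/z.

This vignette describes the models and numerical choices behind both, and
what the synthetic validation suite does and does not demonstrate.

## Replicate consensus: the virtual reference spectrum

Replicate acquisitions of the same sample differ: peak positions scatter
by up to ±2 Da on externally calibrated linear instruments, weak peaks
drop out, and chemical noise adds spurious ones. The consensus construct
(`build_virtual_spectrum()`) keeps exactly the reproducible part:

1. pool all replicate peaks and sort by m/z;
2. partition by single-linkage with gap threshold `tol_da` (default 2 Da):
   a new cluster starts when the gap to the previous peak exceeds the
   tolerance;
3. within a cluster, a replicate may attest only once — its most intense
   member is kept (ties toward lower m/z);
4. a cluster is retained iff its distinct-replicate support reaches
   `ceiling(min_fraction * n_replicates)` — the default `min_fraction` of
   0.70 with 10 replicates means "at least 7 of 10";
5. consensus m/z is the median of member m/z (robust to a single
   outlying replicate), intensity the arithmetic mean;
6. clusters whose span exceeds `2 * tol_da` — possible because single
   linkage chains — are split at their largest internal gap (first such
   gap on ties) and re-tested.

The construction is deterministic and independent of replicate order:
pooled peaks are sorted by (m/z, replicate, −intensity) before
clustering. Reading "at least 70%" as `ceiling` is the literal
interpretation: 70% of 10 spectra is 7 spectra, and 6 is not "at least
70%". The ceiling is computed with a 1e-9 slack so that binary floating
point representation of fractions like 0.7 cannot shift the boundary.

The tests compare the greedy construction against an exhaustive
dynamic-programming oracle that scores *every* contiguous
tolerance-respecting partition of pools of up to 20 peaks by (number of
kept clusters, total support). On replicate-structured pools — jittered
copies of well-separated true peaks plus occasional spurious ones, which
is what the consensus actually consumes — the two agree on the kept-peak
count in ≥ 95% of seeded fixtures; the rare disagreements (dense spurious
coincidences where a cleverer partition rescues one extra cluster) are
reported by the test via `message()`, not hidden.

One known edge of the span rule: a span ≤ `2 * tol_da` guarantees every
member lies within `tol_da` of the cluster *midpoint*; the median can in
principle sit closer to one end. With the jitter magnitudes the method is
designed for (SD well under the tolerance) this does not occur in
practice, and the package follows the simple span rule rather than
iterating membership against the median.

## Shared-peak similarity

The similarity of an inspected spectrum $Q$ against a reference $R$ is
the percentage of $Q$'s peaks that find a counterpart in $R$ within the
tolerance (inclusive boundary — "±2 Da" is a closed interval):

$$\mathrm{score}(Q, R) = 100 \cdot \frac{|\mathrm{matched}(Q, R)|}{|Q|}.$$

The denominator is the inspected spectrum, so the score is directed:
a sparse fingerprint fully contained in a rich one scores 100 in one
direction and less in the other. Matching is one-to-one — each reference
peak certifies at most one query peak — assigned greedily by increasing
$|\Delta m/z|$ with ties toward the lower-m/z query peak. One-to-one
certification prevents a single reference peak from "explaining" several
query peaks that happen to crowd one tolerance window.

Greedy closest-pair matching is not, in full generality, guaranteed to
reach maximum-cardinality bipartite matching: a crossing configuration
with two near-boundary distances can block one match. The test suite
therefore checks greedy against exhaustive maximum matching on 500 seeded
fingerprint-like instances (sparse reference peaks, a query sharing a
subset of them within ± 1.2 × tolerance plus private peaks, both sides
respecting the consensus gap invariant). On this regime — the one the
score actually operates in, where consensus peaks are far apart relative
to the tolerance — the two coincide on every instance. On artificially
dense instances (every gap barely above the tolerance) disagreements of
one match can be produced; the greedy rule is retained because it is the
transparent reading of "count identical peak positions".

For tree building the directed matrix is symmetrized,
$d_{ij} = 100 - (s_{ij} + s_{ji})/2$, and clustered agglomeratively.
UPGMA (average linkage) is the default — the standard choice for
profile-similarity dendrograms, and it yields an ultrametric tree;
complete and single linkage are available. Sample labels are sorted
lexicographically before clustering so that ties break deterministically.
The heat map uses a continuous ramp anchored at red (0), yellow (50) and
dark green (100).

## Protein masses, Met loss and pI

Intact masses are residue-table sums plus one water (monoisotopic
18.01056 Da, average 18.01528 Da). Every sequence beginning with
methionine also gets Met-loss variants, mass minus one Met residue
(monoisotopic 131.04049 Da, average 131.19261 Da): N-terminal methionine
excision is so prevalent among the small, abundant proteins seen in these
fingerprints that both forms are always anticipated; the enzyme's
second-residue specificity is deliberately not modeled. Full precision is
kept internally; report tables round to 0.1 Da, which means recomputing a
−Met column *from rounded inputs* can differ by one unit in the last
digit — the tests allow exactly that on the monoisotopic column.

The isoelectric point solves net charge = 0 for the Henderson–Hasselbalch
model over the termini and the D, E, C, Y (acidic) and H, K, R (basic)
side chains with the Bjellqvist pKa set (including residue-specific
N-terminal values). Net charge is strictly decreasing in pH, so bisection
on [0, 14] converges unconditionally; the default stopping width 1e-4
comfortably supports reporting to 0.01 pH.

Assignment (`match_masses_to_peaks()`) picks, per protein, the
(variant, peak) pair with minimal $|\Delta|$ over the enabled variants and
reports it when within tolerance. Defaults: variants `avg` and
`avg_noMet` — the unresolved isotopic envelopes of intact proteins track
average mass, and instruments are calibrated on average-mass standards —
and ±6 Da absolute. The 6 Da default is chosen to cover the deviations
actually seen between sequence-derived average-minus-Met masses and
observed peaks in the reference table shipped with the package (largest
|Δ| = 5.8 Da, plastocyanin) while staying of the same order as the
reproducibility tolerance; a ppm mode and a `proton` switch (compare
peaks as [M+H]+ by subtracting 1.00728 Da) are provided. Observed peak
m/z is compared to the neutral mass by default because the reference
table's peak column is itself reported on that convention.

## The synthetic-data generator

`sim_config()` defaults encode the acquisition regime the analysis
assumes: 10 replicates per sample; Gaussian m/z jitter with SD 0.6 Da,
placing ~99.9% of replicate scatter within the ±2 Da matching tolerance;
10% peak dropout; Poisson(2) spurious peaks per replicate, uniform over
m/z 1000–20,000; log-normal intensity noise with CV 0.3 (typical
replicate-to-replicate variation for intact-cell spectra); 30 true peaks
per strain, log-uniform intensities over two decades. Clade structure is
induced by a shared peak pool: each strain draws 70% of its peaks from
its clade's pool and the rest privately. Ground-truth peaks are kept
> 4.1 Da apart (just over twice the tolerance) so that
recovered-vs-planted bookkeeping is unambiguous.

What the generator does *not* emulate: physically realistic TOF peak
shapes, detector saturation, isotopic envelopes, mass-dependent
resolution, matrix clusters, or intensity correlations between related
proteins. Passing the synthetic suite therefore demonstrates that the
*algorithms* behave as specified under the stated noise model — it does
not certify performance on real spectra, where calibration drift and
chemistry produce structured rather than independent noise.

With these defaults the validation suite measures, over 20 seeded runs:
mean true-peak recovery of the 70% consensus ≥ 95% with ≤ 5% false
consensus peaks, and clade monophyly of the UPGMA tree in at least 18
of 20 runs (observed: 20 of 20). Problem sizes — 12 strains × 10
replicates × 30 peaks — keep a full run of the suite under a minute while
giving the binomial/Poisson checks a few hundred events each.

## Peak picking from profile spectra

Acquisition software usually exports centroided peak lists, but the
package can also pick peaks from raw profiles. The baseline is a rolling
minimum followed by a rolling mean (window 200 Da): the minimum tracks
the signal floor under peaks, the mean smooths the resulting staircase.
Because a rolling minimum sits a few noise SDs *below* the noise median,
the baseline-subtracted signal is re-centered on its median before the
noise scale is estimated as MAD × 1.4826; otherwise every local noise
maximum would inherit an SNR offset of about +2.5 and a 3-SD threshold
would fire constantly. A peak is emitted at each strict local maximum
within ±5 Da whose SNR reaches `snr_min` (default 3); its m/z is the
intensity-weighted centroid of the contiguous region above half the local
maximum, which is stable to well within the ±2 Da tolerance under
intensity noise. All thresholds are scale-free: multiplying a spectrum by
a constant changes no picked position.

A note on thresholds: on an *N*-point trace, a detection threshold of
`snr_min = 3` admits about `N × P(z > 3) ≈ N/740` false local maxima —
a handful on a typical profile. That is the appropriate operating point
for fingerprinting (the 70% replicate consensus removes unreproducible
peaks downstream), but single-spectrum claims of "exactly one peak"
require `snr_min` above `qnorm(1 − 1/N)` (≈ 3.5 for N = 2000); the test
suite uses 5 for such cases.

## Determinism

Every stochastic component takes an explicit seed, threaded through
`.Random.seed`-preserving wrappers; reruns of the full pipeline with the
same configuration are byte-identical for all non-image outputs. Mass
spectra, peak lists, libraries, matrices and trees all round-trip through
their on-disk formats (two-column TXT, peak-list CSV, mzML via mzR,
library JSON, matrix CSV, Newick) with at most format-precision loss.

## Known limitations

* The consensus and score reproduce the *generic* shared-peak workflow;
  vendor-specific weighted projections (frequency/intensity-weighted MSP
  scores, log-score scales) are intentionally out of scope.
* Similarity trees carry no bootstrap support; the score is a peak-count
  statistic, not a likelihood.
* Assignment is by intact-mass agreement only: at ±6 Da several proteins
  of a proteome can share one peak, so an assignment is a candidacy, not
  an identification. Post-translational modifications other than Met loss
  (notably chromophore-carrying phycobiliproteins) are not modeled.
* Charge states other than +1 are not deconvolved.
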