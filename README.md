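# icmaldi

Classification of microorganisms from intact-cell MALDI-TOF mass
fingerprints, and assignment of candidate proteins to the observed peaks.

Whole microbial cells spotted with matrix yield peptide/protein profile
spectra ("fingerprints") over roughly m/z 1000–20,000 that are
characteristic enough to type strains — including cyanobacteria, where
classical morphology-based taxonomy is notoriously ambiguous. This package
implements the spectral-library workflow used for such typing:

1. **Virtual reference spectra.** For each sample, replicate acquisitions
   (typically 10 spots) are reduced to a consensus line spectrum keeping
   the peaks present in at least a fraction *f* of replicates within an
   m/z tolerance *t*:

   a peak cluster is kept iff `support ≥ ⌈f · n_replicates⌉`, with the
   defaults *f* = 0.70 and *t* = 2 Da, and its consensus m/z is the median
   of the member peaks.

2. **Shared-peak similarity.** The score of an inspected spectrum *Q*
   against a reference *R* is

   `score(Q, R) = 100 · |{q ∈ Q : ∃ r ∈ R, |q − r| ≤ t}| / |Q|`

   with one-to-one peak certification (each reference peak matches at most
   one query peak, closest pairs first). The score is asymmetric; the
   all-pairs matrix is rendered as a heat map (red = 0, yellow = 50, dark
   green = 100) and symmetrized into distances `d = 100 − (s_ij + s_ji)/2`
   for a UPGMA similarity tree.

3. **Peak–protein assignment.** From candidate protein sequences (e.g.
   LC-MS/MS identifications) the package computes monoisotopic and average
   intact masses, the variants after N-terminal methionine excision
   (−131.04049 Da mono, −131.19261 Da average) and the Bjellqvist
   isoelectric point, then assigns each protein to its closest observed
   peak within a tolerance (default ±6 Da absolute, on average masses
   after Met loss).

A synthetic-data module generates ground-truth strain fingerprints and
replicate peak lists with controlled m/z jitter, peak dropout, spurious
peaks and intensity noise, so the whole pipeline is testable without
instrument data.

## Worked example

The numbered scripts under `analysis/` run the workflow end to end on a
simulated 3-clade × 4-strain panel and on the published assignment table
for *Chroococcidiopsis cubana* CCALA 043:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_consensus.R
Rscript analysis/03_similarity.R
Rscript analysis/04_assign.R
```

which prints:

```
Simulated 12 strains (3 clades x 4), 10 replicates each,
30 true peaks per strain; peak lists in results/sim/peaklists/.
Consensus library of 12 virtual spectra -> results/library.json
True-peak recovery: 97.5%; false consensus peaks: 0.0%
Mean within-clade similarity: 67.2%; between-clade: 0.1%
Clades monophyletic in the UPGMA tree: 3 of 3
Average-mass -Met column reproduced to 0.1 Da: TRUE
Proteins assigned at +/- 6 Da: 36 of 36 (max |delta| 5.8 Da)
At +/- 0.5 Da only 6 remain; dropped rows include plastocyanin (K9U7R5): TRUE
```

The 70%-consensus recovers 97.5% of the planted fingerprint peaks with no
false consensus peaks; shared-peak similarity separates clades cleanly
(67% within vs ~0% between), and the UPGMA tree groups every simulated
clade monophyletically. For CCALA 043, all 36 candidate proteins land on
their published peaks at ±6 Da — the largest deviation, 5.8 Da, is
plastocyanin, which is the first row to drop out when the tolerance is
tightened.

Equivalent calls from R:

```r
library(icmaldi)
cfg <- sim_config(seed = 42)
fps <- generate_fingerprints(cfg)
lib <- lapply(fps, function(fp) build_virtual_spectrum(simulate_replicates(fp, cfg)))
m    <- similarity_matrix(lib, tol_da = 2)
tree <- build_tree(m, linkage = "upgma")
```

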