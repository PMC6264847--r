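#!/usr/bin/env Rscript
# Simulate a strain panel with known taxonomy: 3 clades x 4 strains,
# 10 replicate acquisitions each, m/z jitter sd 0.6 Da, 10% peak dropout,
# ~2 spurious peaks per replicate. Writes per-replicate peak-list CSVs
# and the ground truth under results/sim/.

suppressMessages(library(icmaldi))

cfg <- sim_config(seed = 42)
dir.create("results/sim/peaklists", showWarnings = FALSE, recursive = TRUE)

fps <- generate_fingerprints(cfg)
for (fp in fps) {
  for (pl in simulate_replicates(fp, cfg))
    write_peaklist_csv(pl, sprintf("results/sim/peaklists/%s__%s.csv",
                                   fp$sample_id, pl$replicate_id))
}
truth <- lapply(fps, function(fp)
  list(sample_id = fp$sample_id, clade_id = fp$clade_id,
       mz = fp$mz, intensity = fp$intensity))
jsonlite::write_json(truth, "results/sim/ground_truth.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated %d strains (%d clades x %d), %d replicates each,\n",
            length(fps), cfg$n_clades, cfg$strains_per_clade,
            cfg$n_replicates))
cat(sprintf("%d true peaks per strain; peak lists in results/sim/peaklists/.\n",
            cfg$n_peaks_per_strain))
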