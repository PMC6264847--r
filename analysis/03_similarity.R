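#!/usr/bin/env Rscript
# Score every virtual spectrum against every other (shared-peak score,
# +/- 2 Da), draw the similarity heat map with the red-yellow-green ramp,
# and build the UPGMA similarity tree. Checks whether the simulated clades
# come out monophyletic.

suppressMessages(library(icmaldi))

lib <- read_library("results/library.json")
m <- similarity_matrix(lib, tol_da = 2)
write_similarity_csv(m, "results/similarity_matrix.csv")
render_heatmap(m, "results/similarity_heatmap.png")
tree <- build_tree(m, linkage = "upgma")
write_tree_newick(tree, "results/similarity_tree.nwk")

truth <- jsonlite::read_json("results/sim/ground_truth.json",
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
ids <- vapply(truth, `[[`, character(1), "sample_id")
clades <- vapply(truth, `[[`, character(1), "clade_id")
mono <- vapply(unique(clades), function(cl)
  ape::is.monophyletic(tree, ids[clades == cl]), logical(1))

within <- mean(m[outer(clades, clades, "==") & diag(nrow(m)) == 0])
between <- mean(m[outer(clades, clades, "!=")])
cat(sprintf("Mean within-clade similarity: %.1f%%; between-clade: %.1f%%\n",
            within, between))
cat(sprintf("Clades monophyletic in the UPGMA tree: %d of %d\n",
            sum(mono), length(mono)))
cat("Outputs: similarity_matrix.csv, similarity_heatmap.png, similarity_tree.nwk\n")
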