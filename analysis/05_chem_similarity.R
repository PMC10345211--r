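#!/usr/bin/env Rscript
# Stage 5: chemical-similarity companion analysis.
#
# On synthetic fixtures standing in for descriptor and conformer-overlay
# outputs: converts a pairwise conformer-similarity report into a shape
# distance matrix (D = 1 - S/S_max, max over conformer pairings), clusters
# it, runs descriptor PCA, and compares the adverse-event profiles of two
# drugs that sit in the same chemical cluster.

library(vigiprof)

seed <- 1L
ids <- sprintf("drug%03d_1", 1:12)

report <- simulate_similarity_report(ids, seed = seed)
d <- shape_distance_matrix(report, "combo")
hc <- hcluster(d, linkage = "average")
export_dendrogram(hc, newick = "results/shape_dendrogram.nwk",
                  merges = "results/shape_merges.tsv")
cat(sprintf("shape-distance matrix: %d stereoisomers, distances in [%.3f, %.3f]\n",
            nrow(d), min(d[upper.tri(d)]), max(d[upper.tri(d)])))

desc <- simulate_descriptors(ids, n_features = 24, n_clusters = 3,
                             seed = seed)
p <- fingerprint_pca(desc, n_components = 2)
readr::write_tsv(tibble::tibble(id = rownames(p$scores),
                                pc1 = p$scores[, 1], pc2 = p$scores[, 2]),
                 "results/descriptor_pca.tsv")
cat(sprintf("descriptor PCA: first two components explain %.1f%% of variance\n",
            100 * sum(p$explained[1:2])))

# profile comparison of two neighbouring drugs in the dendrogram
pool1 <- read_pool("results/pool1.tsv")
pool2 <- read_pool("results/pool2.tsv")
map <- readr::read_tsv("results/data/meddra_toy.tsv", show_col_types = FALSE)
f1 <- pool1[pool1$sex == "female", ]
f2 <- pool2[pool2$sex == "female", ]
cmp <- profile_compare(f1, f2, map, "drug008", "drug010",
                       groups = unique(map$soc), level = "soc", k = 10)
readr::write_tsv(cmp, "results/profile_compare.tsv")
cat("\ntop-AE profile comparison drug008 vs drug010 (female):\n")
print(cmp)
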