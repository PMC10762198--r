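#!/usr/bin/env Rscript
# Stage 6 — per-subnetwork topology, the network-similarity network, its
# minimum spanning tree, and density-based clustering of subnetworks.
#
# Eight global metrics per subnetwork; pairwise label-free dissimilarity
# from graphlet-orbit correlations (graphlets up to 4 nodes); a complete
# NSN weighted by that dissimilarity; the deterministic Kruskal MST; and
# classical-MDS embedding (10 dimensions) + density-based clustering
# (min 3 neighbours for a core, minimum cluster size 5, noise allowed).

suppressMessages(library(pelagicnets))

dataset <- read_fixture("results/data")
counts <- asv_table(rbind(dataset$prok_counts$counts,
                          dataset$euk_counts$counts),
                    c(dataset$prok_counts$domain, dataset$euk_counts$domain))
net <- import_network("results/static_final.tsv", counts$domain)
subs <- derive_all(counts, dataset$metadata, net, threshold = 0.20)

metrics <- do.call(rbind, lapply(subs$subnetworks, network_metrics,
                                 domains = counts$domain))
write.table(metrics, "results/network_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("metric medians by layer:\n")
md <- dataset$metadata
for (l in unique(md$layer)) {
  sel <- metrics$sample %in% md$sample[md$layer == l]
  cat(sprintf("  %s: density %.2f, transitivity %.2f, path length %.2f\n",
              l, median(metrics$edge_density[sel], na.rm = TRUE),
              median(metrics$transitivity[sel], na.rm = TRUE),
              median(metrics$average_path_length[sel], na.rm = TRUE)))
}

dm <- dissimilarity_matrix(subs)
mst <- minimum_spanning_tree(build_nsn(dm))
cat("MST:", length(unique(c(mst$a, mst$b))), "nodes,", nrow(mst),
    "edges, total weight", round(attr(mst, "total_weight"), 2), "\n")
write.table(mst, "results/mst.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cl <- cluster_subnetworks(dm)
comp <- cluster_composition(cl$assignment, dataset$metadata)
write.table(comp, "results/cluster_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(cl$n_clusters, "clusters of sizes",
    paste(comp$size, collapse = ", "), "\n")
dom <- table(comp$dominant_layer, useNA = "ifany")
cat("dominant layers:", paste(names(dom), dom, sep = "=", collapse = ", "),
    "\n")
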