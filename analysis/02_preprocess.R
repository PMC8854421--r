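#!/usr/bin/env Rscript
# Standard scRNA-seq postprocessing of the simulated dataset: CP10K
# log-normalization, highly variable genes, batch regression + scaling,
# parallel-analysis dimensionality, SNN clustering; evaluates cluster
# recovery against the planted cell types.

library(nfcn)

counts <- read_counts_mtx("results/data")
ann <- read.table("results/data/annotations.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)

ln <- lognormalize(counts)
hvg <- select_variable_genes(ln, n = 500)
scaled <- regress_and_scale(ln[hvg, ], data.frame(batch = factor(ann$batch)))

k <- nontrivial_components(scaled, n_max = 30, n_perm = 10, seed = 1)
message("nontrivial components: ", k)

sv <- svd(scaled, nu = 0, nv = k)
emb <- sv$v %*% diag(sv$d[seq_len(k)], k, k)
rownames(emb) <- colnames(scaled)
clusters <- snn_cluster(emb, k_neighbors = 20, resolution = 0.8, seed = 1)

tab <- table(truth = ann$cluster, snn = clusters[ann$cell])
ari <- {
  comb2 <- function(x) x * (x - 1) / 2
  n <- sum(tab)
  (sum(comb2(tab)) - sum(comb2(rowSums(tab))) * sum(comb2(colSums(tab))) / comb2(n)) /
    ((sum(comb2(rowSums(tab))) + sum(comb2(colSums(tab)))) / 2 -
       sum(comb2(rowSums(tab))) * sum(comb2(colSums(tab))) / comb2(n))
}
message("SNN clusters: ", length(unique(clusters)),
        "; adjusted Rand index vs planted types: ", round(ari, 3))

dir.create("results", showWarnings = FALSE)
write.table(data.frame(cell = names(clusters), snn_cluster = clusters,
                       planted = ann$cluster[match(names(clusters), ann$cell)]),
            "results/clusters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("written results/clusters.tsv")
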