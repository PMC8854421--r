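#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a multi-batch immune scRNA-seq
# experiment with a ligand-producing myeloid subset and exhausted T cells,
# a spatial spot array with one contiguous MES-like niche, and planted
# chromosome 7 gain / chromosome 10 loss in tumor cells.

library(nfcn)

seed <- 1L
out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

config <- synth_config(seed = seed)
sim <- generate_immune_counts(config)
grid <- generate_spatial_spots(config, sim$counts, sim$truth)
positions <- make_gene_positions(rownames(sim$counts))
planted <- plant_cnv(sim$counts, sim$truth, positions, config)

write_synthetic_dataset(planted$counts, planted$truth, out_dir,
                        grid = grid, positions = positions)

lab <- table(sim$truth$cell_labels)
message("simulated ", ncol(sim$counts), " cells x ", nrow(sim$counts),
        " genes in ", config$n_batches, " batches")
message("cell types: ", paste(names(lab), lab, sep = "=", collapse = ", "))
message("spot array: ", nrow(grid$spots), " spots (",
        sum(grid$spots$region == "MES"), " in the MES-like niche), ",
        "median ", median(lengths(attr(grid, "members"))), " cells/spot")
message("planted CNV: 2^", config$cnv_shift, " gain on ",
        config$cnv_gain_chrom, ", loss on ", config$cnv_loss_chrom)
message("written to ", out_dir)
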