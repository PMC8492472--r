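#!/usr/bin/env Rscript
# Step 1 -- generate every input the downstream analyses consume, with
# planted ground truth: heptad gene families (codon alignments + gene
# trees + locations), an expression panel, multi-genome alignment blocks
# and two-population genotypes.  All outputs land under results/inputs/.

suppressMessages(library(allokit))
seed <- 1L
out_dir <- "results/inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("Simulating 400 heptad families (3% HE, 10% complex topologies)...")
heptads <- simulate_heptad_families(400, he_rate = 0.03,
                                    topology_noise = 0.10, seed = seed)
write_heptad_simulation(heptads, file.path(out_dir, "heptads"))
message("  planted HE genes: ", length(heptads$truth$he_genes),
        "; complex families: ", length(heptads$truth$complex_families))

message("Simulating a 2,000-pair expression panel (subB bias 0.6)...")
panel <- simulate_expression_panel(2000, dominance_bias = 0.6,
                                   conserved_fraction = 0.7, seed = seed)
write_expression_panel(panel, file.path(out_dir, "expression"))

message("Simulating 500 seven-genome alignment blocks (10% translocated, ",
        "5% inverted rows)...")
blocks <- simulate_alignment_blocks(25, 500, transloc_rate = 0.10,
                                    inversion_rate = 0.05, seed = seed)
write_maf_blocks(blocks$blocks, file.path(out_dir, "blocks.maf"),
                 blocks$src_sizes)
write.table(blocks$homoeolog_map, file.path(out_dir, "homoeolog_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Simulating two-population genotypes (10 Mb, 5 sweep windows)...")
geno <- simulate_two_population_genotypes(20, 1e7, 5,
                                          pi_background = 2e-3,
                                          pi_sweep = 5e-4, seed = seed)
write_vcf_minimal(geno$gm, file.path(out_dir, "populations.vcf"))
jsonlite::write_json(geno$truth, file.path(out_dir, "sweep_truth.json"),
                     auto_unbox = TRUE, digits = NA)
saveRDS(list(heptads = heptads, panel = panel, blocks = blocks,
             geno = geno),
        file.path(out_dir, "simulation.rds"))
message("Done; inputs and truth records are under ", out_dir)
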