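#!/usr/bin/env Rscript
# Stage 1: generate the synthetic orthologous gene family used by the rest
# of the workflow. Five genes with six introns each across zebrafish,
# chicken, mouse and human; eight planted CISs plus one tandem duplication,
# one exonizing transcript variant, one stop-skip codon and one frameshift
# insertion. Writes FASTA + GFF3 per species, the truth BED and a manifest.

suppressMessages(library(ciscover))

out_dir <- "results/simulated"
cfg <- sim_config(duplication = TRUE, exonize = TRUE, stop_skip = TRUE,
                  frameshift = TRUE, seed = 42L)
sim <- simulate_family(cfg, out_dir = out_dir)

n_genes <- length(sim$genes$zebrafish)
pool <- total_intronic_nucleotides(sim$genes$zebrafish)
message(sprintf("simulated %d genes x %d species; zebrafish intron pool %d nt",
                n_genes, length(sim$genes), pool))
message(sprintf("planted: %d CISs, 1 duplication, stop-skip at codon %d of %s, 1-nt frameshift in %s",
                nrow(sim$truth$cis) / length(sim$genes),
                sim$truth$stop_skip$codon_index, sim$truth$stop_skip$cis_id,
                sim$truth$frameshift$cis_id))
saveRDS(sim$truth, "scratch/truth.rds")  # scratch only; regenerable from seed
message("wrote ", out_dir)
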