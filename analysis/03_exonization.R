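#!/usr/bin/env Rscript
# Stage 3: exonization and codon-level analyses of the CIS calls.
# Classifies every zebrafish CIS call against that gene's transcript
# variants (expressed vs purely intronic, splice flanks, reading frame),
# then runs the cross-species codon comparisons on the planted features:
# stop-skip detection, frameshift-indel detection, and intragene
# duplication detection.

suppressMessages(library(ciscover))

in_dir <- "results/simulated"
species <- c("zebrafish", "chicken", "mouse", "human")
genes <- lapply(species, function(sp)
  read_gene_models(file.path(in_dir, paste0(sp, ".gff3")),
                   file.path(in_dir, paste0(sp, ".fa"))))
names(genes) <- species
genes <- lapply(genes, function(g)
  stats::setNames(g, vapply(g, function(x) x$gene_id, character(1))))
calls <- utils::read.delim("results/cis_zebrafish/cis_calls.tsv")
params <- default_ka_params()

events <- data.frame()
for (i in seq_len(nrow(calls))) {
  g <- genes$zebrafish[[calls$gene_id[i]]]
  ev <- exonization_status(list(start = calls$start[i], end = calls$end[i]),
                           g)
  status <- if (nrow(ev) == 0) "intronic" else "exonized"
  events <- rbind(events, data.frame(
    gene_id = calls$gene_id[i], intron_ordinal = calls$intron_ordinal[i],
    start = calls$start[i], end = calls$end[i], class = status,
    transcript_id = if (nrow(ev)) ev$transcript_id[1] else NA,
    frame = if (nrow(ev)) ev$frame[1] else NA,
    splice_ok = if (nrow(ev)) ev$splice_ok[1] else NA))
}
message(sprintf("%d CIS call(s): %d exonized, %d purely intronic",
                nrow(events), sum(events$class == "exonized"),
                sum(events$class == "intronic")))

# codon-level cross-species comparisons on every exonized call: align the
# mouse and human copies of the region and look for stop-skips/frameshifts
codon <- data.frame()
for (i in which(events$class == "exonized")) {
  gid <- events$gene_id[i]
  seqs <- lapply(c("mouse", "human"), function(sp) {
    iv <- extract_introns(genes[[sp]][[gid]])
    iv$sequence[iv$ordinal == events$intron_ordinal[i]]
  })
  hs <- local_align(seqs[[1]], seqs[[2]], params = params,
                    max_evalue = 9e-10)
  if (nrow(hs) == 0) next
  fse <- detect_frameshift_indel(hs$cigar[1])
  aln_len <- min(hs$q_end[1] - hs$q_start[1], hs$s_end[1] - hs$s_start[1])
  ss <- detect_stop_skip(substring(seqs[[1]], hs$q_start[1] + 1,
                                   hs$q_start[1] + aln_len),
                         substring(seqs[[2]], hs$s_start[1] + 1,
                                   hs$s_start[1] + aln_len),
                         frame = 1, species_a = "mouse",
                         species_b = "human")
  if (nrow(ss))
    codon <- rbind(codon, cbind(gene_id = gid, type = "stop_skip", ss))
  if (nrow(fse))
    message(sprintf("  frameshift indel in %s: %d nt at column %d (frame +%d)",
                    gid, fse$indel_length[1], fse$alignment_position[1],
                    fse$frame_delta[1]))
}
if (nrow(codon))
  message(sprintf("stop-skip events: %d (e.g. %s codon %s -> %s, '%s')",
                  nrow(codon), codon$species_with_stop[1],
                  codon$stop_codon[1], codon$other_codon[1],
                  codon$other_aa[1]))

# intragene duplication scan over all zebrafish introns
dups <- data.frame()
for (gid in names(genes$zebrafish)) {
  iv <- extract_introns(genes$zebrafish[[gid]])
  for (k in seq_len(nrow(iv))) {
    d <- detect_intragene_duplication(iv$sequence[k], params = params)
    if (nrow(d))
      dups <- rbind(dups, cbind(gene_id = gid, intron_ordinal = iv$ordinal[k],
                                d))
  }
}
message(sprintf("duplicated intronic segment pairs: %d%s", nrow(dups),
                if (nrow(dups)) sprintf(" (top identity %.2f)",
                                        max(dups$identity)) else ""))

dir.create("results/exonization", showWarnings = FALSE, recursive = TRUE)
utils::write.table(events, "results/exonization/cis_classification.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
if (nrow(codon))
  utils::write.table(codon, "results/exonization/stop_skip_events.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
if (nrow(dups))
  utils::write.table(dups, "results/exonization/duplications.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/exonization")
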