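#' Construct a transcript variant
#'
#' A transcript is a set of exons given as 0-based half-open intervals in
#' gene-local coordinates (transcription orientation). Exons must be sorted,
#' non-overlapping, and non-empty.
#'
#' @param transcript_id Transcript identifier.
#' @param exons Two-column `data.frame` (`start`, `end`) of 0-based half-open
#'   exon intervals, or a matrix coercible to one.
#' @param cds_start Optional 0-based offset of the first codon within the
#'   spliced transcript sequence; `NA` when unknown or non-coding.
#' @return An object of class `transcript_variant`.
#' @export
transcript_variant <- function(transcript_id, exons, cds_start = NA_integer_) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL
  if (nrow(exons) == 0L)
    stop("transcript '", transcript_id, "' has no exons")
  if (any(exons$end <= exons$start))
    stop("transcript '", transcript_id, "' has an empty or reversed exon")
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("transcript '", transcript_id, "' has unsorted or overlapping exons")
  structure(list(transcript_id = as.character(transcript_id),
                 exons = exons,
                 cds_start = as.integer(cds_start)),
            class = "transcript_variant")
}

#' Construct a gene model
#'
#' One species' copy of a gene: its sequence in transcription orientation and
#' its transcript variants. One transcript is the reference; introns are
#' defined as the gaps between its consecutive exons.
#'
#' @param gene_id Gene identifier.
#' @param species Species label.
#' @param sequence DNA string over `{A,C,G,T,N}`, transcription orientation.
#' @param transcripts List of [transcript_variant()] objects.
#' @param reference_transcript_id Identifier of the reference transcript;
#'   defaults to the first transcript.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species, sequence, transcripts,
                       reference_transcript_id = NULL) {
  sequence <- check_dna(sequence, paste0("gene '", gene_id, "' sequence"))
  if (length(transcripts) == 0L)
    stop("gene '", gene_id, "' has no transcripts")
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids))
    stop("gene '", gene_id, "' has duplicated transcript ids")
  if (is.null(reference_transcript_id)) reference_transcript_id <- ids[1L]
  if (!reference_transcript_id %in% ids)
    stop("reference transcript '", reference_transcript_id,
         "' is not among the transcripts of gene '", gene_id, "'")
  L <- nchar(sequence)
  for (t in transcripts) {
    if (any(t$exons$start < 0L) || any(t$exons$end > L))
      stop("exon of transcript '", t$transcript_id, "' in gene '", gene_id,
           "' lies outside the sequence [0,", L, ")")
  }
  structure(list(gene_id = as.character(gene_id),
                 species = as.character(species),
                 sequence = sequence,
                 transcripts = transcripts,
                 reference_transcript_id = reference_transcript_id),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s): %d nt, %d transcript(s), reference %s\n",
              x$gene_id, x$species, nchar(x$sequence),
              length(x$transcripts), x$reference_transcript_id))
  invisible(x)
}

reference_transcript <- function(gene) {
  ids <- vapply(gene$transcripts, function(t) t$transcript_id, character(1))
  gene$transcripts[[match(gene$reference_transcript_id, ids)]]
}

#' Extract introns from a gene model
#'
#' Introns are the maximal gaps between consecutive exons of the reference
#' transcript, numbered 1..(n_exons - 1) in transcription order. Abutting
#' exons (zero-length gap) produce no intron: they model fused exons.
#'
#' @param gene A [gene_model()].
#' @return A `data.frame` with columns `gene_id`, `ordinal`, `start`, `end`
#'   (0-based half-open, gene-local) and `sequence`.
#' @export
extract_introns <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  ex <- reference_transcript(gene)$exons
  out <- data.frame(gene_id = character(), ordinal = integer(),
                    start = integer(), end = integer(),
                    sequence = character(), stringsAsFactors = FALSE)
  if (nrow(ex) < 2L) return(out)
  gs <- ex$end[-nrow(ex)]
  ge <- ex$start[-1L]
  ord <- seq_along(gs)
  keep <- ge > gs
  gs <- gs[keep]; ge <- ge[keep]; ord <- ord[keep]
  if (length(gs) == 0L) return(out)
  data.frame(gene_id = gene$gene_id, ordinal = ord, start = gs, end = ge,
             sequence = substring(gene$sequence, gs + 1L, ge),
             stringsAsFactors = FALSE)
}

#' Total intronic nucleotides of a set of gene models
#'
#' Sum of reference-transcript intron lengths over the given genes, each
#' position counted once. This is the denominator of the conservation
#' percentages (the species' intron pool).
#'
#' @param genes List of [gene_model()] objects (one species).
#' @return Integer nucleotide count; `0` for an empty list.
#' @export
total_intronic_nucleotides <- function(genes) {
  if (length(genes) == 0L) return(0L)
  sum(vapply(genes, function(g) {
    iv <- extract_introns(g)
    as.integer(interval_total(iv))
  }, integer(1)))
}

# ---- GFF3 + FASTA ---------------------------------------------------------

#' Write gene models to GFF3 and FASTA
#'
#' Each gene is written as one FASTA record (gene-local sequence) and a
#' `gene`/`mRNA`/`exon` feature hierarchy in GFF3 (1-based closed
#' coordinates, `+` strand, gene-local seqid). Species and reference
#' transcript are carried as attributes.
#'
#' @param genes List of [gene_model()] objects.
#' @param gff_path,fasta_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_gene_models <- function(genes, gff_path, fasta_path) {
  lines <- "##gff-version 3"
  seqs <- character(0)
  for (g in genes) {
    L <- nchar(g$sequence)
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", g$gene_id, L))
    lines <- c(lines, paste(g$gene_id, "ciscover", "gene", 1L, L, ".", "+", ".",
                            sprintf("ID=%s;species=%s;reference_transcript_id=%s",
                                    g$gene_id, g$species,
                                    g$reference_transcript_id),
                            sep = "\t"))
    for (t in g$transcripts) {
      attrs <- sprintf("ID=%s;Parent=%s", t$transcript_id, g$gene_id)
      if (!is.na(t$cds_start))
        attrs <- paste0(attrs, ";cds_start=", t$cds_start)
      lines <- c(lines, paste(g$gene_id, "ciscover", "mRNA",
                              min(t$exons$start) + 1L, max(t$exons$end),
                              ".", "+", ".", attrs, sep = "\t"))
      for (i in seq_len(nrow(t$exons))) {
        lines <- c(lines, paste(g$gene_id, "ciscover", "exon",
                                t$exons$start[i] + 1L, t$exons$end[i],
                                ".", "+", ".",
                                sprintf("ID=%s.exon%d;Parent=%s",
                                        t$transcript_id, i, t$transcript_id),
                                sep = "\t"))
      }
    }
    seqs[g$gene_id] <- g$sequence
  }
  writeLines(lines, gff_path)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  invisible(c(gff = gff_path, fasta = fasta_path))
}

#' Read gene models from GFF3 and FASTA
#'
#' Expects `gene`/`mRNA`/`exon` features with `ID`/`Parent` attributes and
#' FASTA records named by gene id. GFF3 1-based closed coordinates are
#' converted to 0-based half-open; minus-strand genes are
#' reverse-complemented into transcription orientation.
#'
#' @param gff_path,fasta_path Input paths.
#' @return List of [gene_model()] objects.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- as.data.frame(rtracklayer::readGFF(gff_path))
  get_attr <- function(df, name, default = NA_character_) {
    if (name %in% names(df)) as.character(df[[name]]) else
      rep(default, nrow(df))
  }
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x)) as.character(x[[1]]) else
      NA_character_, character(1))
  }
  genes_df <- gff[gff$type == "gene", , drop = FALSE]
  mrna_df <- gff[gff$type == "mRNA", , drop = FALSE]
  exon_df <- gff[gff$type == "exon", , drop = FALSE]
  mrna_parent <- first_parent(mrna_df$Parent)
  exon_parent <- first_parent(exon_df$Parent)
  out <- list()
  for (i in seq_len(nrow(genes_df))) {
    gid <- as.character(genes_df$ID[i])
    if (!gid %in% names(seqs))
      stop("no FASTA record for gene '", gid, "'")
    seq <- as.character(seqs[[gid]])
    L <- nchar(seq)
    strand <- as.character(genes_df$strand[i])
    minus <- identical(strand, "-")
    if (minus)
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    mi <- which(mrna_parent == gid)
    if (length(mi) == 0L) stop("gene '", gid, "' has no mRNA features")
    transcripts <- list()
    for (j in mi) {
      tid <- as.character(mrna_df$ID[j])
      ei <- which(exon_parent == tid)
      if (length(ei) == 0L)
        stop("mRNA '", tid, "' has no exon features")
      start <- as.integer(exon_df$start[ei]) - 1L  # to 0-based half-open
      end <- as.integer(exon_df$end[ei])
      if (any(start < 0L) || any(end > L))
        stop("exon of transcript '", tid, "' outside sequence bounds of '",
             gid, "' (length ", L, ")")
      if (minus) {  # flip into transcription orientation
        ns <- L - end
        end <- L - start
        start <- ns
      }
      o <- order(start)
      cds <- suppressWarnings(as.integer(get_attr(mrna_df, "cds_start")[j]))
      transcripts[[length(transcripts) + 1L]] <-
        transcript_variant(tid, data.frame(start = start[o], end = end[o]),
                           cds_start = if (length(cds)) cds else NA_integer_)
    }
    ref <- get_attr(genes_df, "reference_transcript_id")[i]
    if (is.na(ref)) ref <- NULL
    sp <- get_attr(genes_df, "species")[i]
    out[[length(out) + 1L]] <-
      gene_model(gid, if (is.na(sp)) "unknown" else sp, seq, transcripts,
                 reference_transcript_id = ref)
  }
  out
}

#' Write CIS calls as BED6
#'
#' 0-based half-open intervals on the anchor gene; the name field is
#' `gene:intronOrdinal:speciesSet` with species joined by `+`; strand is
#' always `+` (all sequences are kept in transcription orientation).
#'
#' @param calls `data.frame` with columns `gene_id`, `intron_ordinal`,
#'   `start`, `end`, `conserved_in` (species joined by `+`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cis_bed <- function(calls, path) {
  if (nrow(calls) > 0 && any(calls$end <= calls$start))
    stop("CIS call with end <= start refused")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ciscover CIS calls (BED6)", con)
  if (nrow(calls) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s:%d:%s\t0\t+",
                     calls$gene_id, calls$start, calls$end,
                     calls$gene_id, calls$intron_ordinal, calls$conserved_in)
    writeLines(lines, con)
  }
  invisible(path)
}
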