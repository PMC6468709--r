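#' Translate a segment in all three forward frames
#'
#' Frame `+k` starts translation at offset `k - 1` of the segment. The
#' standard genetic code is used (all study species are vertebrates and the
#' genes are nuclear); stop codons are rendered `*`, codons containing `N`
#' become `X`, and a trailing partial codon is dropped.
#'
#' @param seq DNA string of length >= 3 over `{A,C,G,T,N}`.
#' @return Named list `frame1`, `frame2`, `frame3`, each with `peptide` and
#'   `stop_positions` (1-based codon indices of stops).
#' @export
translate_frames <- function(seq) {
  seq <- check_dna(seq)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (off in 0:2) {
    n_codon <- (nchar(seq) - off) %/% 3L
    if (n_codon <= 0L) {
      out[[paste0("frame", off + 1L)]] <-
        list(peptide = "", stop_positions = integer())
      next
    }
    starts <- off + 3L * (seq_len(n_codon) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"  # codons containing N
    pep <- paste(aa, collapse = "")
    out[[paste0("frame", off + 1L)]] <-
      list(peptide = pep, stop_positions = which(aa == "*"))
  }
  out
}

#' Are all three frames interrupted by stop codons?
#'
#' `TRUE` iff each of the three forward frames contains at least one stop
#' codon, i.e. the segment cannot be read through in any frame.
#'
#' @param seq DNA string of length >= 5.
#' @return Logical scalar.
#' @export
stops_in_all_frames <- function(seq) {
  seq <- check_dna(seq)
  if (nchar(seq) < 5L) stop("sequence too short for a three-frame stop scan")
  tf <- translate_frames(seq)
  all(vapply(tf, function(f) length(f$stop_positions) > 0L, logical(1)))
}

#' Is a segment an open reading frame in a given frame?
#'
#' `TRUE` iff the chosen frame contains no stop codon over the whole
#' segment.
#'
#' @param seq DNA string of length >= 3.
#' @param frame Reading frame, 1, 2 or 3.
#' @return Logical scalar.
#' @export
orf_scan <- function(seq, frame = 1L) {
  stopifnot(frame %in% 1:3)
  tf <- translate_frames(seq)
  length(tf[[paste0("frame", frame)]]$stop_positions) == 0L
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Cross-species stop-codon differences at aligned codons
#'
#' Compares two pre-aligned sequences codon by codon in the given frame and
#' reports every aligned codon where exactly one species has a stop codon
#' (e.g. a `TAA` skipped in the orthologue by mutation into `TTA`, or
#' corresponding to `TGG`). Alignment columns containing gaps (`-`) are
#' excluded before codons are threaded.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (may contain `-`).
#' @param frame Reading frame (1, 2 or 3) applied after gap-column removal.
#' @param species_a,species_b Species labels for the report.
#' @return `data.frame` with `aligned_codon_index`, `species_with_stop`,
#'   `stop_codon`, `other_codon`, `other_aa`.
#' @export
detect_stop_skip <- function(seq_a, seq_b, frame = 1L,
                             species_a = "a", species_b = "b") {
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences have different lengths")
  stopifnot(frame %in% 1:3)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  off <- frame - 1L
  n_codon <- (length(a) - off) %/% 3L
  out <- data.frame(aligned_codon_index = integer(),
                    species_with_stop = character(),
                    stop_codon = character(), other_codon = character(),
                    other_aa = character(), stringsAsFactors = FALSE)
  if (n_codon <= 0L) return(out)
  code <- Biostrings::GENETIC_CODE
  for (k in seq_len(n_codon)) {
    i0 <- off + 3L * (k - 1L) + 1L
    ca <- paste(a[i0:(i0 + 2L)], collapse = "")
    cb <- paste(b[i0:(i0 + 2L)], collapse = "")
    sa <- ca %in% STOP_CODONS
    sb <- cb %in% STOP_CODONS
    if (xor(sa, sb)) {
      other <- if (sa) cb else ca
      aa <- unname(code[other])
      out <- rbind(out, data.frame(
        aligned_codon_index = k,
        species_with_stop = if (sa) species_a else species_b,
        stop_codon = if (sa) ca else cb,
        other_codon = other,
        other_aa = if (is.na(aa)) "X" else aa,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Frameshifting indels in an HSP
#'
#' Scans a run-length CIGAR string for gap runs whose length is not a
#' multiple of three; each such run shifts the downstream reading frame by
#' `length mod 3`.
#'
#' @param cigar Run-length CIGAR text (`M`, `I`, `D` operations).
#' @return `data.frame` with `alignment_position` (1-based first column of
#'   the gap run), `indel_length`, `frame_delta` (1 or 2).
#' @export
detect_frameshift_indel <- function(cigar) {
  m <- gregexpr("\\d+[MID]", cigar)[[1]]
  runs <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1]]
  lens <- as.integer(sub("[MID]", "", runs))
  ops <- sub("\\d+", "", runs)
  pos <- cumsum(c(1L, lens))[seq_along(lens)]
  sel <- ops %in% c("I", "D") & lens %% 3L != 0L
  data.frame(alignment_position = pos[sel],
             indel_length = lens[sel],
             frame_delta = lens[sel] %% 3L)
}

#' Classify a CIS against a gene's transcript variants
#'
#' For every transcript variant, computes the overlap of the CIS interval
#' with the variant's exons. An exonization event is emitted when at least
#' half of the CIS is expressed or the overlap reaches `min_overlap_nt`.
#' Splice-site plausibility (`splice_ok`) checks the gene sequence for `AG`
#' immediately upstream and `GT` immediately downstream of the expressed
#' block. When the transcript has a known CDS start, the reading frame of
#' the CIS start within that CDS is reported (+1/+2/+3), `NA` otherwise.
#'
#' @param cis List or one-row `data.frame` with `start`, `end` (0-based
#'   half-open, gene-local).
#' @param gene A [gene_model()].
#' @param min_fraction Fraction-of-CIS threshold (default 0.5).
#' @param min_overlap_nt Absolute overlap threshold in nt (default 30).
#' @return `data.frame` with `transcript_id`, `overlap_start`, `overlap_end`,
#'   `overlap_nt`, `fraction_of_cis`, `frame`, `splice_ok`.
#' @export
exonization_status <- function(cis, gene, min_fraction = 0.5,
                               min_overlap_nt = 30L) {
  cs <- as.integer(cis$start); ce <- as.integer(cis$end)
  L <- nchar(gene$sequence)
  if (cs < 0L || ce > L || ce <= cs)
    stop("CIS interval outside gene coordinates")
  out <- data.frame(transcript_id = character(), overlap_start = integer(),
                    overlap_end = integer(), overlap_nt = integer(),
                    fraction_of_cis = numeric(), frame = integer(),
                    splice_ok = logical(), stringsAsFactors = FALSE)
  for (t in gene$transcripts) {
    ov <- intersect_intervals(t$exons, intervals_df(cs, ce))
    nt <- interval_total(ov)
    frac <- nt / (ce - cs)
    if (nt == 0L || (frac < min_fraction && nt < min_overlap_nt)) next
    b0 <- min(ov$start); b1 <- max(ov$end)
    # expressed block = exonic span covering the overlap
    up <- if (b0 >= 2L) substring(gene$sequence, b0 - 1L, b0) else ""
    dn <- if (b1 + 2L <= L) substring(gene$sequence, b1 + 1L, b1 + 2L) else ""
    splice_ok <- identical(up, "AG") && identical(dn, "GT")
    frame <- NA_integer_
    if (!is.na(t$cds_start)) {
      # spliced-coordinate offset of the CIS start (or of the first
      # expressed CIS base) relative to the CDS start
      exl <- t$exons
      pos <- 0L; spliced <- NA_integer_
      for (i in seq_len(nrow(exl))) {
        if (b0 >= exl$start[i] && b0 < exl$end[i]) {
          spliced <- pos + (b0 - exl$start[i])
          break
        }
        pos <- pos + (exl$end[i] - exl$start[i])
      }
      if (!is.na(spliced))
        frame <- ((spliced - t$cds_start) %% 3L) + 1L
    }
    out <- rbind(out, data.frame(
      transcript_id = t$transcript_id, overlap_start = b0, overlap_end = b1,
      overlap_nt = nt, fraction_of_cis = frac, frame = frame,
      splice_ok = splice_ok, stringsAsFactors = FALSE))
  }
  out
}
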