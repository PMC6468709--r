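# Shared fixtures and independent oracles for the test suite.

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Independent full Smith-Waterman oracle (Biostrings dynamic programming);
# same gap convention as the package: gap of length L costs open + L * ext.
sw_oracle_score <- function(q, s, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend))
}

# Brute-force DUST window scores: triplet counts computed directly.
dust_oracle <- function(seq, window, threshold) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  if (n < window) return(data.frame(start = integer(), end = integer()))
  hits <- logical(n)
  for (w0 in 0:(n - window)) {
    win <- x[(w0 + 1):(w0 + window)]
    tri <- vapply(seq_len(window - 2),
                  function(i) paste(win[i:(i + 2)], collapse = ""),
                  character(1))
    tri <- tri[!grepl("N", tri)]
    ct <- table(tri)
    score <- sum(ct * (ct - 1) / 2) / (window - 2)
    if (score > threshold) hits[(w0 + 1):(w0 + window)] <- TRUE
  }
  r <- rle(hits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Exhaustive maximum-weight order-consistent subset of HSPs.
chain_oracle <- function(hsps) {
  n <- nrow(hsps)
  best_w <- -1; best <- integer(0)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > 1) {
      o <- idx[order(hsps$q_start[idx])]
      if (any(diff(hsps$q_start[o]) <= 0) || any(diff(hsps$s_start[o]) <= 0))
        next
    }
    w <- sum(hsps$q_end[idx] - hsps$q_start[idx])
    if (w > best_w) { best_w <- w; best <- idx }
  }
  list(weight = best_w, idx = best)
}

# Per-position boolean-array oracle for interval union / intersection.
bitmap_union_len <- function(iv, n) {
  b <- logical(n)
  for (i in seq_len(nrow(iv))) b[(iv$start[i] + 1):iv$end[i]] <- TRUE
  sum(b)
}
bitmap_intersect <- function(list_iv, n) {
  b <- rep(TRUE, n)
  for (iv in list_iv) {
    bi <- logical(n)
    for (i in seq_len(nrow(iv))) bi[(iv$start[i] + 1):iv$end[i]] <- TRUE
    b <- b & bi
  }
  b
}

# Brute force over all monotone exon pairings, maximizing the stated score.
exon_pairing_oracle <- function(la, lb, gap = 1.0) {
  na <- length(la); nb <- length(lb)
  best <- list(score = -Inf, pairs = NULL)
  rec <- function(i, j, score, pairs) {
    if (i > na || j > nb) {
      score <- score - gap * ((na - i + 1) + (nb - j + 1))
      if (score > best$score) best <<- list(score = score, pairs = pairs)
      return()
    }
    rec(i + 1, j + 1, score - abs(log(la[i] / lb[j])), rbind(pairs, c(i, j)))
    rec(i + 1, j, score - gap, pairs)
    rec(i, j + 1, score - gap, pairs)
  }
  rec(1, 1, 0, NULL)
  best
}

# Direct per-frame stop scan (codon table written out independently).
stops_oracle <- function(seq, frame) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  found <- FALSE
  i <- frame
  while (i + 2 <= n) {
    if (substring(seq, i, i + 2) %in% stops) found <- TRUE
    i <- i + 3
  }
  found
}

# Fisher exact two-sided p for a 2x2 table by hypergeometric enumeration.
fisher_oracle <- function(x1, x2, n) {
  k <- x1 + x2  # total successes; margin fixed
  support <- max(0, k - n):min(n, k)
  probs <- stats::dhyper(support, n, n, k)
  p_obs <- stats::dhyper(x1, n, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Cached Karlin-Altschul calibration shared across test files.
test_ka_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_ka_params()
    cache
  }
})

# Small synthetic family reused by several files.
test_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_family(sim_config(
        n_genes = 2L, introns_per_gene = 3L,
        intron_length_range = c(1200L, 1800L), n_planted_cis = 3L,
        duplication = TRUE, exonize = TRUE, stop_skip = TRUE,
        frameshift = TRUE, seed = 77L))
    cache
  }
})
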