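#' Correspondence between introns of two orthologous gene models
#'
#' When the reference transcripts have the same number of introns the
#' pairing is ordinal identity. Otherwise the two exon-length vectors are
#' globally aligned (similarity of exons of lengths `a`, `b` is
#' `-|log(a/b)|`, gap penalty 1.0) and intron `k` of one gene pairs with
#' intron `l` of the other when the exons immediately upstream of the two
#' introns are aligned. The pairing is monotone (no crossing).
#'
#' @param gene_a,gene_b [gene_model()] objects.
#' @return `data.frame` with columns `ordinal_a`, `ordinal_b`.
#' @export
correspond_introns <- function(gene_a, gene_b) {
  ia <- extract_introns(gene_a)
  ib <- extract_introns(gene_b)
  empty <- data.frame(ordinal_a = integer(), ordinal_b = integer())
  if (nrow(ia) == 0L || nrow(ib) == 0L) return(empty)
  ea <- reference_transcript(gene_a)$exons
  eb <- reference_transcript(gene_b)$exons
  na <- nrow(ea); nb <- nrow(eb)
  if (na == nb) {
    ords <- intersect(ia$ordinal, ib$ordinal)
    return(data.frame(ordinal_a = ords, ordinal_b = ords))
  }
  la <- ea$end - ea$start
  lb <- eb$end - eb$start
  pairs <- align_exon_vectors(la, lb)
  # intron k lies downstream of exon k: pair introns by their upstream exons
  out <- empty
  for (r in seq_len(nrow(pairs))) {
    k <- pairs$a[r]; l <- pairs$b[r]
    if (k < na && l < nb &&
        k %in% ia$ordinal && l %in% ib$ordinal)
      out <- rbind(out, data.frame(ordinal_a = k, ordinal_b = l))
  }
  out
}

# Needleman-Wunsch on exon-length vectors; similarity -|log(a/b)|, gap -1
align_exon_vectors <- function(la, lb, gap = 1.0) {
  na <- length(la); nb <- length(lb)
  S <- matrix(-Inf, na + 1L, nb + 1L)
  S[1, ] <- -gap * (0:nb)
  S[, 1] <- -gap * (0:na)
  tb <- matrix(0L, na + 1L, nb + 1L)  # 1 diag, 2 up (gap in b), 3 left
  tb[1, -1] <- 3L; tb[-1, 1] <- 2L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d <- S[i, j] - abs(log(la[i] / lb[j]))
      u <- S[i, j + 1L] - gap
      l <- S[i + 1L, j] - gap
      best <- max(d, u, l)
      S[i + 1L, j + 1L] <- best
      tb[i + 1L, j + 1L] <- if (best == d) 1L else if (best == u) 2L else 3L
    }
  }
  i <- na + 1L; j <- nb + 1L
  a <- integer(); b <- integer()
  while (i > 1L || j > 1L) {
    t <- tb[i, j]
    if (t == 1L) { a <- c(i - 1L, a); b <- c(j - 1L, b); i <- i - 1L; j <- j - 1L }
    else if (t == 2L) i <- i - 1L
    else j <- j - 1L
  }
  data.frame(a = a, b = b)
}

#' Filter HSPs by E-value
#'
#' Keeps exactly the HSPs whose E-value is less than or equal to
#' `max_evalue`. The significance boundary is inclusive: an HSP at exactly
#' the threshold is kept.
#'
#' @param hsps HSP `data.frame` from [local_align()].
#' @param max_evalue Inclusive E-value bound (default `9e-10`).
#' @return Filtered HSP `data.frame`.
#' @export
filter_hsps <- function(hsps, max_evalue = 9e-10) {
  hsps[hsps$evalue <= max_evalue, , drop = FALSE]
}

#' Order-consistent HSP chain
#'
#' Among HSPs between one pair of corresponding introns, returns the
#' maximum-weight subset whose query and subject start coordinates are both
#' strictly increasing (same order in the two introns). Weight is the
#' number of aligned anchor (query) nucleotides. Computed by weighted
#' longest-increasing-subsequence; equal-weight ties prefer the chain with
#' the smaller total query start sum (upstream-most).
#'
#' @param hsps HSP `data.frame`.
#' @return The chained subset, in query order.
#' @export
chain_order_consistent <- function(hsps) {
  n <- nrow(hsps)
  if (n <= 1L) return(hsps)
  o <- order(hsps$q_start, hsps$s_start)
  h <- hsps[o, , drop = FALSE]
  w <- as.numeric(h$q_end - h$q_start)
  best_w <- w
  best_ss <- as.numeric(h$q_start)  # start-coordinate sum of best chain
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i > 1L) for (j in seq_len(i - 1L)) {
      if (h$q_start[j] < h$q_start[i] && h$s_start[j] < h$s_start[i]) {
        cand_w <- best_w[j] + w[i]
        cand_ss <- best_ss[j] + h$q_start[i]
        if (cand_w > best_w[i] ||
            (cand_w == best_w[i] && cand_ss < best_ss[i])) {
          best_w[i] <- cand_w
          best_ss[i] <- cand_ss
          prev[i] <- j
        }
      }
    }
  }
  end <- which(best_w == max(best_w))
  if (length(end) > 1L) end <- end[which.min(best_ss[end])]
  idx <- integer()
  i <- end[1L]
  while (i > 0L) { idx <- c(i, idx); i <- prev[i] }
  out <- h[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor-side union of chained HSP intervals
#'
#' Merges the anchor-side intervals of the chained HSPs; the union length is
#' the conserved-nucleotide count contributed by this intron and target
#' (each anchor position counted once, never double-counted across
#' overlapping HSPs).
#'
#' @param chained HSP `data.frame` (already filtered and chained).
#' @param anchor_side `"query"` or `"subject"`: which side of the HSPs is
#'   the anchor intron.
#' @return `data.frame` of merged 0-based half-open intervals
#'   (`start`, `end`).
#' @export
conserved_intervals <- function(chained, anchor_side = c("query", "subject")) {
  anchor_side <- match.arg(anchor_side)
  if (nrow(chained) == 0L) return(intervals_df())
  iv <- if (anchor_side == "query")
    intervals_df(chained$q_start, chained$q_end)
  else intervals_df(chained$s_start, chained$s_end)
  merge_intervals(iv)
}

#' Multi-species intersection of conserved intervals
#'
#' Positions of the anchor intron covered in *every* target species form
#' maximal runs; runs of at least `min_len` nucleotides become CIS calls
#' conserved in the full target set.
#'
#' @param per_target Named list (one element per target species) of interval
#'   `data.frame`s on the same anchor intron.
#' @param min_len Minimum call length in nucleotides (default 30).
#' @return `data.frame` with `start`, `end`, `conserved_in` (targets joined
#'   by `+`).
#' @export
intersect_multispecies <- function(per_target, min_len = 30L) {
  stopifnot(length(per_target) > 0)
  runs <- Reduce(intersect_intervals, per_target)
  runs <- runs[runs$end - runs$start >= min_len, , drop = FALSE]
  rownames(runs) <- NULL
  if (nrow(runs) > 0)
    runs$conserved_in <- paste(names(per_target), collapse = "+")
  else runs$conserved_in <- character(0)
  runs
}

#' Conservation report (per anchor -> target accounting)
#'
#' Sums per-target conserved anchor nucleotides over all genes and introns
#' and expresses them as a percentage of the anchor species' total intron
#' pool. Counts are anchor-side unions: each anchor position is counted at
#' most once per target.
#'
#' @param anchor_species Anchor species label.
#' @param conserved Named integer vector: conserved nucleotides per target.
#' @param total Total intronic nucleotides of the anchor species.
#' @return `data.frame` with `anchor`, `target`, `conserved_nt`, `total_nt`,
#'   `percentage` (half-up, 3 decimals).
#' @export
build_report <- function(anchor_species, conserved, total) {
  if (total <= 0) stop("empty intron pool for anchor '", anchor_species, "'")
  data.frame(anchor = anchor_species,
             target = names(conserved),
             conserved_nt = as.integer(conserved),
             total_nt = as.integer(total),
             percentage = conservation_percentage(as.integer(conserved),
                                                  total),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect an intragene duplicated segment
#'
#' Aligns an inter-exon region against itself, excluding the trivial
#' self-diagonal, and reports disjoint off-diagonal segment pairs passing
#' the E-value threshold as candidate duplicated copies with their percent
#' identity.
#'
#' @param region DNA string of one inter-exon region.
#' @param scheme,params Alignment scheme and Karlin-Altschul parameters.
#' @param max_evalue Inclusive E-value bound (default `9e-10`).
#' @param min_copy_gap Minimum diagonal offset between copies (default 20).
#' @return `data.frame` with copy intervals (`a_start`, `a_end`, `b_start`,
#'   `b_end`), `identity`, `score`, `evalue`; copy A is the upstream one.
#' @export
detect_intragene_duplication <- function(region, scheme = scoring_scheme(),
                                         params = default_ka_params(scheme),
                                         max_evalue = 9e-10,
                                         min_copy_gap = 20L) {
  hs <- local_align(region, region, scheme, params, max_evalue = max_evalue,
                    min_diag = as.integer(min_copy_gap))
  hs <- hs[hs$q_start < hs$s_start, , drop = FALSE]  # one of each mirror pair
  hs <- hs[hs$q_end <= hs$s_start, , drop = FALSE]   # copies must be disjoint
  out <- data.frame(a_start = hs$q_start, a_end = hs$q_end,
                    b_start = hs$s_start, b_end = hs$s_end,
                    identity = hs$identity, score = hs$score,
                    evalue = hs$evalue)
  rownames(out) <- NULL
  out
}
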