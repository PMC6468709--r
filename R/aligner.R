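#' Scoring scheme for local nucleotide alignment
#'
#' Defaults are the classic blastn parameters: match +2, mismatch -3, gap
#' opening 5, gap extension 2. A gap of length L costs
#' `gap_open + gap_extend * L`. The expected pair score under the background
#' frequencies must be negative for local-alignment (E-value) theory to
#' apply.
#'
#' @param match Positive match reward.
#' @param mismatch Negative mismatch penalty.
#' @param gap_open Non-negative gap opening penalty.
#' @param gap_extend Non-negative per-column gap extension penalty.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Low-complexity masking (DUST-style)
#'
#' For every window, the score is `sum_t c_t (c_t - 1) / 2` over the
#' window's overlapping-triplet counts `c_t`, normalised by the number of
#' triplets (`window - 2`). Windows scoring above `threshold` are merged
#' into maximal masked intervals. Masked positions are excluded from
#' alignment seeding but may be crossed by extension. Sequences shorter
#' than the window are never masked.
#'
#' @param seq DNA string.
#' @param window Window length (>= 3); default 64.
#' @param threshold Score threshold; default 2.
#' @return `data.frame` of masked 0-based half-open intervals
#'   (`start`, `end`).
#' @export
mask_low_complexity <- function(seq, window = 64L, threshold = 2) {
  seq <- check_dna(seq)
  stopifnot(window >= 3)
  as.data.frame(cpp_mask_dust(seq, as.integer(window), threshold))
}

#' Karlin-Altschul parameters for an ungapped scheme
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` (bisection to 1e-9). `K` is
#' estimated by Monte-Carlo calibration of ungapped null alignments with a
#' fixed internal seed (gapped constants have no closed form; the ungapped
#' `K` uses the same extreme-value fit with `lambda` held at its analytic
#' value).
#'
#' @param scheme A [scoring_scheme()] (gap penalties ignored: ungapped).
#' @param background Base frequencies (A,C,G,T) summing to 1.
#' @param k_reps,k_len Monte-Carlo sample size and sequence length for the
#'   `K` estimate.
#' @return An object of class `ka_params` with `lambda`, `K`, `background`,
#'   and `mode = "ungapped"`.
#' @export
calibrate_ungapped <- function(scheme, background = rep(0.25, 4),
                               k_reps = 200L, k_len = 300L) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-8)
  smat <- matrix(scheme$mismatch, 4, 4)
  diag(smat) <- scheme$match
  pp <- outer(background, background)
  if (sum(pp * smat) >= 0)
    stop("scheme not local-alignment admissible: expected pair score >= 0")
  f <- function(lam) sum(pp * exp(lam * smat)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 1e-9
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  # Monte-Carlo K with lambda fixed: max ungapped score of null pairs is
  # Gumbel with location ln(K m n) / lambda
  big_gap <- as.integer(1e6)
  scores <- withr::with_seed(424243L, {
    vapply(seq_len(k_reps), function(i) {
      q <- random_dna(k_len, background)
      s <- random_dna(k_len, background)
      cpp_sw_score(q, s, scheme$match, scheme$mismatch, big_gap, big_gap)
    }, numeric(1))
  })
  u <- mean(scores) - 0.57722 / lambda
  K <- exp(lambda * u) / (as.numeric(k_len) * k_len)
  structure(list(lambda = lambda, K = K, background = background,
                 mode = "ungapped", reps = k_reps),
            class = "ka_params")
}

random_dna <- function(n, background = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = background),
        collapse = "")
}

#' Empirical E-value calibration
#'
#' Aligns `reps` pairs of i.i.d. random sequences of lengths `m`, `n` under
#' the full (gapped) scheme and fits the null score distribution to the
#' extreme-value form `P(S >= x) = 1 - exp(-K m n exp(-lambda x))` by the
#' method of moments, with bootstrap standard errors. The result is used as
#' the gapped-mode Karlin-Altschul parameters.
#'
#' @param scheme A [scoring_scheme()].
#' @param m,n Null sequence lengths.
#' @param reps Number of null pairs (>= 200).
#' @param seed RNG seed; identical seeds give identical tables.
#' @param background Base frequencies.
#' @return A `ka_params` object with `lambda`, `K`, their standard errors,
#'   the null `scores`, and `mode = "gapped-empirical"`.
#' @export
empirical_evalue_calibration <- function(scheme, m = 500L, n = 500L,
                                         reps = 500L, seed = 101L,
                                         background = rep(0.25, 4)) {
  stopifnot(inherits(scheme, "scoring_scheme"), reps >= 200)
  scores <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(reps), function(i) {
      q <- random_dna(m, background)
      s <- random_dna(n, background)
      cpp_sw_score(q, s, scheme$match, scheme$mismatch,
                   scheme$gap_open, scheme$gap_extend)
    }, numeric(1))
  })
  if (sd(scores) == 0)
    stop("degenerate calibration: all null scores equal")
  fit <- function(x) {
    lam <- pi / (sd(x) * sqrt(6))
    u <- mean(x) - 0.57722 / lam
    c(lambda = lam, K = exp(lam * u) / (as.numeric(m) * n))
  }
  est <- fit(scores)
  boot <- withr::with_seed(as.integer(seed) + 1L, {
    t(vapply(seq_len(100L),
             function(i) fit(sample(scores, replace = TRUE)),
             numeric(2)))
  })
  structure(list(lambda = unname(est["lambda"]), K = unname(est["K"]),
                 lambda_se = sd(boot[, 1]), K_se = sd(boot[, 2]),
                 background = background, mode = "gapped-empirical",
                 reps = reps, m = m, n = n, seed = as.integer(seed),
                 scores = scores),
            class = "ka_params")
}

#' @export
print.ka_params <- function(x, ...) {
  cat(sprintf("<ka_params> mode=%s lambda=%.4f K=%.4g\n",
              x$mode, x$lambda, x$K))
  invisible(x)
}

# cached default gapped calibration for the default scheme
.ka_cache <- new.env(parent = emptyenv())

#' Default gapped Karlin-Altschul parameters
#'
#' Empirical calibration of the default blastn-style scheme (500 null pairs
#' of 500 nt, fixed seed 101), computed once per session and cached.
#'
#' @param scheme A [scoring_scheme()]; defaults to [scoring_scheme()].
#' @return A `ka_params` object.
#' @export
default_ka_params <- function(scheme = scoring_scheme()) {
  key <- paste(scheme$match, scheme$mismatch, scheme$gap_open,
               scheme$gap_extend, sep = "/")
  if (is.null(.ka_cache[[key]]))
    .ka_cache[[key]] <- empirical_evalue_calibration(scheme)
  .ka_cache[[key]]
}

#' E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of alignments
#' scoring at least `S` between random sequences of lengths `m` and `n`.
#'
#' @param score Alignment score(s).
#' @param m,n Lengths of the two sequences searched.
#' @param params A `ka_params` object.
#' @return Numeric E-value(s).
#' @export
hsp_evalue <- function(score, m, n, params) {
  params$K * as.numeric(m) * as.numeric(n) * exp(-params$lambda * score)
}

#' Seeded local alignment with affine gaps and E-values
#'
#' BLAST-style seed-and-extend: exact-match words of length `word` outside
#' masked intervals are grouped by diagonal and extended with banded
#' affine-gap dynamic programming under an X-drop rule; overlapping HSPs
#' keep the maximum score. Each HSP's E-value is
#' `K * m * n * exp(-lambda * score)` with `m`, `n` the full sequence
#' lengths. Only same-orientation (Plus/Plus) alignments are computed.
#'
#' @param q,s Query and subject DNA strings (non-empty).
#' @param scheme A [scoring_scheme()].
#' @param params A `ka_params` object (see [default_ka_params()]).
#' @param max_evalue Keep HSPs with E-value `<=` this bound (inclusive);
#'   default `Inf` keeps everything with positive score.
#' @param word Seed word length (default 11).
#' @param band Band half-width around the seed diagonal (default 40).
#' @param xdrop X-drop extension cutoff (default 30).
#' @param mask Apply [mask_low_complexity()] before seeding (default TRUE).
#' @param min_diag Minimum |diagonal| for seeds; positive values exclude
#'   near-self-diagonal seeds (used for self-alignment).
#' @return `data.frame` of HSPs sorted by score (descending): `q_start`,
#'   `q_end`, `s_start`, `s_end` (0-based half-open), `score`, `evalue`,
#'   `identity`, `matches`, `aligned_columns`, `cigar`.
#' @export
local_align <- function(q, s, scheme = scoring_scheme(),
                        params = default_ka_params(scheme),
                        max_evalue = Inf, word = 11L, band = 40L,
                        xdrop = 30L, mask = TRUE, min_diag = 0L) {
  q <- check_dna(q, "query"); s <- check_dna(s, "subject")
  stopifnot(nchar(q) > 0, nchar(s) > 0)
  mask_pos <- function(x) {
    if (!mask) return(integer(0))
    iv <- cpp_mask_dust(x, 64L, 2)
    if (nrow(iv) == 0L) return(integer(0))
    unlist(lapply(seq_len(nrow(iv)),
                  function(i) seq.int(iv$start[i], iv$end[i] - 1L)))
  }
  hs <- cpp_seed_extend(q, s, scheme$match, scheme$mismatch, scheme$gap_open,
                        scheme$gap_extend, as.integer(word), as.integer(band),
                        as.integer(xdrop), mask_pos(q), mask_pos(s),
                        as.integer(min_diag))
  hs <- as.data.frame(hs)
  hs$evalue <- hsp_evalue(hs$score, nchar(q), nchar(s), params)
  hs$identity <- ifelse(hs$aligned_columns > 0,
                        hs$matches / hs$aligned_columns, 0)
  hs <- hs[hs$evalue <= max_evalue, , drop = FALSE]
  hs <- hs[order(-hs$score, hs$q_start, hs$s_start), , drop = FALSE]
  rownames(hs) <- NULL
  hs
}
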