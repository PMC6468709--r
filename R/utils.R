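#' Round half away from zero
#'
#' Fixed-precision rounding where ties go away from zero (`0.0005` at three
#' decimals becomes `0.001`), unlike [base::round()]'s round-half-even.
#' Report percentages are printed with this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# validate a DNA string over {A,C,G,T,N}; returns the uppercased string
check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s))
    stop(what, " contains symbols outside {A,C,G,T,N}")
  s
}

# 0-based half-open intervals as a two-column data.frame
intervals_df <- function(start = integer(), end = integer()) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

# merge overlapping/adjacent-free union of 0-based half-open intervals
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(intervals_df())
  ir <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  intervals_df(IRanges::start(ir) - 1L, IRanges::end(ir))
}

# intersection of two interval sets (0-based half-open)
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(intervals_df())
  ia <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  ib <- IRanges::IRanges(start = b$start + 1L, end = b$end)
  ir <- IRanges::intersect(ia, ib)
  intervals_df(IRanges::start(ir) - 1L, IRanges::end(ir))
}

interval_total <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  sum(iv$end - iv$start)
}
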