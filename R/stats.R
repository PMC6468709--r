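#' Conservation percentage
#'
#' `100 * conserved / total`, rounded half-up to three decimals -- the form
#' in which conservation tables print their percentages.
#'
#' @param conserved Conserved nucleotide count(s).
#' @param total Total intronic nucleotides (> 0).
#' @return Numeric percentage(s).
#' @export
conservation_percentage <- function(conserved, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(conserved < 0) || any(conserved > total))
    stop("conserved must lie in [0, total]")
  round_half_up(100 * conserved / total, 3)
}

#' Percent increase of one conservation level over another
#'
#' `100 * (a - b) / b`, rounded half-up to the nearest integer for headline
#' reporting (set `digits` for more precision).
#'
#' @param a,b Conservation percentages (`b > 0`).
#' @param digits Decimal places of the rounded result (default 0).
#' @return Rounded percent increase.
#' @export
percent_increase <- function(a, b, digits = 0) {
  if (b <= 0) stop("baseline must be positive")
  round_half_up(100 * (a - b) / b, digits)
}

#' Two-proportion test on a shared denominator
#'
#' Tests whether two conserved-nucleotide counts out of a common intron-pool
#' size differ, via the two-sided Pearson chi-square test on the 2x2 table
#' `((x1, n - x1), (x2, n - x2))` without continuity correction. When any
#' expected cell is 5 or fewer, Fisher's exact test is used instead; the
#' method applied is recorded. The two proportions are treated as
#' independent samples of size `n` each -- a simplification, since both are
#' fractions of the same anchor intron pool.
#'
#' @param x1,x2 Success (conserved nucleotide) counts.
#' @param n Common denominator (> 0).
#' @return List of class `two_proportion_result`: `x1`, `x2`, `n`, `p1`,
#'   `p2`, `statistic`, `p_value`, `method`.
#' @export
two_proportion_test <- function(x1, x2, n) {
  stopifnot(n > 0, x1 >= 0, x2 >= 0, x1 <= n, x2 <= n)
  tab <- matrix(c(x1, n - x1, x2, n - x2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) {
    ft <- fisher.test(tab)
    res <- list(statistic = NA_real_, p_value = ft$p.value,
                method = "fisher-exact")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    res <- list(statistic = unname(ct$statistic), p_value = ct$p.value,
                method = "pearson-chi-square")
  }
  structure(c(list(x1 = x1, x2 = x2, n = n, p1 = x1 / n, p2 = x2 / n), res),
            class = "two_proportion_result")
}

#' @export
print.two_proportion_result <- function(x, ...) {
  cat(sprintf("two-proportion test (%s): %d/%d vs %d/%d, p = %.3g\n",
              x$method, x$x1, x$n, x$x2, x$n, x$p_value))
  invisible(x)
}
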