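# 2x2 enrichment analysis of domain annotation between variant groups
# (e.g. rare vs common, pathogenic vs other). The table crosses
# (annotated vs not) with (group 1 vs group 2); the chi-square test of
# independence and the odds ratio quantify whether one group's variants
# fall onto annotated domains more often than the other's.

#' Cross-tabulate annotation and group flags into a 2x2 table
#'
#' @param annotated_flags Logical: variant falls on an annotated domain.
#' @param group_flags Logical: variant belongs to group 1 (e.g. rare,
#'   pathogenic).
#' @return `contingency_table` with cells `a` (group1 & annotated), `b`
#'   (group1 & not), `c` (group2 & annotated), `d` (group2 & not).
#' @export
make_table <- function(annotated_flags, group_flags) {
  stopifnot(is.logical(annotated_flags), is.logical(group_flags))
  if (length(annotated_flags) != length(group_flags)) {
    stop("flag vectors must have equal length")
  }
  if (length(annotated_flags) == 0L) stop("empty input")
  contingency_table(a = sum(group_flags & annotated_flags),
                    b = sum(group_flags & !annotated_flags),
                    c = sum(!group_flags & annotated_flags),
                    d = sum(!group_flags & !annotated_flags))
}

#' Construct a 2x2 contingency table from counts
#' @param a,b,c,d Non-negative counts: rows are groups 1/2, columns
#'   annotated / not annotated.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("negative cell count")
  if (sum(cells) <= 0) stop("empty contingency table")
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("group1", "group2"),
                              c("annotated", "not_annotated")))
  print(m)
  invisible(x)
}

#' Chi-square test of independence for a 2x2 table
#'
#' Uses the closed-form statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, identical to summing
#' `(O - E)^2 / E` over the four cells; with `yates = TRUE` the continuity
#' correction subtracts `n/2` from `|ad - bc|` before squaring. P-value
#' from the chi-square distribution with 1 degree of freedom. A zero
#' marginal leaves the test undefined and raises an error; expected counts
#' below 1 trigger a validity warning.
#'
#' @param table A `contingency_table`.
#' @param yates Apply Yates' continuity correction (default `FALSE`).
#' @return List: `statistic`, `p_value`, `expected` (4 expected counts,
#'   same a/b/c/d layout), `yates`.
#' @export
chi_square_test <- function(table, yates = FALSE) {
  # double precision: cell products overflow integer range at cohort scale
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  c <- as.numeric(table$c); d <- as.numeric(table$d)
  n <- a + b + c + d
  m <- c(r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d)
  if (any(m == 0)) stop("zero marginal: chi-square test undefined")
  expected <- c(a = m["r1"] * m["c1"], b = m["r1"] * m["c2"],
                c = m["r2"] * m["c1"], d = m["r2"] * m["c2"]) / n
  names(expected) <- c("a", "b", "c", "d")
  if (any(expected < 1)) {
    warning("expected cell count below 1: chi-square approximation unreliable",
            call. = FALSE)
  }
  diff <- abs(a * d - b * c)
  if (yates) diff <- max(0, diff - n / 2)
  stat <- n * diff^2 / prod(m)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected, yates = yates)
}

#' Odds ratio of a 2x2 table
#'
#' `(a d) / (b c)`; when any cell is zero the Haldane-Anscombe correction
#' adds 0.5 to every cell first (flagged in the result).
#'
#' @param table A `contingency_table`.
#' @return List: `or`, `corrected` (logical).
#' @export
odds_ratio <- function(table) {
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  c <- as.numeric(table$c); d <- as.numeric(table$d)
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(or = (a * d) / (b * c), corrected = corrected)
}

#' Full enrichment report for an annotated variant cohort
#'
#' Joins a per-variant annotation flag with a per-variant group flag,
#' builds the 2x2 table and reports the chi-square test (with and without
#' Yates), the odds ratio, and per-group annotated proportions.
#'
#' @param annotated Logical vector (or an [annotate_variants()] output
#'   collapsed per query via `hit`).
#' @param group Logical vector, `TRUE` for group 1; `NA`s are dropped
#'   pairwise with a count.
#' @return `enrichment_result`: `table`, `chi_square`, `chi_square_yates`,
#'   `odds_ratio`, `or_corrected`, `p_value`, `expected`, `proportions`
#'   (annotated fraction per group), `n_dropped`.
#' @export
enrichment_report <- function(annotated, group) {
  stopifnot(length(annotated) == length(group))
  keep <- !is.na(annotated) & !is.na(group)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " variant(s) without group/annotation label dropped")
  }
  tab <- make_table(annotated[keep], group[keep])
  cs <- chi_square_test(tab, yates = FALSE)
  csy <- chi_square_test(tab, yates = TRUE)
  orr <- odds_ratio(tab)
  structure(list(
    table = tab,
    chi_square = cs$statistic,
    chi_square_yates = csy$statistic,
    p_value = cs$p_value,
    expected = cs$expected,
    odds_ratio = orr$or,
    or_corrected = orr$corrected,
    proportions = c(group1 = tab$a / (tab$a + tab$b),
                    group2 = tab$c / (tab$c + tab$d)),
    n_dropped = n_dropped), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  print(x$table)
  cat(sprintf("annotated: %.1f%% (group1) vs %.1f%% (group2)\n",
              100 * x$proportions[1], 100 * x$proportions[2]))
  cat(sprintf("chi-square = %.3f (Yates %.3f), p = %.3g, OR = %.3f%s\n",
              x$chi_square, x$chi_square_yates, x$p_value, x$odds_ratio,
              if (x$or_corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}
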