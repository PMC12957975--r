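#' Normality- and variance-gated two-sample test
#'
#' Compares a continuous variable (age, symptom score) between two groups.
#' Both samples are first assessed with the Shapiro-Wilk normality test and
#' Levene's test for homogeneity of variance at level `alpha`; if all gates
#' pass, a pooled-variance two-sample t-test is reported, otherwise the
#' Mann-Whitney U test with its tie-corrected normal-approximation z (no
#' continuity correction).  Samples that Shapiro-Wilk cannot assess (for
#' instance all-identical values) are treated as non-normal.
#'
#' @param x,y numeric vectors (n >= 3 each).
#' @param alpha gate level for the normality and variance tests.
#' @param welch use Welch's t instead of the pooled-variance t when the
#'   parametric branch is taken.
#' @return list: `test` (`"t"` or `"mann-whitney"`), `statistic` (t or z),
#'   `p` (two-tailed), `U` (for the nonparametric branch), and the gate
#'   p-values.
#' @export
gated_two_sample_test <- function(x, y, alpha = 0.05, welch = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3 || length(y) < 3) {
    stop("gated_two_sample_test: need at least 3 observations per group")
  }
  sw_p <- function(v) {
    tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
  }
  px <- sw_p(x); py <- sw_p(y)
  lev <- tryCatch({
    g <- factor(rep(c("x", "y"), c(length(x), length(y))))
    suppressWarnings(car::leveneTest(c(x, y), g)[["Pr(>F)"]][1])
  }, error = function(e) 0)
  normal <- px > alpha && py > alpha && lev > alpha
  if (normal) {
    tt <- t.test(x, y, var.equal = !welch)
    return(list(test = "t", statistic = unname(tt$statistic),
                p = tt$p.value, U = NA_real_,
                shapiro_p = c(x = px, y = py), levene_p = lev))
  }
  mw <- mann_whitney_z(x, y)
  list(test = "mann-whitney", statistic = mw$z, p = mw$p, U = mw$U,
       shapiro_p = c(x = px, y = py), levene_p = lev)
}

#' Mann-Whitney U with tie-corrected normal approximation
#'
#' `U` counts pairs where `x` exceeds `y` (plus half-ties); `z` standardizes
#' `U` by its null mean `n1*n2/2` and the tie-corrected variance
#' `n1*n2/12 * ((n+1) - sum(t^3 - t)/(n*(n-1)))`.  No continuity correction.
#'
#' @param x,y numeric vectors.
#' @return list with `U`, `z`, and the two-tailed `p`.
#' @export
mann_whitney_u <- function(x, y) {
  mann_whitney_z(as.numeric(x), as.numeric(y))
}

mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (v > 0) (U - mu) / sqrt(v) else 0
  list(U = U, z = z, p = 2 * pnorm(-abs(z)))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Plain Pearson chi-square without continuity correction:
#' `sum (O - E)^2 / E` over the four cells with expectations from the margin
#' products, referred to a chi-square distribution with 1 degree of freedom.
#'
#' @param table 2x2 matrix of counts (rows = groups, columns = categories),
#'   or four counts `a, b, c, d` given row-wise.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("chi_square_2x2: need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) {
    stop("chi_square_2x2: counts must be nonnegative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi_square_2x2: zero margin")
  }
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), df = 1, p = ct$p.value)
}

#' Table-1-style demographics summary
#'
#' Consumes a demographics data.frame (or CSV path) with columns
#' `subject_id`, `group`, and any mix of continuous columns (compared with
#' [gated_two_sample_test()]) and a `sex` column (compared with
#' [chi_square_2x2()]).
#'
#' @param demographics data.frame or CSV path.
#' @param group_col grouping column (two levels).
#' @param continuous columns to compare as continuous.
#' @param categorical columns to compare as 2-level categorical.
#' @return data.frame with one row per variable: descriptives per group,
#'   test name, statistic, and two-tailed p.
#' @export
demographics_table <- function(demographics, group_col = "group",
                               continuous = NULL, categorical = NULL) {
  d <- if (is.character(demographics)) {
    read.csv(demographics, stringsAsFactors = FALSE)
  } else as.data.frame(demographics)
  if (!group_col %in% names(d)) stop("demographics_table: no group column")
  g <- factor(d[[group_col]])
  if (nlevels(g) != 2) stop("demographics_table: need exactly two groups")
  if (is.null(continuous)) {
    continuous <- setdiff(names(d)[vapply(d, is.numeric, logical(1))],
                          c(group_col, "subject_id"))
  }
  if (is.null(categorical)) {
    categorical <- intersect("sex", names(d))
  }
  rows <- list()
  for (v in continuous) {
    x <- d[[v]][g == levels(g)[1]]
    y <- d[[v]][g == levels(g)[2]]
    res <- gated_two_sample_test(x, y)
    rows[[v]] <- data.frame(
      variable = v,
      group1 = sprintf("%.2f (%.2f)", mean(x), sd(x)),
      group2 = sprintf("%.2f (%.2f)", mean(y), sd(y)),
      test = res$test, statistic = res$statistic, p = res$p
    )
  }
  for (v in categorical) {
    tab <- table(g, factor(d[[v]]))
    if (ncol(tab) != 2) next
    res <- chi_square_2x2(tab)
    rows[[v]] <- data.frame(
      variable = v,
      group1 = paste(tab[1, ], collapse = "/"),
      group2 = paste(tab[2, ], collapse = "/"),
      test = "chi-square", statistic = res$statistic, p = res$p
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
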