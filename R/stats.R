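#' Standard error of the mean
#'
#' Sample SD (n - 1 denominator) divided by the square root of n; the
#' error-bar statistic for replicate-level summaries.
#'
#' @param values numeric vector, n >= 2.
#' @return SEM (scalar).
#' @examples
#' sem(c(2, 4, 6))  # 2 / sqrt(3)
#' @export
sem <- function(values) {
  if (length(values) < 2L) stop("sem requires n >= 2")
  stats::sd(values) / sqrt(length(values))
}

.checkGroups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs n >= 2 for variance-based tests")
  groups
}

.groupsToDf <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with (k - 1, N - k) degrees of freedom and an
#' upper-tail F p-value, fitted via \code{stats::aov}. Zero between-group
#' variance gives F = 0, p = 1; zero variance both between and within groups
#' is undefined and raises an error.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2),
#'   typically per-sample replicate values.
#' @return a [StatsResult-class] with \code{testName = "one_way_anova"}.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # F = 13.5
#' @export
oneWayAnova <- function(groups) {
  groups <- .checkGroups(groups)
  df <- .groupsToDf(groups)
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  msB <- tab[["Mean Sq"]][1L]; msW <- tab[["Mean Sq"]][2L]
  if (msB == 0 && msW == 0)
    stop("undefined-F error: zero variance within and between groups")
  f <- if (msW == 0) Inf else msB / msW
  p <- if (msW == 0) 0 else stats::pf(f, tab$Df[1L], tab$Df[2L],
                                      lower.tail = FALSE)
  StatsResult("one_way_anova", statistic = f,
              df = c(between = tab$Df[1L], within = tab$Df[2L]),
              pValue = p)
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group comparisons after a one-way ANOVA, with the
#' Tukey-Kramer standard error for unequal group sizes:
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{MS_{within}/2\,(1/n_i + 1/n_j)}},
#' adjusted p-values from the studentized-range distribution with
#' \code{(k, N - k)} parameters (via \code{stats::TukeyHSD}/\code{ptukey}).
#'
#' @param groups named list of numeric vectors.
#' @param alpha familywise level used for the confidence intervals.
#' @return a [StatsResult-class] carrying the ANOVA F and a \code{pairwise}
#'   data.frame (\code{pair, mean_diff, adj_p}).
#' @examples
#' tukeyHsd(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(1.5, 2.5, 3.5)))
#' @export
tukeyHsd <- function(groups, alpha = 0.05) {
  groups <- .checkGroups(groups)
  an <- oneWayAnova(groups)
  df <- .groupsToDf(groups)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairwise <- data.frame(pair = rownames(tk),
                         mean_diff = tk[, "diff"],
                         adj_p = tk[, "p adj"],
                         row.names = NULL)
  StatsResult("tukey_hsd", statistic = an@statistic, df = an@df,
              pValue = an@pValue, pairwise = pairwise)
}

#' Unpaired Student's t-test
#'
#' Pooled-variance two-sample t with \code{df = n_a + n_b - 2} (Welch's
#' correction available behind \code{welch = TRUE}); two-tailed by default.
#' When both samples have zero variance: equal means are undefined (error);
#' unequal means follow the p -> 0 convention with a warning.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param twoTailed logical; if FALSE, the upper-tail p for mean(a) >
#'   mean(b) is returned.
#' @param welch logical; use Welch's unequal-variance form.
#' @return a [StatsResult-class] with \code{testName = "t_test_unpaired"}.
#' @examples
#' tTestUnpaired(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p ~= 0.0213
#' @export
tTestUnpaired <- function(a, b, twoTailed = TRUE, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      stop("undefined: zero pooled variance with equal means")
    warning("zero pooled variance with unequal means: p -> 0 convention")
    return(StatsResult("t_test_unpaired",
                       statistic = sign(mean(a) - mean(b)) * Inf,
                       df = length(a) + length(b) - 2L, pValue = 0))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  p <- if (twoTailed) tt$p.value
       else stats::pt(tt$statistic, tt$parameter, lower.tail = FALSE)
  StatsResult("t_test_unpaired", statistic = unname(tt$statistic),
              df = unname(tt$parameter), pValue = unname(p))
}
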