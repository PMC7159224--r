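# Common result row: one comparison per row, the package-wide statistics
# output shape.
.statResult <- function(comparison, statistic, df, p, pAdj = NA_real_,
                        method = "") {
  data.frame(comparison = comparison, statistic = statistic, df = df,
             p = p, p_adj = pAdj, method = method, stringsAsFactors = FALSE)
}

.checkTable <- function(df, valueCol, groupCol) {
  if (!all(c(valueCol, groupCol) %in% names(df)))
    nmStop("nm_invalid_input",
           sprintf("table must have columns '%s' and '%s'", groupCol, valueCol))
  g <- factor(df[[groupCol]])
  if (nlevels(g) < 2L)
    nmStop("nm_invalid_input", "at least 2 groups are required")
  if (any(table(g) < 2L))
    nmStop("nm_invalid_input", "every group needs at least 2 observations")
  g
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F = MS_between / MS_within on
#' (k - 1, N - k) degrees of freedom, the omnibus test used to compare
#' genotype means before many-to-one post hoc testing.
#'
#' @param df data.frame in long format.
#' @param valueCol,groupCol column names (defaults "value", "group").
#' @return one-row result data.frame with columns comparison, statistic,
#'   df (a string "df1,df2"), p, p_adj, method.
#' @export
oneWayAnova <- function(df, valueCol = "value", groupCol = "group") {
  g <- .checkTable(df, valueCol, groupCol)
  v <- df[[valueCol]]
  ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
  .statResult("omnibus", unname(ft$statistic),
              paste(ft$parameter, collapse = ","), ft$p.value,
              method = "one-way ANOVA")
}

#' Dunnett's many-to-one comparisons by seeded Monte Carlo
#'
#' Each non-control group is compared with the control via a t statistic
#' with the pooled within-group variance; the family-wise adjusted p-value
#' is \code{P(max_j |T_j| >= |t_j|)} under the joint null, where the T_j
#' follow the equicorrelated multivariate t distribution implied by the
#' shared control mean and the pooled variance estimate. That tail
#' probability is evaluated by Monte Carlo: standard-normal group means and
#' a shared chi-square variance draw reproduce the exact null dependence,
#' so the only error is simulation noise (about 1/sqrt(mcDraws)). With a
#' single comparison the procedure reduces to the two-sided two-sample
#' pooled t-test.
#'
#' @param df data.frame in long format.
#' @param control control group label.
#' @param mcDraws Monte Carlo draws (default 200000).
#' @param seed integer seed for the draws.
#' @param valueCol,groupCol column names.
#' @return result data.frame, one row per non-control group, with raw
#'   two-sided t-test p and Dunnett-adjusted p (adjusted >= raw by
#'   construction).
#' @export
dunnettTest <- function(df, control, mcDraws = 200000, seed = 1,
                        valueCol = "value", groupCol = "group") {
  g <- .checkTable(df, valueCol, groupCol)
  if (!control %in% levels(g))
    nmStop("nm_invalid_input", sprintf("control group '%s' not found", control))
  v <- df[[valueCol]]
  labs <- levels(g)
  means <- tapply(v, g, mean)
  ns <- tapply(v, g, length)
  vars <- tapply(v, g, stats::var)
  k <- length(labs)
  N <- sum(ns)
  dfW <- N - k
  s2 <- sum((ns - 1) * vars) / dfW
  if (s2 <= 0)
    nmStop("nm_invalid_input", "zero pooled within-group variance")
  others <- setdiff(labs, control)
  se <- sqrt(s2 * (1 / ns[others] + 1 / ns[[control]]))
  tObs <- (means[others] - means[[control]]) / se
  pRaw <- 2 * stats::pt(-abs(tObs), dfW)

  pAdj <- .withSeed(seed, {
    m <- length(others)
    z0 <- stats::rnorm(mcDraws)
    S <- sqrt(stats::rchisq(mcDraws, dfW) / dfW)
    maxT <- rep(0, mcDraws)
    for (j in seq_len(m)) {
      dj <- (stats::rnorm(mcDraws) / sqrt(ns[[others[j]]]) -
               z0 / sqrt(ns[[control]])) /
        sqrt(1 / ns[[others[j]]] + 1 / ns[[control]])
      maxT <- pmax(maxT, abs(dj / S))
    }
    vapply(abs(tObs), function(t0) mean(maxT >= t0), numeric(1))
  })
  pAdj <- pmax(pAdj, pRaw)   # adjusted never below raw, up to MC noise

  .statResult(paste(others, "vs", control), unname(tObs),
              as.character(dfW), unname(pRaw), unname(pAdj),
              method = sprintf("Dunnett (Monte Carlo, %d draws)", mcDraws))
}

#' Two-sided F test of variances
#'
#' \code{F = s_a^2 / s_b^2} on (n_a - 1, n_b - 1) degrees of freedom with
#' two-sided p-value \code{2 * min(P(F <= f), P(F >= f))}; used to compare
#' the spread of fibre-length distributions between genotypes.
#'
#' @param a,b numeric samples, each of length \code{>= 2}.
#' @return one-row result data.frame.
#' @export
varianceFTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    nmStop("nm_invalid_input", "each sample needs at least 2 values")
  if (stats::var(b) == 0)
    nmStop("nm_invalid_input", "zero variance in denominator sample")
  ft <- stats::var.test(a, b)
  .statResult("a vs b", unname(ft$statistic),
              paste(ft$parameter, collapse = ","), ft$p.value,
              method = "two-sided F test of variances")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' The FDR control applied across the chi-square post hoc family; the
#' step-up adjustment is monotone and never below the raw p-value.
#'
#' @param p raw p-values.
#' @return adjusted p-values.
#' @export
fdrAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Chi-square post hoc comparisons with FDR control
#'
#' For each non-control group, a 2x2 Pearson chi-square test (no continuity
#' correction) of its defective/non-defective counts against the control's,
#' with Benjamini-Hochberg adjustment across all comparisons -- the
#' categorical-score battery for defect tables.
#'
#' @param counts data.frame with columns \code{group}, \code{defective},
#'   \code{notDefective} (counts \code{>= 0}, row totals \code{> 0}).
#' @param control control group label.
#' @return result data.frame, one row per non-control group.
#' @export
chiSquarePosthocFdr <- function(counts, control) {
  need <- c("group", "defective", "notDefective")
  if (!all(need %in% names(counts)))
    nmStop("nm_invalid_input",
           "counts must have columns group, defective, notDefective")
  if (any(counts$defective < 0) || any(counts$notDefective < 0))
    nmStop("nm_invalid_input", "counts must be non-negative")
  if (any(counts$defective + counts$notDefective <= 0))
    nmStop("nm_invalid_input", "every group needs a positive total")
  if (!control %in% counts$group)
    nmStop("nm_invalid_input", sprintf("control group '%s' not found", control))
  ctrl <- counts[counts$group == control, ][1, ]
  others <- counts[counts$group != control, ]
  res <- lapply(seq_len(nrow(others)), function(i) {
    m <- rbind(c(ctrl$defective, ctrl$notDefective),
               c(others$defective[i], others$notDefective[i]))
    exp0 <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(exp0 == 0))
      nmStop("nm_degenerate_table",
             sprintf("expected count of 0 for group '%s'", others$group[i]))
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    .statResult(paste(others$group[i], "vs", control),
                unname(ct$statistic), as.character(unname(ct$parameter)),
                ct$p.value, method = "Pearson chi-square (2x2), BH-adjusted")
  })
  out <- do.call(rbind, res)
  out$p_adj <- fdrAdjust(out$p)
  out
}

#' Gaussian kernel density with variance summary
#'
#' Density estimate of a fibre-length (or other) sample on a stated grid,
#' with Silverman's rule-of-thumb bandwidth unless one is given; the sample
#' variance is returned alongside for pairing with the variance F test.
#'
#' @param values numeric sample, \code{n >= 5}.
#' @param bandwidth optional bandwidth; default \code{stats::bw.nrd0}.
#' @param n grid size (default 512).
#' @return list with \code{x}, \code{y} (the curve), \code{bw},
#'   \code{variance} and \code{pointMass} (TRUE for a zero-variance sample,
#'   in which case no curve is returned).
#' @export
kdeDensity <- function(values, bandwidth = NULL, n = 512) {
  if (length(values) < 5L)
    nmStop("nm_invalid_input", "density estimation needs at least 5 values")
  v <- stats::var(values)
  if (v == 0) {
    warning("zero-variance sample: returning a point mass at the common value")
    return(list(x = values[1], y = Inf, bw = NA_real_, variance = 0,
                pointMass = TRUE))
  }
  bw <- bandwidth %||% stats::bw.nrd0(values)
  d <- stats::density(values, bw = bw, n = n)
  list(x = d$x, y = d$y, bw = d$bw, variance = v, pointMass = FALSE)
}
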