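## Group comparison and reporting: distribution-free median confidence
## intervals, normality-screened two-group and multi-group tests with Dunn
## post hoc comparisons, and a tidy report builder.

#' Distribution-free confidence interval for the median
#'
#' Order-statistic (binomial) interval: the widest symmetric pair of order
#' statistics whose coverage is at least `level`. For samples too small for
#' the binomial construction at the requested level, a seeded percentile
#' bootstrap is used instead.
#'
#' @param values numeric vector, `n >= 3`.
#' @param level confidence level (default 0.95).
#' @param bootSeed seed for the small-sample bootstrap fallback.
#' @return one-row data.frame `median, lower, upper, n, method`.
#' @examples
#' medianCi(1:101)
#' @export
medianCi <- function(values, level = 0.95, bootSeed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L) stop("need at least 3 values for a median CI")
  xs <- sort(values)
  alpha <- 1 - level
  ## largest k with P(X < k) <= alpha/2 for X ~ Binomial(n, 1/2):
  ## CI = [x_(k), x_(n+1-k)] has coverage >= level
  k <- stats::qbinom(alpha / 2, n, 0.5)
  if (stats::pbinom(k - 1, n, 0.5) > alpha / 2) k <- k - 1
  if (k >= 1L) {
    return(data.frame(median = stats::median(values), lower = xs[k],
                      upper = xs[n + 1L - k], n = n, method = "binomial"))
  }
  ## sample too small for the requested coverage: percentile bootstrap
  meds <- withr::with_seed(bootSeed, replicate(2000, stats::median(
    sample(values, n, replace = TRUE))))
  q <- stats::quantile(meds, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  data.frame(median = stats::median(values), lower = q[1L], upper = q[2L],
             n = n, method = "bootstrap")
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the sample-size-corrected z transforms of skewness and kurtosis
#' into the K-squared statistic, referred to a chi-squared distribution with
#' 2 degrees of freedom. Requires `n >= 8` (the kurtosis transform is not
#' defined below that).
#'
#' @param x numeric vector.
#' @return one-row data.frame `k2, p_value, z_skew, z_kurt, n`.
#' @export
dagostinoTest <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  ## skewness transform
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  ## kurtosis transform
  g2 <- mean((x - m)^4) / s2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  zk <- ((1 - 2 / (9 * a)) -
         ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- zs^2 + zk^2
  data.frame(k2 = k2, p_value = stats::pchisq(k2, df = 2,
                                              lower.tail = FALSE),
             z_skew = zs, z_kurt = zk, n = n)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics from the pooled-sample rank sums with the usual tie
#' correction. By default (when `control` is given) only many-to-one
#' comparisons against the control group are made, with the multiplicity
#' correction applied over that family; otherwise all pairs are compared.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param control optional control group label for many-to-one comparisons.
#' @param pAdjust multiplicity correction passed to [stats::p.adjust()]
#'   (default `"bonferroni"`, the classical Dunn correction).
#' @return data.frame `group1, group2, z, p_value, p_adjusted`.
#' @export
dunnTest <- function(values, groups, control = NULL,
                     pAdjust = "bonferroni") {
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  g <- unique(groups)
  if (length(g) < 2L) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)           # midranks for ties
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- if (!is.null(control)) {
    if (!control %in% g) stop("control group not present")
    cbind(control, setdiff(g, control))
  } else t(utils::combn(g, 2L))
  z <- p <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs[i, 1L]; g2 <- pairs[i, 2L]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z[i] <- (rbar[[g1]] - rbar[[g2]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L], z = z,
             p_value = p, p_adjusted = stats::p.adjust(p, method = pAdjust))
}

#' Compare groups with normality-screened tests
#'
#' Each group is screened for Gaussianity with the D'Agostino-Pearson test
#' (groups with `n < 8` force the nonparametric branch, as the screen is
#' undefined there). Two groups: Student's t-test when all groups pass,
#' Mann-Whitney otherwise. Three or more: one-way ANOVA, or Kruskal-Wallis
#' with Dunn's post hoc comparisons. The chosen test is recorded in the
#' result.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @param control optional control label for many-to-one Dunn comparisons.
#' @param normalityAlpha screening level (default 0.05).
#' @return list of class `comparisonResult`: `test`, `statistic`, `p_value`,
#'   `posthoc` (data.frame or NULL), `group_summaries` (per-group median and
#'   95% CI from [medianCi()]), `normal` (named logical).
#' @export
compareGroups <- function(values, groups, control = NULL,
                          normalityAlpha = 0.05) {
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  g <- unique(groups)
  if (length(g) < 2L) stop("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 3L))
    stop("group(s) below minimum n = 3: ",
         paste(names(ns)[ns < 3L], collapse = ", "))
  normal <- vapply(g, function(gg) {
    v <- values[groups == gg]
    if (length(v) < 8L) return(FALSE)
    dagostinoTest(v)$p_value > normalityAlpha
  }, logical(1))
  names(normal) <- g
  gaussian <- all(normal)
  posthoc <- NULL
  if (length(g) == 2L) {
    v1 <- values[groups == g[1L]]; v2 <- values[groups == g[2L]]
    if (gaussian) {
      ht <- stats::t.test(v1, v2)
      test <- "Student t (two-tailed, unpaired)"
    } else {
      ht <- stats::wilcox.test(v1, v2, exact = FALSE, correct = TRUE)
      test <- "Mann-Whitney"
    }
  } else {
    if (gaussian) {
      fit <- stats::aov(values ~ factor(groups))
      sm <- summary(fit)[[1L]]
      ht <- list(statistic = sm$`F value`[1L], p.value = sm$`Pr(>F)`[1L])
      test <- "one-way ANOVA"
    } else {
      ht <- stats::kruskal.test(values, factor(groups))
      test <- "Kruskal-Wallis"
      posthoc <- dunnTest(values, groups, control = control)
    }
  }
  summaries <- do.call(rbind, lapply(g, function(gg) {
    ci <- medianCi(values[groups == gg])
    cbind(data.frame(group = gg), ci)
  }))
  structure(list(test = test, statistic = unname(ht$statistic[[1L]]),
                 p_value = ht$p.value, posthoc = posthoc,
                 group_summaries = summaries, normal = normal),
            class = "comparisonResult")
}

#' @export
print.comparisonResult <- function(x, ...) {
  cat(x$test, ": statistic =", signif(x$statistic, 4),
      ", p =", signif(x$p_value, 4), "\n")
  print(x$group_summaries, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("post hoc (Dunn):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Two-factor ANOVA on per-culture percentages
#'
#' Routine two-way ANOVA (factor crossing, type I sums of squares) used for
#' percentage outcomes recorded per culture under two crossed factors.
#'
#' @param values numeric outcomes.
#' @param factorA,factorB factors of the same length.
#' @return ANOVA table as a data.frame.
#' @export
compareTwoFactor <- function(values, factorA, factorB) {
  fit <- stats::aov(values ~ factor(factorA) * factor(factorB))
  out <- as.data.frame(summary(fit)[[1L]])
  out$term <- trimws(rownames(out))
  rownames(out) <- NULL
  out
}

#' Build a per-metric comparison report
#'
#' Runs [compareGroups()] for every metric column of a grouped table and
#' collects per-group descriptives. With a single group only descriptives
#' are produced. The report is invariant to row order.
#'
#' @param data data.frame containing `groupCol` and the metric columns.
#' @param metrics character vector of metric column names.
#' @param groupCol name of the grouping column (default `"group"`).
#' @param control optional control group label.
#' @return list of class `reportBundle` with one entry per metric:
#'   `comparison` (a `comparisonResult` or NULL for a single group) and
#'   `descriptives` (per-group median CI table).
#' @export
buildReport <- function(data, metrics, groupCol = "group", control = NULL) {
  stopifnot(groupCol %in% names(data))
  missing <- setdiff(metrics, names(data))
  if (length(missing))
    stop("unknown metric column(s): ", paste(missing, collapse = ", "))
  groups <- as.character(data[[groupCol]])
  gl <- sort(unique(groups))
  out <- lapply(metrics, function(mc) {
    v <- data[[mc]]
    desc <- do.call(rbind, lapply(gl, function(gg) {
      vv <- v[groups == gg & !is.na(v)]
      cbind(data.frame(group = gg, metric = mc), medianCi(vv))
    }))
    comp <- if (length(gl) >= 2L)
      compareGroups(v[!is.na(v)], groups[!is.na(v)], control = control)
    else NULL
    list(comparison = comp, descriptives = desc)
  })
  names(out) <- metrics
  structure(out, class = "reportBundle")
}

#' @export
print.reportBundle <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    if (!is.null(x[[nm]]$comparison)) print(x[[nm]]$comparison)
    else print(x[[nm]]$descriptives, row.names = FALSE)
  }
  invisible(x)
}
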