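# Descriptive statistics and RSQI/QBR agreement analysis: normality
# (Shapiro-Wilk), variance homogeneity (Levene), Pearson correlation.

#' Descriptive statistics of a score vector
#'
#' @param values numeric vector, `n >= 1`.
#' @return one-row tibble: `n`, `mean`, `sd` (sample, `n - 1` denominator;
#'   reported as 0 with `single_value = TRUE` when `n = 1`), `min`, `max`.
#' @export
descriptives <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) abort("empty input")
  n <- length(values)
  tibble(n = n, mean = mean(values),
         sd = if (n > 1) sd(values) else 0,
         min = min(values), max = max(values),
         single_value = n == 1)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' `n - 2` degrees of freedom. Significance is flagged at the two-star
#' `alpha = 0.01` convention.
#'
#' @param x,y numeric vectors of equal length `>= 3`, neither constant.
#' @return one-row tibble: `r`, `p_value`, `n`, `significant_01`.
#' @export
pearson <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for constant input")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         significant_01 = ct$p.value < 0.01)
}

#' Shapiro-Wilk normality check
#' @param values numeric vector, `n >= 3`.
#' @return one-row tibble: `statistic`, `p_value`, `normal` (`p > 0.05`).
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) abort("Shapiro-Wilk needs at least 3 observations")
  sw <- shapiro.test(values)
  tibble(statistic = unname(sw$statistic), p_value = sw$p.value,
         normal = sw$p.value > 0.05)
}

#' Levene variance-homogeneity check
#'
#' Levene's test (deviation-from-group-mean form) across two or more groups.
#'
#' @param values numeric vector.
#' @param group grouping vector of the same length, `>= 2` groups.
#' @return one-row tibble: `statistic`, `p_value`, `homogeneous` (`p > 0.05`).
#' @export
variance_check <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) abort("Levene needs at least 2 groups")
  lt <- car::leveneTest(values, group, center = mean)
  tibble(statistic = lt[["F value"]][1], p_value = lt[["Pr(>F)"]][1],
         homogeneous = lt[["Pr(>F)"]][1] > 0.05)
}

#' RSQI vs QBR agreement report
#'
#' Descriptives for both indices, the parametric gate (Shapiro-Wilk
#' normality on both indices and Levene homogeneity between them, all at
#' `p > 0.05`), Pearson's r with its two-sided p-value, and the category
#' tallies. The checks gate reporting only; they never alter scores.
#'
#' @param scores a `ripaq_scores` tibble with `rsqi` and `qbr_total`.
#' @return list of class `ripaq_agreement`: `descriptives` (tibble, one row
#'   per index), `normality`, `variance`, `parametric`, `correlation`,
#'   `categories`.
#' @export
index_agreement <- function(scores) {
  ok <- stats::complete.cases(scores$rsqi, scores$qbr_total)
  r <- scores$rsqi[ok]; q <- scores$qbr_total[ok]
  if (length(r) < 3) abort("need at least 3 stations with both indices")
  desc <- dplyr::bind_rows(
    mutate(descriptives(r), index = "rsqi", .before = 1),
    mutate(descriptives(q), index = "qbr", .before = 1)
  )
  norm <- dplyr::bind_rows(
    mutate(normality_check(r), index = "rsqi", .before = 1),
    mutate(normality_check(q), index = "qbr", .before = 1)
  )
  vc <- variance_check(c(r, q), rep(c("rsqi", "qbr"), c(length(r), length(q))))
  cats <- dplyr::count(scores[ok, ], .data$rsqi_category, .data$qbr_category)
  structure(
    list(descriptives = desc, normality = norm, variance = vc,
         parametric = all(norm$normal) && vc$homogeneous,
         correlation = pearson(r, q),
         categories = cats),
    class = "ripaq_agreement"
  )
}

#' @export
print.ripaq_agreement <- function(x, ...) {
  d <- x$descriptives
  for (i in seq_len(nrow(d))) {
    cat(sprintf("%-5s mean %.2f +/- %.2f (range %.0f-%.0f, n = %d)\n",
                toupper(d$index[i]), d$mean[i], d$sd[i], d$min[i], d$max[i], d$n[i]))
  }
  cat(sprintf("parametric assumptions %s (Shapiro-Wilk + Levene, p > 0.05)\n",
              if (x$parametric) "met" else "not met"))
  co <- x$correlation
  cat(sprintf("Pearson r = %.3f%s (p = %.3g, n = %d)\n", co$r,
              if (co$significant_01) "**" else "", co$p_value, co$n))
  invisible(x)
}

#' One-row summary of an agreement report
#' @param x a `ripaq_agreement`.
#' @param ... unused.
#' @return tibble: index means/sds, `r`, `p_value`, `parametric`, `n`.
#' @export
glance.ripaq_agreement <- function(x, ...) {
  d <- x$descriptives
  tibble(rsqi_mean = d$mean[d$index == "rsqi"],
         rsqi_sd = d$sd[d$index == "rsqi"],
         qbr_mean = d$mean[d$index == "qbr"],
         qbr_sd = d$sd[d$index == "qbr"],
         r = x$correlation$r, p_value = x$correlation$p_value,
         parametric = x$parametric, n = x$correlation$n)
}
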