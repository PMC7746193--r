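# Domain-comparison statistics. Conventions: Pearson statistics without
# continuity correction, two-sided asymptotic p-values throughout, no
# multiple-testing adjustment (raw p-values are reported).

#' Homogeneity chi-squared test on an r x c count table
#'
#' Pearson statistic without continuity correction; all-zero columns are
#' dropped before computing, df = (r-1)(c-1) on the reduced table.
#'
#' @param tab numeric matrix of nonnegative counts (rows = groups,
#'   columns = categories).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_homogeneity <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate table after dropping empty margins", call. = FALSE)
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df,
                                                    lower.tail = FALSE))
}

#' Goodness-of-fit chi-squared on per-domain counts
#'
#' `sum((O-E)^2/E)` with df = k-1. The expectation model is one of:
#' * `"equal"` — equal expected counts in every domain (this is the model
#'   that reproduces published per-domain variant-count tests run without
#'   an opportunity correction);
#' * `"length"` — expected counts proportional to supplied domain lengths;
#' * `"possible"` — proportional to supplied possible-SNV opportunities.
#'
#' @param observed numeric vector of observed counts (k >= 2).
#' @param model expectation model.
#' @param weights domain lengths (for `"length"`) or possible-SNV counts
#'   (for `"possible"`); ignored for `"equal"`.
#' @return list with `statistic`, `df`, `p`, `expected`, `model`.
#' @examples
#' chi2_goodness_of_fit(c(193, 132))$statistic  # 11.449...
#' @export
chi2_goodness_of_fit <- function(observed,
                                 model = c("equal", "length", "possible"),
                                 weights = NULL) {
  model <- match.arg(model)
  k <- length(observed)
  if (k < 2L) stop("need >= 2 domains", call. = FALSE)
  w <- switch(model,
              equal = rep(1, k),
              length = ,
              possible = {
                if (is.null(weights) || length(weights) != k)
                  stop("model '", model, "' needs one weight per domain",
                       call. = FALSE)
                as.numeric(weights)
              })
  expected <- sum(observed) * w / sum(w)
  if (any(expected <= 0)) stop("zero expected count", call. = FALSE)
  stat <- sum((observed - expected)^2 / expected)
  df <- k - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected, model = model)
}

# Asymptotic two-sided Kolmogorov p-value: Q(lambda) via the alternating
# series, truncated when terms vanish.
kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the exact supremum distance between the two empirical CDFs; the
#' p-value is the asymptotic two-sided Kolmogorov approximation (ties make
#' it conservative).
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("empty sample", call. = FALSE)
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) sum(x <= t), numeric(1)) / n1
  Fy <- vapply(pts, function(t) sum(y <= t), numeric(1)) / n2
  D <- max(abs(Fx - Fy))
  neff <- n1 * n2 / (n1 + n2)
  list(D = D, p = kolmogorov_q(sqrt(neff) * D))
}

#' Mann-Whitney U test (first-sample-greater convention)
#'
#' `W = #\{(i,j): x_i > y_j\} + 0.5 * #ties`, computed from midranks; the
#' p-value is the two-sided normal approximation with tie correction and
#' no continuity correction. Degenerate variance (all values tied) yields
#' `p = NA`.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `W` and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("empty sample", call. = FALSE)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(W = W, p = NA_real_))
  z <- (W - n1 * n2 / 2) / sqrt(sigma2)
  list(W = W, p = 2 * stats::pnorm(-abs(z)))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return list with `F`, `p`, `tukey` (data.frame: comparison, diff,
#'   p_adj).
#' @export
oneway_anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2L))
    stop("each group needs >= 2 values", call. = FALSE)
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups))))
  if (all(vapply(groups, stats::var, numeric(1)) == 0) &&
      stats::var(df$value) == 0)
    stop("zero variance everywhere; F undefined", call. = FALSE)
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          row.names = NULL))
}

#' Wald's-domain verdict
#'
#' A Wald's domain — the domain whose damage is mostly invisible because
#' it is not tolerated — is expected to show (1) a lower observed/expected
#' missense ratio, (2) a higher mean conservation grade, (3) more
#' disease-propensity hotspot positions and (4) a lower mean dN/dS. Each
#' criterion awards one point (0.5 each on an exact tie); the domain
#' winning at least 3 of 4 is the Wald's domain, otherwise the verdict is
#' "inconclusive".
#'
#' @param summary_a,summary_b per-domain lists with elements `oe_ratio`,
#'   `mean_grade`, `hotspot_positions`, `mean_dnds`.
#' @param name_a,name_b domain names.
#' @return list with `walds_domain` (name or "inconclusive"), `score_a`,
#'   `score_b`, and `criteria` (data.frame of the four comparisons).
#' @export
walds_domain_verdict <- function(summary_a, summary_b, name_a, name_b) {
  # each row: criterion label, value_a, value_b, TRUE if lower value wins
  crits <- data.frame(
    criterion = c("lower_oe_ratio", "higher_mean_grade",
                  "more_hotspot_positions", "lower_mean_dnds"),
    value_a = c(summary_a$oe_ratio, summary_a$mean_grade,
                summary_a$hotspot_positions, summary_a$mean_dnds),
    value_b = c(summary_b$oe_ratio, summary_b$mean_grade,
                summary_b$hotspot_positions, summary_b$mean_dnds),
    lower_wins = c(TRUE, FALSE, FALSE, TRUE))
  pt_a <- ifelse(is.na(crits$value_a) | is.na(crits$value_b), 0.5,
          ifelse(crits$value_a == crits$value_b, 0.5,
          ifelse((crits$value_a < crits$value_b) == crits$lower_wins, 1, 0)))
  crits$points_a <- pt_a
  crits$points_b <- 1 - pt_a
  score_a <- sum(crits$points_a)
  score_b <- sum(crits$points_b)
  winner <- if (score_a >= 3) name_a else if (score_b >= 3) name_b
            else "inconclusive"
  list(walds_domain = winner, score_a = score_a, score_b = score_b,
       domain_a = name_a, domain_b = name_b, criteria = crits)
}
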