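# Bisulphite-pyrosequencing cumulative methylation scoring, beta/M-value
# conversion, region probe-count filtering, and group comparison.

#' Cumulative methylation score per sample
#'
#' Per sample, averages replicate percent-methylation values at each CpG site
#' and sums the per-site means across sites: an unmethylated site contributes
#' 0 and a fully methylated site 100, so a sample assayed at `n` sites has a
#' maximum cumulative score of `100 * n` (2300 for 23 sites, 1200 for 12).
#'
#' @param pyro Tibble `sample_id`, `group`, `chrom`, `pos`, `replicate`,
#'   `pct_meth` with `pct_meth` in \[0, 100\].
#' @return Tibble `sample_id`, `group`, `n_sites`, `cumulative`, `max_score`,
#'   `overall_pct` (cumulative / n_sites, i.e. the mean per-site percent).
#' @export
cumulative_methylation <- function(pyro) {
  assert_cols(pyro, c("sample_id", "group", "chrom", "pos", "pct_meth"), "pyro")
  if (nrow(pyro) == 0) abort_data("the pyrosequencing table is empty.")
  if (any(is.na(pyro$pct_meth)) || any(pyro$pct_meth < 0 | pyro$pct_meth > 100)) {
    abort_data("percent methylation must lie in [0, 100] with no missing replicates.")
  }
  site_means <- pyro %>%
    group_by(.data$sample_id, .data$group, .data$chrom, .data$pos) %>%
    summarise(site_mean = mean(.data$pct_meth), .groups = "drop")
  site_means %>%
    group_by(.data$sample_id, .data$group) %>%
    summarise(
      n_sites = dplyr::n(),
      cumulative = sum(.data$site_mean),
      .groups = "drop"
    ) %>%
    mutate(
      max_score = 100 * .data$n_sites,
      overall_pct = .data$cumulative / .data$n_sites
    )
}

#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))`, the logit-log2 transform of an array
#' methylation fraction; beta is clipped to `[eps, 1 - eps]` first so M stays
#' finite at fully (un)methylated probes. Strictly increasing: beta 0.5 maps
#' to 0, 0.8 to 2, 0.2 to -2.
#'
#' @param beta Numeric vector of methylation fractions in \[0, 1\].
#' @param eps Clipping bound; default 1e-6.
#' @return Numeric vector of M-values.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(is.na(beta)) || any(beta < 0 | beta > 1)) {
    abort_data("beta values must lie in [0, 1].")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Inverse of [beta_to_m()]
#'
#' @param m Numeric vector of M-values.
#' @return Beta values, `2^m / (1 + 2^m)`.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Filter genomic regions by array probe support
#'
#' A region is retained only if at least `min_probes` distinct probes fall
#' inside it -- the minimum support for a meaningful region-level methylation
#' call (a four-probe region is dropped; seven probes suffice). Regions use
#' 0-based half-open coordinates (BED convention); probe positions are
#' 1-based as in array manifests, so probe `pos` is in `[start, end)` after
#' conversion. Duplicated probe records count once per unique `probe_id`.
#'
#' @param probes Tibble `probe_id`, `chrom`, `pos` (1-based).
#' @param regions Tibble `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `name`; `min_probes` may also be a per-region column.
#' @param min_probes Minimum probe count; default 5.
#' @return `regions` with `n_probes` and logical `retained` added. The probe
#'   -> region assignment is attached as attribute `"region_probes"`.
#' @export
region_probe_filter <- function(probes, regions, min_probes = 5L) {
  assert_cols(probes, c("probe_id", "chrom", "pos"), "probes")
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  if (any(regions$start >= regions$end)) abort_data("regions must satisfy start < end.")
  probes <- distinct(probes, .data$probe_id, .keep_all = TRUE)
  if (!"name" %in% names(regions)) {
    regions <- mutate(regions, name = sprintf("%s:%d-%d", .data$chrom,
                                              .data$start, .data$end))
  }
  if (!"min_probes" %in% names(regions)) {
    regions <- mutate(regions, min_probes = as.integer(min_probes))
  }
  assignment <- purrr::pmap_dfr(regions, function(chrom, start, end, name, ...) {
    inside <- probes$chrom == chrom & (probes$pos - 1L) >= start & (probes$pos - 1L) < end
    tibble(region = name, probe_id = probes$probe_id[inside])
  })
  counts <- assignment %>% count(.data$region, name = "n_probes")
  out <- regions %>%
    left_join(counts, by = c(name = "region")) %>%
    mutate(
      n_probes = dplyr::coalesce(.data$n_probes, 0L),
      retained = .data$n_probes >= .data$min_probes
    )
  attr(out, "region_probes") <- assignment
  out
}

#' Two-group comparison of cumulative methylation scores
#'
#' Unpaired two-sided t test between the two groups (Student's equal-variance
#' test by default; set `var_equal = FALSE` for Welch), with per-group mean,
#' SD and SEM. Degenerate inputs are handled explicitly: when both groups
#' have zero variance, identical group means give `t = 0, p = 1` and
#' different means give a flagged result with `p = NA`.
#'
#' @param scores Tibble with one row per sample, e.g. from
#'   [cumulative_methylation()].
#' @param value,group Column names (strings) of the score and group label;
#'   defaults `"cumulative"` and `"group"`.
#' @param var_equal Use the pooled-variance Student's t test; default `TRUE`.
#' @return A `group_comparison` object with [tidy()] (per-group summaries)
#'   and [glance()] (test statistic, df, p) methods.
#' @export
compare_groups <- function(scores, value = "cumulative", group = "group",
                           var_equal = TRUE) {
  assert_cols(scores, c(value, group), "scores")
  v <- scores[[value]]
  g <- as.character(scores[[group]])
  levels <- unique(g)
  if (length(levels) != 2) abort_data("exactly two groups are required.")
  split_v <- split(v, factor(g, levels = levels))
  if (any(lengths(split_v) < 2)) abort_data("each group needs at least 2 samples.")
  summary <- tibble(
    group = levels,
    n = unname(lengths(split_v)),
    mean = unname(vapply(split_v, mean, numeric(1))),
    sd = unname(vapply(split_v, stats::sd, numeric(1))),
    sem = unname(vapply(split_v, function(x) stats::sd(x) / sqrt(length(x)),
                        numeric(1)))
  )
  degenerate <- all(summary$sd == 0)
  if (degenerate) {
    same <- summary$mean[1] == summary$mean[2]
    res <- list(statistic = if (same) 0 else NA_real_,
                df = sum(summary$n) - 2,
                p_value = if (same) 1 else NA_real_,
                method = if (var_equal) "Student's t-test" else "Welch's t-test")
  } else {
    tt <- t.test(split_v[[1]], split_v[[2]], var.equal = var_equal)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, method = tt$method)
  }
  structure(
    c(res, list(summary = summary, degenerate = degenerate,
                value = value, groups = levels)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s on `%s`: t = %s, df = %.1f, p = %s%s\n",
              x$method, x$value,
              format(x$statistic, digits = 4), x$df,
              format(x$p_value, digits = 4),
              if (x$degenerate) " [degenerate variance]" else ""))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    method = x$method, degenerate = x$degenerate,
    mean_diff = x$summary$mean[1] - x$summary$mean[2]
  )
}

#' Ordinary least-squares co-expression fit
#'
#' Fits `y ~ x` by OLS, for miRNA/target co-expression style scatter plots:
#' reports slope, intercept, R-squared and the slope's two-sided p-value.
#'
#' @param data Tibble holding the two variables.
#' @param x,y Column names (strings) of predictor and response.
#' @return A `coexpression_fit` object with [tidy()] (coefficient table) and
#'   [glance()] (R-squared, p, n) methods; the underlying `lm` fit is kept in
#'   `$fit`.
#' @export
coexpression_fit <- function(data, x, y) {
  assert_cols(data, c(x, y), "data")
  if (nrow(data) < 3) abort_data("at least 3 points are required for regression.")
  fit <- lm(stats::reformulate(x, y), data = data)
  sm <- summary(fit)
  coefs <- stats::coef(sm)
  structure(
    list(
      fit = fit,
      slope = coefs[2, "Estimate"],
      intercept = coefs[1, "Estimate"],
      r_squared = sm$r.squared,
      p_value = coefs[2, "Pr(>|t|)"],
      n = nrow(data), x = x, y = y
    ),
    class = "coexpression_fit"
  )
}

#' @export
print.coexpression_fit <- function(x, ...) {
  cat(sprintf("<coexpression_fit> %s ~ %s: slope %.4g, R^2 %.4f, p %.4g (n = %d)\n",
              x$y, x$x, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.coexpression_fit <- function(x, ...) {
  coefs <- stats::coef(summary(x$fit))
  tibble(
    term = rownames(coefs),
    estimate = unname(coefs[, "Estimate"]),
    std_error = unname(coefs[, "Std. Error"]),
    statistic = unname(coefs[, "t value"]),
    p_value = unname(coefs[, "Pr(>|t|)"])
  )
}

#' @export
glance.coexpression_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         p_value = x$p_value, n = x$n)
}
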