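pyro_fixture <- function(values_by_sample, n_sites, group = NULL,
                         replicates = 1L) {
  # values_by_sample: named list of per-site means (recycled over sites)
  purrr::imap_dfr(values_by_sample, function(v, sid) {
    tidyr::expand_grid(site = seq_len(n_sites), replicate = seq_len(replicates)) |>
      dplyr::mutate(
        sample_id = sid,
        group = if (is.null(group)) "malignant" else group[[sid]],
        chrom = "chr11",
        pos = 100L + 10L * site,
        pct_meth = rep_len(v, dplyr::n())
      )
  })
}

test_that("cumulative methylation sums per-site replicate means", {
  # fully methylated panels reach the panel maxima
  full23 <- cumulative_methylation(pyro_fixture(list(m1 = 100), 23))
  expect_equal(full23$cumulative, 2300)
  expect_equal(full23$max_score, 2300)
  full12 <- cumulative_methylation(pyro_fixture(list(m1 = 100), 12))
  expect_equal(full12$cumulative, 1200)
  full35 <- cumulative_methylation(pyro_fixture(list(m1 = 100), 35))
  expect_equal(full35$max_score, 3500)

  zero <- cumulative_methylation(pyro_fixture(list(m1 = 0), 23))
  expect_equal(zero$cumulative, 0)
  expect_equal(zero$overall_pct, 0)

  half35 <- cumulative_methylation(pyro_fixture(list(m1 = 50), 35))
  expect_equal(half35$cumulative, 1750)
  expect_equal(half35$overall_pct, 50)

  # replicates are averaged per site before summing
  two_reps <- pyro_fixture(list(m1 = c(40, 60)), 10, replicates = 2)
  # per site the two replicate values alternate 40/60 -> mean 50
  two_reps$pct_meth <- rep(c(40, 60), 10)
  expect_equal(cumulative_methylation(two_reps)$cumulative, 500)

  # permutation over sites changes nothing
  py <- pyro_fixture(list(m1 = c(10, 90, 30)), 9)
  shuffled <- py[sample(nrow(py)), ]
  expect_equal(cumulative_methylation(shuffled), cumulative_methylation(py))

  bad <- pyro_fixture(list(m1 = 150), 3)
  expect_error(cumulative_methylation(bad), class = "seedscape_data_error")
})

test_that("beta/M conversion matches the logit-log2 closed form", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  # antisymmetry and monotonicity
  b <- seq(0.05, 0.95, by = 0.05)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b))
  expect_false(is.unsorted(beta_to_m(b)))
  # inverse identity on a grid
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)
  # boundary betas stay finite through clipping
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
  expect_error(beta_to_m(1.2), class = "seedscape_data_error")
  expect_error(beta_to_m(-0.1), class = "seedscape_data_error")
})

test_that("region filter needs five probes, half-open, unique probe ids", {
  probes <- tibble::tibble(
    probe_id = sprintf("cg%02d", 1:11),
    chrom = c(rep("chr21", 4), rep("chr11", 7)),
    pos = c(101:104, 201:207)
  )
  regions <- tibble::tibble(chrom = c("chr21", "chr11"),
                            start = c(100L, 200L), end = c(300L, 300L),
                            name = c("roi21", "roi11"))
  out <- region_probe_filter(probes, regions)
  expect_equal(out$n_probes, c(4L, 7L))
  expect_equal(out$retained, c(FALSE, TRUE)) # 4 probes dropped, 7 kept

  # exactly five probes is enough (>= rule)
  five <- region_probe_filter(probes[probes$chrom == "chr11", ][1:5, ], regions)
  expect_true(five$retained[five$name == "roi11"])

  # duplicated probe records count once; probe order is irrelevant
  dup <- dplyr::bind_rows(probes, probes[5:8, ])
  out_dup <- region_probe_filter(dup[sample(nrow(dup)), ], regions)
  expect_equal(out_dup$n_probes, out$n_probes)

  # half-open boundaries: 1-based probe at pos = start+1 is in, pos = end is out
  edge <- tibble::tibble(probe_id = c("lo", "hi"), chrom = "chr1",
                         pos = c(101L, 200L))
  r <- tibble::tibble(chrom = "chr1", start = 100L, end = 199L)
  got <- region_probe_filter(edge, r, min_probes = 1L)
  expect_equal(got$n_probes, 1L)
  expect_equal(attr(got, "region_probes")$probe_id, "lo")
})

test_that("group comparison handles real, identical and degenerate groups", {
  scores <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    group = rep(c("malignant", "control"), each = 4),
    cumulative = c(1800, 1900, 2000, 1850, 400, 500, 450, 420)
  )
  cmp <- compare_groups(scores)
  tt <- t.test(scores$cumulative[1:4], scores$cumulative[5:8], var.equal = TRUE)
  expect_equal(cmp$statistic, unname(tt$statistic))
  expect_equal(cmp$p_value, tt$p.value)
  expect_equal(glance(cmp)$mean_diff, mean(scores$cumulative[1:4]) -
                 mean(scores$cumulative[5:8]))
  expect_equal(nrow(tidy(cmp)), 2L)

  welch <- compare_groups(scores, var_equal = FALSE)
  expect_equal(welch$p_value,
               t.test(scores$cumulative[1:4], scores$cumulative[5:8])$p.value)

  # identical groups: t = 0, p = 1
  same <- scores
  same$cumulative <- rep(c(100, 100), each = 4)
  cmp0 <- compare_groups(same)
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)

  # zero variance but different means: flagged, p undefined
  degen <- scores
  degen$cumulative <- rep(c(100, 50), each = 4)
  cmpd <- compare_groups(degen)
  expect_true(cmpd$degenerate)
  expect_true(is.na(cmpd$p_value))

  expect_error(compare_groups(dplyr::mutate(scores, group = "one")),
               class = "seedscape_data_error")
})

test_that("the default two-group design is decisively powered", {
  # means 70 vs 20 per site, SD 5, n = 5 vs 5: reject at alpha = 1e-4
  reject <- vapply(1:200, function(seed) {
    cfg <- synth_config(seed = seed)
    scores <- cumulative_methylation(simulate_methylation(cfg))
    compare_groups(scores)$p_value < 1e-4
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("co-expression fit reports slope, R-squared and p", {
  df <- tibble::tibble(x = 1:10, y = 3 - 2 * (1:10))
  fit <- suppressWarnings(coexpression_fit(df, "x", "y")) # perfect fit
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, -2)
  expect_equal(fit$intercept, 3)

  withr::with_seed(2, df2 <- tibble::tibble(x = rnorm(30), y = rnorm(30)))
  fit2 <- coexpression_fit(df2, "x", "y")
  sm <- summary(lm(y ~ x, df2))
  expect_equal(fit2$r_squared, sm$r.squared)
  expect_equal(fit2$p_value, coef(sm)[2, 4])
  expect_equal(glance(fit2)$n, 30)
  expect_equal(tidy(fit2)$estimate[2], fit2$slope)

  expect_error(coexpression_fit(df[1:2, ], "x", "y"),
               class = "seedscape_data_error")
})
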