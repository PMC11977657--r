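ranked_from_ids <- function(ids) {
  tibble::tibble(rank = seq_along(ids), gene_id = ids, log2fc = seq_along(ids))
}

index_from_flags <- function(ids, carrier, word = "ACGGGT") {
  tibble::tibble(gene_id = ids, word = word,
                 count = as.integer(carrier), present = carrier)
}

test_that("landscape tails equal exhaustive enumeration on small universes", {
  # N = 10, K = 4 carriers, leading 5 genes hold x = 4 of them
  ids <- sprintf("g%02d", 1:10)
  carrier <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6))
  ls <- hypergeometric_landscape(ranked_from_ids(ids),
                                 index_from_flags(ids, carrier),
                                 bin_width = 5)
  want <- oracle_hyper_tails(carrier, n = 5, x = 4)
  expect_equal(ls$enrich_p[1], want[["enrich"]], tolerance = 1e-12)
  expect_equal(ls$deplete_p[1], want[["deplete"]], tolerance = 1e-12)

  # random universes up to 12 genes, every bin, both tails
  set.seed(77)
  for (rep in 1:15) {
    N <- sample(4:12, 1)
    B <- sample(1:3, 1)
    if (B > N) next
    carrier <- runif(N) < runif(1)
    ids <- sprintf("r%02d", seq_len(N))
    perm <- sample(N) # carriers scattered along the ranking
    ls <- hypergeometric_landscape(ranked_from_ids(ids[perm]),
                                   index_from_flags(ids, carrier),
                                   bin_width = B)
    for (k in seq_len(nrow(ls))) {
      n <- ls$n_leading[k]
      x <- sum(carrier[perm][seq_len(n)])
      expect_equal(ls$x[k], x)
      want <- oracle_hyper_tails(carrier, n = n, x = x)
      expect_equal(ls$enrich_p[k], want[["enrich"]], tolerance = 1e-9)
      expect_equal(ls$deplete_p[k], want[["deplete"]], tolerance = 1e-9)
    }
  }
})

test_that("signed score conventions: absent words, balanced bins, sign of tails", {
  ids <- sprintf("g%02d", 1:10)
  none <- index_from_flags(ids, rep(FALSE, 10))
  expect_message(
    ls <- hypergeometric_landscape(ranked_from_ids(ids), none, bin_width = 5),
    "no ranked gene"
  )
  expect_equal(ls$signed_score, c(0, 0))

  # leading fraction equal to background fraction -> |score| <= -log10(0.5)
  ids <- sprintf("g%03d", 1:100)
  carrier <- rep(c(TRUE, FALSE), 50) # every other gene carries: 50% everywhere
  ls <- hypergeometric_landscape(ranked_from_ids(ids),
                                 index_from_flags(ids, carrier),
                                 bin_width = 20)
  expect_true(all(abs(ls$signed_score) <= -log10(0.5) + 1e-9))

  # carriers piled at the top -> positive; piled at the bottom -> negative
  top <- c(rep(TRUE, 20), rep(FALSE, 80))
  ls_top <- hypergeometric_landscape(ranked_from_ids(ids),
                                     index_from_flags(ids, top), bin_width = 20)
  expect_gt(ls_top$signed_score[1], 2)
  bottom <- rev(top)
  ls_bot <- hypergeometric_landscape(ranked_from_ids(ids),
                                     index_from_flags(ids, bottom), bin_width = 20)
  expect_lt(ls_bot$signed_score[1], -2)

  expect_error(hypergeometric_landscape(ranked_from_ids(ids[1:5]),
                                        index_from_flags(ids[1:5], top[1:5]),
                                        bin_width = 10),
               class = "seedscape_config_error")
})

test_that("reversing the ranked list swaps enrichment and depletion tails", {
  set.seed(5)
  N <- 12; B <- 2
  ids <- sprintf("g%02d", 1:N)
  carrier <- runif(N) < 0.5
  idx <- index_from_flags(ids, carrier)
  fwd <- hypergeometric_landscape(ranked_from_ids(ids), idx, bin_width = B)
  rev_ls <- hypergeometric_landscape(ranked_from_ids(rev(ids)), idx, bin_width = B)
  K <- sum(carrier)
  for (k in 1:(N / B - 1)) {
    n <- k * B
    comp_bin <- (N - n) / B
    # P(X_n >= x) in the forward list equals P(X_{N-n} <= K - x) reversed
    expect_equal(fwd$enrich_p[k], rev_ls$deplete_p[comp_bin], tolerance = 1e-12)
  }
})

test_that("SSSS is the bin-wise sum over a miRNA's elements", {
  ids <- sprintf("g%03d", 1:60)
  set.seed(8)
  idx <- dplyr::bind_rows(
    index_from_flags(ids, runif(60) < 0.4, word = "ACGGGT"),
    index_from_flags(ids, runif(60) < 0.2, word = "CGGGTT")
  )
  ls <- hypergeometric_landscape(ranked_from_ids(ids), idx, bin_width = 10)

  one <- tibble::tibble(mirna = "m", word = "ACGGGT")
  ss1 <- ssss_integration(ls, one)
  expect_equal(ss1$ssss,
               dplyr::filter(tibble::as_tibble(ls), word == "ACGGGT")$signed_score)

  two <- tibble::tibble(mirna = "m", word = c("ACGGGT", "CGGGTT"))
  ss2 <- ssss_integration(ls, two)
  a <- dplyr::filter(tibble::as_tibble(ls), word == "ACGGGT")$signed_score
  b <- dplyr::filter(tibble::as_tibble(ls), word == "CGGGTT")$signed_score
  expect_equal(ss2$ssss, a + b)

  expect_error(ssss_integration(ls, tibble::tibble(mirna = "m", word = "TTTTTT")),
               class = "seedscape_data_error")
})

test_that("six-element SSSS equals summing six separately computed landscapes", {
  cfg <- synth_config(seed = 31, n_genes = 600, n_responders = 200)
  sim <- simulate_scr_experiment(cfg)
  el <- derive_scr_elements(mirna_table("miR-100-5p", "AACCCGUAGAUCCGAACUUGUG"))
  occ <- scan_occurrences(sim$utrs, el$word)
  ranked <- collapse_and_rank(detection_filter(sim$expr, sim$probe_info),
                              sim$sample_info, sim$annotation)
  ls <- hypergeometric_landscape(ranked, occ, bin_width = 50)
  ss <- ssss_integration(ls, el)
  separate <- lapply(el$word, function(w) {
    hypergeometric_landscape(ranked, occ, words = w, bin_width = 50)$signed_score
  })
  expect_equal(ss$ssss, Reduce(`+`, separate))
})

test_that("CPDV selection matches its definition and reports gene counts", {
  cp <- cpdv_select(c(1, 5, 2, 2, 2, 2, 2, 2), bin_width = 200)
  expect_equal(cp$selected_bin, 2L)
  expect_equal(cp$table$cpdv[2], 3)

  # selected bin 7 at 200-gene bins -> 1400-gene leading edge
  curve <- c(10, 20, 30, 40, 50, 60, 70, 30, 20, 10, 5, 4, 3, 2, 1)
  cp <- cpdv_select(curve, bin_width = 200)
  expect_equal(cp$selected_bin, 7L)
  expect_equal(cp$n_leading, 1400L)

  # brute-force equivalence on random curves
  set.seed(13)
  for (i in 1:200) {
    values <- rnorm(15)
    cp <- cpdv_select(values)
    want <- oracle_cpdv(values)
    expect_equal(cp$table$cpdv, want)
    expect_equal(cp$selected_bin, which.max(want))
  }

  # adding a constant never changes the selection or the CPDV curve
  values <- rnorm(12)
  expect_equal(cpdv_select(values + 11.3)$table$cpdv, cpdv_select(values)$table$cpdv)

  # flat curve -> bin 1; final bin never selected
  flat <- cpdv_select(rep(2, 6))
  expect_equal(flat$selected_bin, 1L)
  expect_equal(flat$table$cpdv[6], -Inf)
  set.seed(14)
  for (i in 1:50) expect_lt(cpdv_select(rnorm(8))$selected_bin, 8L)

  expect_error(cpdv_select(1), class = "seedscape_data_error")
})

test_that("spiked simulations put the SSSS peak at the responder boundary", {
  res <- recovery_experiment()
  expect_gte(mean(abs(res$peak_bin - 7) <= 1), 0.9)
})

test_that("per-element landscape scores are calibrated under the null", {
  # with no expression effect, no single word's signed score should reach the
  # p < 1e-4 scale in the vast majority of runs (the score is an actual
  # hypergeometric -log10 p, unlike the summed SSSS)
  null_runs <- null_calibration_experiment()
  expect_gte(mean(null_runs$max_element < 4), 0.95)
})
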