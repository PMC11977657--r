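# Seeded synthetic-data generators: 3'UTR universes with spiked SCR words,
# ranked expression experiments, two-group pyrosequencing tables, Ct panels.

#' Configuration for the synthetic-data generators
#'
#' One seed drives everything: at construction the root seed is fanned out
#' into independent substreams (design, UTR sequences, expression,
#' methylation, Ct panel) so each generator is reproducible on its own.
#' Defaults emulate the study conditions the pipeline targets: ~4000 genes
#' with annotated 3'UTRs (log-normal lengths, median ~1 kb, 40% GC), 1400
#' responder genes shifted by -1.5 log2 units under 0.5 SD Gaussian noise,
#' the canonical miR-100-5p SCR `ACGGGT` spiked into 60% of responders versus
#' 10% of background genes, triplicate arrays per condition, and a
#' pyrosequencing design of 23 CpG sites with high methylation in the
#' malignant group.
#'
#' @param seed Integer root seed.
#' @param n_genes Universe size.
#' @param utr_log_mean,utr_log_sd Log-normal UTR length parameters (natural
#'   log scale).
#' @param gc_content Fraction G+C of the background sequence.
#' @param spike_word DNA word inserted into carriers.
#' @param n_responders Number of genes given the expression effect.
#' @param carrier_rate_responder,carrier_rate_background Probability that a
#'   responder / background gene has the word spiked into its UTR.
#' @param effect_size True log2 fold change of responders (negative =
#'   downregulated).
#' @param noise_sd SD of the Gaussian noise on observed log2 fold changes.
#' @param n_treated,n_control Array samples per condition.
#' @param n_neg_control_probes Negative-control probes on the simulated
#'   array.
#' @param baseline_log2 Baseline log2 intensity of expressed probes.
#' @param nc_mean,nc_sd Negative-control intensity distribution (linear
#'   scale).
#' @param meth_n_sites CpG sites per pyrosequencing panel.
#' @param meth_mean_case,meth_mean_control Per-site mean percent methylation
#'   by group.
#' @param meth_sd Per-replicate SD of percent methylation.
#' @param meth_n_per_group Samples per group.
#' @param meth_n_replicates Replicates per site and sample (duplicate assays
#'   on three bisulphite preparations by default).
#' @param ct_n_samples Non-reference samples in the Ct panel.
#' @param ct_true_fc True fold changes per sample (recycled), linear scale.
#' @param ct_n_replicates Ct replicates per (sample, assay).
#' @param ct_sd Ct measurement noise SD.
#' @param ct_n_reference_assays Normalizer assays in the panel.
#' @return A `synth_config` list, including the derived substream seeds.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 4000L,
                         utr_log_mean = log(1000),
                         utr_log_sd = 0.5,
                         gc_content = 0.4,
                         spike_word = "ACGGGT",
                         n_responders = 1400L,
                         carrier_rate_responder = 0.6,
                         carrier_rate_background = 0.1,
                         effect_size = -1.5,
                         noise_sd = 0.5,
                         n_treated = 3L,
                         n_control = 3L,
                         n_neg_control_probes = 100L,
                         baseline_log2 = 8,
                         nc_mean = 30,
                         nc_sd = 5,
                         meth_n_sites = 23L,
                         meth_mean_case = 70,
                         meth_mean_control = 20,
                         meth_sd = 5,
                         meth_n_per_group = 5L,
                         meth_n_replicates = 6L,
                         ct_n_samples = 3L,
                         ct_true_fc = c(1, 2, 0.5),
                         ct_n_replicates = 3L,
                         ct_sd = 0.1,
                         ct_n_reference_assays = 3L) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    utr_log_mean = utr_log_mean, utr_log_sd = utr_log_sd,
    gc_content = gc_content, spike_word = toupper(spike_word),
    n_responders = as.integer(n_responders),
    carrier_rate_responder = carrier_rate_responder,
    carrier_rate_background = carrier_rate_background,
    effect_size = effect_size, noise_sd = noise_sd,
    n_treated = as.integer(n_treated), n_control = as.integer(n_control),
    n_neg_control_probes = as.integer(n_neg_control_probes),
    baseline_log2 = baseline_log2, nc_mean = nc_mean, nc_sd = nc_sd,
    meth_n_sites = as.integer(meth_n_sites),
    meth_mean_case = meth_mean_case, meth_mean_control = meth_mean_control,
    meth_sd = meth_sd, meth_n_per_group = as.integer(meth_n_per_group),
    meth_n_replicates = as.integer(meth_n_replicates),
    ct_n_samples = as.integer(ct_n_samples), ct_true_fc = ct_true_fc,
    ct_n_replicates = as.integer(ct_n_replicates), ct_sd = ct_sd,
    ct_n_reference_assays = as.integer(ct_n_reference_assays)
  )
  rates <- c(cfg$carrier_rate_responder, cfg$carrier_rate_background)
  if (any(rates < 0 | rates > 1)) abort_config("carrier rates must lie in [0, 1].")
  if (cfg$n_responders > cfg$n_genes) abort_config("n_responders cannot exceed n_genes.")
  if (grepl("[^ACGT]", cfg$spike_word)) abort_config("spike_word must be uppercase DNA.")
  cfg$substream <- withr::with_seed(
    cfg$seed,
    setNames(sample.int(.Machine$integer.max - 1L, 5L),
             c("design", "utr", "expr", "meth", "ct"))
  )
  structure(cfg, class = "synth_config")
}

gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Designate responder genes
#'
#' Samples the responder set (the genes that will receive the expression
#' effect) uniformly from the universe, using the `design` substream.
#'
#' @param config A [synth_config()].
#' @return Integer vector of responder gene indices.
#' @export
simulate_responders <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$substream[["design"]],
                   sort(sample.int(config$n_genes, config$n_responders)))
}

#' Simulate a 3'UTR universe with spiked SCR words
#'
#' Draws i.i.d. background sequence at the configured GC content with
#' log-normal lengths, then designates carriers -- responder genes with
#' probability `carrier_rate_responder`, all others with
#' `carrier_rate_background` -- and overwrites a uniformly placed window of
#' each carrier's UTR with the spike word (replacement keeps the length
#' distribution exact). Note that the word also arises by chance in
#' non-carrier background sequence at roughly the rate seen for real 6-mers
#' in real 3'UTRs; the truth table records designed carriers only.
#'
#' @param config A [synth_config()].
#' @param responders Integer indices of responder genes (for
#'   carrier-enrichment), `NULL` for none (every gene uses the background
#'   rate).
#' @return List with `utrs` (tibble `gene_id`, `sequence`) and `truth`
#'   (tibble `gene_id`, `length`, `is_responder`, `is_carrier`, `spike_pos`).
#' @export
simulate_utr_universe <- function(config, responders = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_genes
  wlen <- nchar(config$spike_word)
  withr::with_seed(config$substream[["utr"]], {
    lens <- pmax(1L, as.integer(round(rlnorm(n, config$utr_log_mean, config$utr_log_sd))))
    if (any(lens < wlen)) {
      abort_data("spike word is longer than the shortest simulated UTR.")
    }
    gc <- config$gc_content
    base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    draws <- sample(names(base_probs), sum(lens), replace = TRUE, prob = base_probs)
    ends <- cumsum(lens)
    seqs <- substring(paste(draws, collapse = ""), ends - lens + 1L, ends)
    is_responder <- rep(FALSE, n)
    if (!is.null(responders)) is_responder[responders] <- TRUE
    rate <- ifelse(is_responder, config$carrier_rate_responder,
                   config$carrier_rate_background)
    is_carrier <- runif(n) < rate
    spike_pos <- rep(NA_integer_, n)
    idx <- which(is_carrier)
    if (length(idx) > 0) {
      starts <- vapply(lens[idx] - wlen + 1L,
                       function(m) sample.int(m, 1L), integer(1))
      spike_pos[idx] <- starts
      stringr::str_sub(seqs[idx], starts, starts + wlen - 1L) <- config$spike_word
    }
  })
  ids <- gene_ids(n)
  list(
    utrs = tibble(gene_id = ids, sequence = unname(seqs)),
    truth = tibble(
      gene_id = ids, length = lens,
      is_responder = is_responder, is_carrier = is_carrier,
      spike_pos = spike_pos
    )
  )
}

#' Simulate a ranked differential-expression experiment
#'
#' Responders get true log2 fold change `effect_size`, all other genes 0; the
#' observed per-gene log2 fold change adds `Normal(0, noise_sd)` noise. Probe
#' intensities are constructed so that [collapse_and_rank()] recovers the
#' observed fold changes exactly (one probe per gene; control intensity
#' `2^b - 1`, treated `2^(b + fc) - 1`), and negative-control probes are
#' drawn from a low-intensity null so the detection filter separates signal
#' from background.
#'
#' @param config A [synth_config()].
#' @param truth Truth tibble from [simulate_utr_universe()] (its
#'   `is_responder` column defines the responders).
#' @return List with `expr` (wide intensity tibble), `probe_info`,
#'   `sample_info`, `annotation`, and `truth` extended with `true_log2fc` and
#'   `obs_log2fc`.
#' @export
simulate_ranked_experiment <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  assert_cols(truth, c("gene_id", "is_responder"), "truth")
  n <- nrow(truth)
  samples <- c(sprintf("T%02d", seq_len(config$n_treated)),
               sprintf("C%02d", seq_len(config$n_control)))
  conditions <- rep(c("treated", "control"), c(config$n_treated, config$n_control))
  withr::with_seed(config$substream[["expr"]], {
    true_fc <- ifelse(truth$is_responder, config$effect_size, 0)
    obs_fc <- true_fc + rnorm(n, 0, config$noise_sd)
    nc <- matrix(
      pmax(rnorm(config$n_neg_control_probes * length(samples),
                 config$nc_mean, config$nc_sd), 0.1),
      nrow = config$n_neg_control_probes
    )
  })
  b <- config$baseline_log2
  control_int <- rep(2^b - 1, n)
  treated_int <- 2^(b + obs_fc) - 1
  signal <- cbind(
    matrix(rep(treated_int, config$n_treated), ncol = config$n_treated),
    matrix(rep(control_int, config$n_control), ncol = config$n_control)
  )
  probe_ids <- c(paste0("P_", truth$gene_id),
                 sprintf("NEG%03d", seq_len(config$n_neg_control_probes)))
  intensities <- rbind(signal, nc)
  expr <- as_tibble(as.data.frame(intensities))
  names(expr) <- samples
  expr <- dplyr::bind_cols(tibble(probe_id = probe_ids), expr)
  list(
    expr = expr,
    probe_info = tibble(
      probe_id = probe_ids,
      is_negative_control = c(rep(FALSE, n), rep(TRUE, config$n_neg_control_probes))
    ),
    sample_info = tibble(sample_id = samples, condition = conditions),
    annotation = tibble(
      probe_id = paste0("P_", truth$gene_id),
      gene_id = truth$gene_id,
      has_full_utr = TRUE
    ),
    truth = mutate(truth, true_log2fc = true_fc, obs_log2fc = obs_fc)
  )
}

#' Simulate a full SCR spike-in experiment
#'
#' Composes [simulate_responders()], [simulate_utr_universe()] and
#' [simulate_ranked_experiment()] under one configuration: responders are
#' designated first, carriers are then drawn at the responder/background
#' rates, and the expression experiment applies the effect to the responders.
#'
#' @param config A [synth_config()].
#' @return The list from [simulate_ranked_experiment()] plus `utrs`.
#' @export
simulate_scr_experiment <- function(config) {
  responders <- simulate_responders(config)
  uni <- simulate_utr_universe(config, responders = responders)
  exp <- simulate_ranked_experiment(config, uni$truth)
  c(list(utrs = uni$utrs), exp)
}

#' Simulate two-group pyrosequencing methylation tables
#'
#' Per-site, per-replicate percent methylation is drawn
#' `Normal(group mean, meth_sd)` and clamped to \[0, 100\]. Site means may be
#' scalars (shared across sites) or per-site vectors.
#'
#' @param config A [synth_config()].
#' @return Pyro tibble `sample_id`, `group`, `chrom`, `pos`, `replicate`,
#'   `pct_meth` with groups `malignant` and `control`.
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_sites <- config$meth_n_sites
  mean_case <- rep_len(config$meth_mean_case, n_sites)
  mean_control <- rep_len(config$meth_mean_control, n_sites)
  design <- tidyr::expand_grid(
    group = c("malignant", "control"),
    member = seq_len(config$meth_n_per_group),
    site = seq_len(n_sites),
    replicate = seq_len(config$meth_n_replicates)
  ) %>%
    mutate(
      sample_id = sprintf("%s%02d", if_else(.data$group == "malignant", "M", "N"),
                          .data$member),
      chrom = "chr11",
      pos = 1000L + 50L * .data$site,
      mu = if_else(.data$group == "malignant", mean_case[.data$site],
                   mean_control[.data$site])
    )
  withr::with_seed(config$substream[["meth"]], {
    design$pct_meth <- pmin(pmax(rnorm(nrow(design), design$mu, config$meth_sd), 0), 100)
  })
  design %>%
    select("sample_id", "group", "chrom", "pos", "replicate", "pct_meth")
}

#' Simulate a qPCR Ct table with known relative quantities
#'
#' A target assay plus `ct_n_reference_assays` normalizer assays over a
#' reference sample (`S00`, true relative quantity 1) and `ct_n_samples`
#' further samples with true fold changes `ct_true_fc`. Target Cts are
#' `baseline - log2(true relative quantity) + Normal(0, ct_sd)`; reference
#' assays sit at fixed baselines plus noise, so
#' [ddct_relative_expression()] recovers the configured fold changes.
#'
#' @param config A [synth_config()].
#' @return List with `ct` (tibble `sample`, `assay`, `replicate`, `ct`),
#'   `reference_assays`, `reference_sample` and `truth` (tibble `sample`,
#'   `true_fc`).
#' @export
simulate_ct_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  samples <- c("S00", sprintf("S%02d", seq_len(config$ct_n_samples)))
  true_fc <- c(1, rep_len(config$ct_true_fc, config$ct_n_samples))
  ref_assays <- sprintf("REF%d", seq_len(config$ct_n_reference_assays))
  ref_baseline <- 20 + seq_along(ref_assays)
  target_baseline <- 26
  design <- tidyr::expand_grid(
    sample = samples,
    assay = c("TARGET", ref_assays),
    replicate = seq_len(config$ct_n_replicates)
  ) %>%
    left_join(tibble(sample = samples, true_fc = true_fc), by = "sample") %>%
    mutate(mu = if_else(
      .data$assay == "TARGET",
      target_baseline - log2(.data$true_fc),
      ref_baseline[match(.data$assay, ref_assays)]
    ))
  withr::with_seed(config$substream[["ct"]], {
    design$ct <- design$mu + rnorm(nrow(design), 0, config$ct_sd)
  })
  list(
    ct = select(design, "sample", "assay", "replicate", "ct"),
    reference_assays = ref_assays,
    reference_sample = "S00",
    truth = tibble(sample = samples, true_fc = true_fc)
  )
}
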