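# Probe-level expression preparation: detection filtering, gene-level
# collapse and ranking, BH adjustment, and delta-delta-Ct utilities.

#' Empirical detection p-values against negative-control probes
#'
#' For each probe, the detection p-value is the fraction of negative-control
#' intensity values (pooled over all negative-control probes and samples) that
#' are greater than or equal to the probe's mean intensity across samples.
#' Probes indistinguishable from the array's background therefore get large
#' p-values.
#'
#' @param expr Wide tibble: `probe_id` plus one numeric column per sample.
#' @param probe_info Tibble with `probe_id` and logical `is_negative_control`.
#' @return Tibble `probe_id`, `is_negative_control`, `mean_intensity`,
#'   `detection_p`.
#' @export
detection_pvalues <- function(expr, probe_info) {
  assert_cols(expr, "probe_id", "expr")
  assert_cols(probe_info, c("probe_id", "is_negative_control"), "probe_info")
  if (anyDuplicated(expr$probe_id)) abort_data("duplicate probe_ids in `expr`.")
  sample_cols <- setdiff(names(expr), "probe_id")
  if (length(sample_cols) == 0) abort_data("`expr` has no sample columns.")
  info <- expr %>%
    left_join(probe_info %>% select("probe_id", "is_negative_control"),
              by = "probe_id") %>%
    mutate(is_negative_control = dplyr::coalesce(.data$is_negative_control, FALSE))
  nc_rows <- info %>% filter(.data$is_negative_control)
  if (nrow(nc_rows) < 2) {
    abort_config("at least two negative-control probes are required for detection filtering.")
  }
  null_pool <- unlist(nc_rows[sample_cols], use.names = FALSE)
  mean_int <- rowMeans(as.matrix(info[sample_cols]))
  tibble(
    probe_id = info$probe_id,
    is_negative_control = info$is_negative_control,
    mean_intensity = mean_int,
    detection_p = vapply(mean_int, function(m) mean(null_pool >= m), numeric(1))
  )
}

#' Remove probes not detected above negative controls
#'
#' Retains probes whose empirical detection p-value (see
#' [detection_pvalues()]) is at most `alpha`; probes whose intensities are not
#' significantly above the negative controls are removed. Negative-control
#' probes themselves are kept (flagged in `probe_info`), so the filter is
#' idempotent: filtering an already-filtered matrix removes nothing.
#'
#' @inheritParams detection_pvalues
#' @param alpha Detection significance level; default 0.01.
#' @return The filtered `expr` tibble. The removed probes (with their
#'   detection p-values) are attached as attribute `"removal_log"`.
#' @export
detection_filter <- function(expr, probe_info, alpha = 0.01) {
  dp <- detection_pvalues(expr, probe_info)
  keep <- dp$is_negative_control | dp$detection_p <= alpha
  out <- expr[keep, , drop = FALSE]
  attr(out, "removal_log") <- dp[!keep, c("probe_id", "mean_intensity", "detection_p")]
  out
}

#' Collapse probes to genes and rank by log2 fold change
#'
#' Intensities are transformed as `log2(x + 1)`; the per-probe statistic is
#' mean log2 intensity in treated minus mean in control samples. Each gene is
#' represented by its probe with the largest absolute log2 fold change (ties
#' broken by probe_id), genes without full-length 3'UTR annotation are
#' dropped, and the list is sorted ascending: rank 1 is the most
#' downregulated gene -- the substrate of the enrichment landscape.
#'
#' @param expr Wide expression tibble (`probe_id` + sample columns), normally
#'   already passed through [detection_filter()].
#' @param sample_info Tibble `sample_id`, `condition` with conditions
#'   `"treated"` and `"control"`.
#' @param annotation Tibble `probe_id`, `gene_id`, `has_full_utr`.
#' @param log_offset Offset added before the log2 transform; default 1.
#' @return Ranked tibble `rank`, `gene_id`, `log2fc`.
#' @export
collapse_and_rank <- function(expr, sample_info, annotation, log_offset = 1) {
  assert_cols(expr, "probe_id", "expr")
  assert_cols(sample_info, c("sample_id", "condition"), "sample_info")
  assert_cols(annotation, c("probe_id", "gene_id", "has_full_utr"), "annotation")
  treated <- sample_info$sample_id[sample_info$condition == "treated"]
  control <- sample_info$sample_id[sample_info$condition == "control"]
  if (length(treated) == 0 || length(control) == 0) {
    abort_config("both treated and control samples are required.")
  }
  missing <- setdiff(c(treated, control), names(expr))
  if (length(missing) > 0) {
    abort_data(sprintf("sample column(s) absent from `expr`: %s",
                       paste(missing, collapse = ", ")))
  }
  logm <- function(cols) rowMeans(log2(as.matrix(expr[cols]) + log_offset))
  per_probe <- tibble(
    probe_id = expr$probe_id,
    log2fc = logm(treated) - logm(control)
  )
  ranked <- per_probe %>%
    inner_join(annotation, by = "probe_id") %>%
    filter(!is.na(.data$gene_id), .data$has_full_utr) %>%
    arrange(dplyr::desc(abs(.data$log2fc)), .data$probe_id) %>%
    distinct(.data$gene_id, .keep_all = TRUE) %>%
    arrange(.data$log2fc, .data$gene_id) %>%
    mutate(rank = dplyr::row_number()) %>%
    select("rank", "gene_id", "log2fc")
  if (nrow(ranked) == 0) abort_data("no genes remain after annotation filtering.")
  ranked
}

#' Benjamini-Hochberg adjustment with a significance flag
#'
#' Step-up false-discovery-rate control; flags tests whose adjusted p-value is
#' at most `q` (the array comparisons use q = 0.1).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q FDR cutoff; default 0.1.
#' @return Tibble `p_value`, `p_adjusted`, `significant`.
#' @export
bh_adjust <- function(p_values, q = 0.1) {
  if (length(p_values) == 0) {
    return(tibble(p_value = numeric(), p_adjusted = numeric(), significant = logical()))
  }
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_data("p-values must lie in [0, 1].")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, p_adjusted = adj, significant = adj <= q)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Cts are averaged per (sample, assay); per sample,
#' `delta Ct = Ct(target) - mean(Ct over reference assays)`; relative
#' expression is `2^-(delta Ct - delta Ct of the reference sample)`, so the
#' reference sample maps to 1. With a multi-assay normalizer panel the
#' arithmetic mean of the reference Cts is used (equivalent to a geometric
#' mean of linear quantities).
#'
#' @param ct Tibble `sample`, `assay`, `replicate`, `ct`.
#' @param reference_assays Character vector of normalizer assay names.
#' @param reference_sample Sample whose expression defines 1.0.
#' @return Tibble `sample`, `assay`, `delta_ct`, `ddct`, `rel_expr` for every
#'   non-reference assay.
#' @export
ddct_relative_expression <- function(ct, reference_assays, reference_sample) {
  assert_cols(ct, c("sample", "assay", "ct"), "ct")
  if (any(!is.finite(ct$ct))) abort_data("Ct values must be finite.")
  if (!all(reference_assays %in% ct$assay)) {
    abort_config("reference assay(s) missing from the Ct table.")
  }
  if (!reference_sample %in% ct$sample) {
    abort_config("reference sample missing from the Ct table.")
  }
  means <- ct %>%
    group_by(.data$sample, .data$assay) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- means %>%
    filter(.data$assay %in% reference_assays) %>%
    group_by(.data$sample) %>%
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  if (!all(means$sample %in% ref$sample)) {
    abort_data("every sample needs Ct values for the reference assays.")
  }
  dct <- means %>%
    filter(!.data$assay %in% reference_assays) %>%
    left_join(ref, by = "sample") %>%
    mutate(delta_ct = .data$ct - .data$ref_ct)
  ref_dct <- dct %>%
    filter(.data$sample == reference_sample) %>%
    select("assay", ref_delta_ct = "delta_ct")
  if (nrow(ref_dct) == 0) abort_config("reference sample has no target-assay Ct values.")
  dct %>%
    left_join(ref_dct, by = "assay") %>%
    mutate(
      ddct = .data$delta_ct - .data$ref_delta_ct,
      rel_expr = 2^(-.data$ddct)
    ) %>%
    select("sample", "assay", "delta_ct", "ddct", "rel_expr") %>%
    arrange(.data$assay, .data$sample)
}
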