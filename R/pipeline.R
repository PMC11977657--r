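# End-to-end orchestration: detection filter -> rank -> scan -> landscape ->
# SSSS -> CPDV -> targets -> summary (+ optional ORA and methylation branch).

#' Assemble and validate a pipeline configuration
#'
#' Inputs may be given as in-memory tibbles or as file paths (read on
#' [run_pipeline()] entry); thresholds default to the pipeline's standard
#' operating values (detection alpha 0.01, FDR q 0.1, de-repression log2FC
#' threshold 0.5, five probes per region, 200-gene bins, 5-bin CPDV
#' lookahead). Validation of thresholds and file existence happens here, so a
#' misconfigured run fails before any computation.
#'
#' @param utrs,mirnas,expr,probe_info,sample_info,annotation,gene_sets,pyro
#'   In-memory inputs (see the module functions for their shapes).
#' @param utr_fasta,mirna_tsv,expr_tsv,probe_info_tsv,sample_info_tsv,
#'   annotation_tsv,gmt,pyro_tsv File-path alternatives.
#' @param bin_width Genes per landscape bin.
#' @param lookahead CPDV lookahead in bins.
#' @param detection_alpha Detection-filter significance level.
#' @param fdr_q BH FDR cutoff carried in the manifest.
#' @param fc_threshold De-repression log2 fold-change threshold.
#' @param min_probes Region probe-count minimum.
#' @param element_spec SCR element spans (`NULL` = six defaults).
#' @param ssss_method `"sum"` or `"fisher"`.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @param seed Seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(utrs = NULL, utr_fasta = NULL,
                            mirnas = NULL, mirna_tsv = NULL,
                            expr = NULL, expr_tsv = NULL,
                            probe_info = NULL, probe_info_tsv = NULL,
                            sample_info = NULL, sample_info_tsv = NULL,
                            annotation = NULL, annotation_tsv = NULL,
                            gene_sets = NULL, gmt = NULL,
                            pyro = NULL, pyro_tsv = NULL,
                            bin_width = 200L, lookahead = 5L,
                            detection_alpha = 0.01, fdr_q = 0.1,
                            fc_threshold = 0.5, min_probes = 5L,
                            element_spec = NULL,
                            ssss_method = c("sum", "fisher"),
                            out_dir = NULL, seed = 1L) {
  ssss_method <- match.arg(ssss_method)
  if (detection_alpha <= 0 || detection_alpha >= 1) {
    abort_config("detection_alpha must lie in (0, 1).")
  }
  if (fdr_q <= 0 || fdr_q > 1) abort_config("fdr_q must lie in (0, 1].")
  if (bin_width < 1 || lookahead < 1) {
    abort_config("bin_width and lookahead must be positive.")
  }
  paths <- list(utr_fasta = utr_fasta, mirna_tsv = mirna_tsv, expr_tsv = expr_tsv,
                probe_info_tsv = probe_info_tsv, sample_info_tsv = sample_info_tsv,
                annotation_tsv = annotation_tsv, gmt = gmt, pyro_tsv = pyro_tsv)
  for (key in names(paths)) {
    if (!is.null(paths[[key]]) && !file.exists(paths[[key]])) {
      abort_config(sprintf("configured %s does not exist: %s", key, paths[[key]]))
    }
  }
  need <- function(obj, path, what) {
    if (is.null(obj) && is.null(path)) {
      abort_config(sprintf("pipeline needs %s (object or file).", what))
    }
  }
  need(utrs, utr_fasta, "a 3'UTR universe")
  need(mirnas, mirna_tsv, "miRNA definitions")
  need(expr, expr_tsv, "an expression matrix")
  need(probe_info, probe_info_tsv, "probe annotations (negative-control flags)")
  need(sample_info, sample_info_tsv, "sample condition labels")
  need(annotation, annotation_tsv, "a probe-to-gene annotation")
  structure(
    list(
      utrs = utrs, mirnas = mirnas, expr = expr, probe_info = probe_info,
      sample_info = sample_info, annotation = annotation,
      gene_sets = gene_sets, pyro = pyro, paths = paths,
      bin_width = as.integer(bin_width), lookahead = as.integer(lookahead),
      detection_alpha = detection_alpha, fdr_q = fdr_q,
      fc_threshold = fc_threshold, min_probes = as.integer(min_probes),
      element_spec = element_spec, ssss_method = ssss_method,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

read_tsv_checked <- function(path) readr::read_tsv(path, show_col_types = FALSE)

resolve_inputs <- function(config) {
  p <- config$paths
  config$utrs <- config$utrs %||% read_utr_fasta(p$utr_fasta)
  config$mirnas <- config$mirnas %||% read_mirna_table(p$mirna_tsv)
  config$expr <- config$expr %||% read_tsv_checked(p$expr_tsv)
  config$probe_info <- config$probe_info %||% read_tsv_checked(p$probe_info_tsv)
  config$sample_info <- config$sample_info %||% read_tsv_checked(p$sample_info_tsv)
  config$annotation <- config$annotation %||% read_tsv_checked(p$annotation_tsv)
  if (is.null(config$gene_sets) && !is.null(p$gmt)) {
    config$gene_sets <- read_gmt(p$gmt)
  }
  if (is.null(config$pyro) && !is.null(p$pyro_tsv)) {
    config$pyro <- read_pyro_table(p$pyro_tsv)
  }
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
          class = c("seedscape_stage_error",
                    setdiff(class(e), c("rlang_error", "error", "condition"))),
          parent = e)
  })
}

#' Run the full SCR enrichment pipeline
#'
#' Executes, in order: negative-control detection filtering, gene-level
#' collapse and ranking, SCR element derivation, 3'UTR occurrence scanning,
#' the binned hypergeometric landscape, SSSS integration per miRNA, CPDV cut
#' selection (on the bin-wise sum of the per-miRNA SSSS curves when several
#' miRNAs are configured; per-miRNA cut points are also reported),
#' leading-edge SCR target selection with a two-set summary, and -- when the
#' corresponding inputs are configured -- hypergeometric over-representation
#' analysis and the methylation branch (cumulative scores plus a two-group
#' comparison). When `out_dir` is set, the tabular results and a JSON run
#' manifest holding every parameter and the seed are written there.
#'
#' @param config A `pipeline_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return A `scr_pipeline` list: `ranked`, `elements`, `occurrences`,
#'   `landscape`, `ssss`, `cutpoint`, `cutpoints_by_mirna`, `targets`,
#'   `target_summary`, `ora`, `methylation`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  config <- stage("load_inputs", resolve_inputs(config))

  filtered <- stage("detection_filter",
                    detection_filter(config$expr, config$probe_info,
                                     alpha = config$detection_alpha))
  ranked <- stage("collapse_and_rank",
                  collapse_and_rank(filtered, config$sample_info, config$annotation))
  elements <- stage("derive_scr_elements",
                    derive_scr_elements(config$mirnas, element_spec = config$element_spec))
  occurrences <- stage("scan_occurrences",
                       scan_occurrences(config$utrs, unique(elements$word)))
  landscape <- stage("hypergeometric_landscape",
                     hypergeometric_landscape(ranked, occurrences,
                                              words = unique(elements$word),
                                              bin_width = config$bin_width))
  ssss <- stage("ssss_integration",
                ssss_integration(landscape, elements, method = config$ssss_method))

  combined <- ssss %>%
    group_by(.data$bin, .data$n_leading) %>%
    summarise(ssss = sum(.data$ssss), .groups = "drop")
  cutpoint <- stage("cpdv_select",
                    cpdv_select(combined$ssss, lookahead = config$lookahead,
                                bin_width = config$bin_width))
  cutpoints_by_mirna <- ssss %>%
    split(.$mirna) %>%
    purrr::map(cpdv_select, lookahead = config$lookahead,
               bin_width = config$bin_width)

  words <- stage("canonical_words", canonical_scr_words(config$mirnas))
  targets <- stage("select_down_targets",
                   select_down_targets(ranked, cutpoint, occurrences, words))
  target_summary <- if (length(words) == 2) {
    stage("summarize_targets", summarize_targets(targets, cutpoint$n_leading))
  } else NULL

  ora_table <- if (!is.null(config$gene_sets)) {
    stage("ora", ora(targets, config$gene_sets, universe = ranked$gene_id))
  } else NULL

  methylation <- if (!is.null(config$pyro)) {
    stage("methylation", {
      scores <- cumulative_methylation(config$pyro)
      list(scores = scores, comparison = compare_groups(scores))
    })
  } else NULL

  manifest <- list(
    package = "seedscape",
    version = as.character(utils::packageVersion("seedscape")),
    seed = config$seed,
    parameters = list(
      bin_width = config$bin_width, lookahead = config$lookahead,
      detection_alpha = config$detection_alpha, fdr_q = config$fdr_q,
      fc_threshold = config$fc_threshold, min_probes = config$min_probes,
      ssss_method = config$ssss_method
    ),
    inputs = Filter(Negate(is.null), config$paths),
    n_genes_ranked = nrow(ranked),
    n_probes_removed = nrow(attr(filtered, "removal_log")),
    selected_bin = cutpoint$selected_bin,
    n_leading = cutpoint$n_leading,
    target_sizes = as.list(table(as_tibble(targets)$mirna)),
    target_union = if (!is.null(target_summary)) target_summary$n_union else NULL
  )

  result <- structure(
    list(
      ranked = ranked, elements = elements, occurrences = occurrences,
      landscape = landscape, ssss = ssss, cutpoint = cutpoint,
      cutpoints_by_mirna = cutpoints_by_mirna, targets = targets,
      target_summary = target_summary, ora = ora_table,
      methylation = methylation, manifest = manifest
    ),
    class = "scr_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$ranked, file.path(out_dir, "ranked_list.tsv"))
  readr::write_tsv(as_tibble(result$landscape), file.path(out_dir, "landscape.tsv"))
  readr::write_tsv(as_tibble(result$ssss), file.path(out_dir, "ssss.tsv"))
  readr::write_tsv(result$cutpoint$table, file.path(out_dir, "cpdv.tsv"))
  readr::write_tsv(as_tibble(result$targets), file.path(out_dir, "targets.tsv"))
  if (!is.null(result$target_summary)) {
    readr::write_tsv(result$target_summary, file.path(out_dir, "target_summary.tsv"))
  }
  if (!is.null(result$ora)) {
    readr::write_tsv(result$ora, file.path(out_dir, "ora.tsv"))
  }
  if (!is.null(result$methylation)) {
    readr::write_tsv(result$methylation$scores,
                     file.path(out_dir, "methylation_scores.tsv"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.scr_pipeline <- function(x, ...) {
  cat("<scr_pipeline>\n")
  cat(sprintf("  ranked genes: %d\n", nrow(x$ranked)))
  cat(sprintf("  cut: bin %d (%s genes)\n", x$cutpoint$selected_bin,
              format(x$cutpoint$n_leading)))
  if (!is.null(x$target_summary)) {
    cat(sprintf("  target union: %d (%.1f%% of leading edge)\n",
                x$target_summary$n_union, x$target_summary$union_pct))
  }
  invisible(x)
}
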