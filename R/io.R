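# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA 3'UTR universes, TSV tables, BED regions, GMT gene sets, YAML config.

#' Read a 3'UTR universe from FASTA
#'
#' Record ids are truncated at the first whitespace; sequences are uppercased
#' and `U` is converted to `T` so all matching happens in DNA space.
#'
#' @param path FASTA file.
#' @return Tibble `gene_id`, `sequence`.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) abort_data(sprintf("duplicate FASTA ids in %s", path))
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  if (any(grepl("[^ACGTN]", seqs))) {
    abort_data(sprintf("non-DNA characters in FASTA sequences: %s", path))
  }
  tibble(gene_id = ids, sequence = unname(seqs))
}

#' Write a 3'UTR universe to FASTA
#'
#' @param utrs Tibble `gene_id`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  assert_cols(utrs, c("gene_id", "sequence"), "utrs")
  ss <- Biostrings::DNAStringSet(setNames(toupper(utrs$sequence), utrs$gene_id))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read / write a ranked gene list as TSV
#'
#' Columns `rank`, `gene_id`, `log2fc`.
#'
#' @param path TSV file.
#' @return Ranked tibble, ordered by `rank`.
#' @export
read_ranked_list <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("ranked-list file not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(out, c("rank", "gene_id", "log2fc"), "ranked list")
  if (anyDuplicated(out$gene_id)) abort_data("duplicate gene_ids in ranked list.")
  arrange(out, .data$rank)
}

#' @rdname read_ranked_list
#' @param ranked Ranked tibble from [collapse_and_rank()].
#' @export
write_ranked_list <- function(ranked, path) {
  assert_cols(ranked, c("rank", "gene_id", "log2fc"), "ranked")
  readr::write_tsv(ranked, path)
  invisible(path)
}

#' Read miRNA definitions from TSV
#'
#' Columns `name`, `mature_seq` and optionally `seed_from`, `seed_to`
#' (defaults 1 and 8).
#'
#' @param path TSV file.
#' @return Validated miRNA tibble (see [mirna_table()]).
#' @export
read_mirna_table <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("miRNA file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(raw, c("name", "mature_seq"), "miRNA table")
  mirna_table(
    raw$name, raw$mature_seq,
    seed_from = if ("seed_from" %in% names(raw)) raw$seed_from else 1L,
    seed_to = if ("seed_to" %in% names(raw)) raw$seed_to else 8L
  )
}

#' Read BED regions (0-based half-open)
#'
#' @param path BED file (chrom, start, end, optional name).
#' @return Tibble `chrom`, `start`, `end`(, `name`).
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("BED file not found: %s", path))
  out <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, comment = "#")
  if (ncol(out) < 3) abort_data("BED files need at least 3 columns.")
  names(out)[1:3] <- c("chrom", "start", "end")
  if (ncol(out) >= 4) names(out)[4] <- "name"
  out <- out[, intersect(c("chrom", "start", "end", "name"), names(out))]
  if (any(out$start >= out$end)) abort_data("BED intervals must satisfy start < end.")
  out
}

#' @rdname read_bed_regions
#' @param regions Tibble `chrom`, `start`, `end`(, `name`).
#' @export
write_bed_regions <- function(regions, path) {
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  cols <- intersect(c("chrom", "start", "end", "name"), names(regions))
  readr::write_tsv(regions[cols], path, col_names = FALSE)
  invisible(path)
}

#' Convert between BED (0-based half-open) and 1-based inclusive intervals
#'
#' Summaries report 1-based inclusive coordinates; files store BED. The two
#' conversions are exact inverses.
#'
#' @param regions Tibble with `start`, `end`.
#' @return The tibble with converted coordinates.
#' @export
bed_to_1based <- function(regions) {
  assert_cols(regions, c("start", "end"), "regions")
  mutate(regions, start = .data$start + 1L, end = .data$end)
}

#' @rdname bed_to_1based
#' @export
onebased_to_bed <- function(regions) {
  assert_cols(regions, c("start", "end"), "regions")
  mutate(regions, start = .data$start - 1L, end = .data$end)
}

#' Read GMT gene sets
#'
#' @param path GMT file (set name, description, tab-separated gene ids).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("GMT file not found: %s", path))
  fgsea::gmtPathways(path)
}

#' Read a pyrosequencing percent-methylation table
#'
#' @param path TSV with columns `sample_id`, `group`, `chrom`, `pos`,
#'   `replicate`, `pct_meth`.
#' @return Pyro tibble as consumed by [cumulative_methylation()].
#' @export
read_pyro_table <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("pyro table not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(out, c("sample_id", "group", "chrom", "pos", "replicate", "pct_meth"),
              "pyro table")
  out
}

#' Read an array beta-value table and derive M-values
#'
#' @param path TSV with columns `probe_id`, `chrom`, `pos` plus one numeric
#'   beta column per sample.
#' @param eps Clipping bound passed to [beta_to_m()].
#' @return Long tibble `probe_id`, `chrom`, `pos`, `sample_id`, `beta`,
#'   `m_value`.
#' @export
read_beta_table <- function(path, eps = 1e-6) {
  if (!file.exists(path)) abort_config(sprintf("beta table not found: %s", path))
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(wide, c("probe_id", "chrom", "pos"), "beta table")
  wide %>%
    tidyr::pivot_longer(-c("probe_id", "chrom", "pos"),
                        names_to = "sample_id", values_to = "beta") %>%
    mutate(m_value = beta_to_m(.data$beta, eps = eps))
}

#' Read a pipeline configuration from YAML
#'
#' Validates threshold ranges and that every referenced input file exists,
#' before any computation starts.
#'
#' @param path YAML file; keys mirror the arguments of [pipeline_config()],
#'   with input paths under `utr_fasta`, `mirna_tsv`.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  for (key in c("utr_fasta", "mirna_tsv")) {
    if (!is.null(raw[[key]]) && !file.exists(raw[[key]])) {
      abort_config(sprintf("configured %s does not exist: %s", key, raw[[key]]))
    }
  }
  do.call(pipeline_config, raw)
}
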