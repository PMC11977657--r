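# SCR-containing target gene lists, set-algebra summaries, and generic
# hypergeometric over-representation analysis.

new_scr_targets <- function(df, direction) {
  structure(df, class = c("scr_targets", class(tibble())), direction = direction)
}

#' Downregulated SCR-containing targets at a leading-edge cut
#'
#' Genes among the `n_leading` most-downregulated whose 3'UTR contains the
#' miRNA's SCR word: the direct-target candidates behind an enrichment peak.
#'
#' @param ranked Ranked tibble (`rank`, `gene_id`) from [collapse_and_rank()].
#' @param cut A `scr_cutpoint` from [cpdv_select()], or an integer leading-edge
#'   gene count.
#' @param occurrences Occurrence index from [scan_occurrences()].
#' @param words Named character vector, miRNA name -> SCR word (typically
#'   [canonical_scr_words()]).
#' @return A `scr_targets` tibble (`mirna`, `gene_id`, `word`, `rank`) with
#'   attribute `direction = "down"`.
#' @export
select_down_targets <- function(ranked, cut, occurrences, words) {
  assert_cols(ranked, "gene_id", "ranked")
  assert_cols(occurrences, c("gene_id", "word", "present"), "occurrences")
  n_leading <- if (inherits(cut, "scr_cutpoint")) cut$n_leading else as.integer(cut)
  if (is.na(n_leading)) abort_config("the cut does not define a leading-edge gene count.")
  if (n_leading > nrow(ranked)) abort_config("cut exceeds the ranked list length.")
  if (is.null(names(words)) || any(!nzchar(names(words)))) {
    abort_config("`words` must be a named vector (miRNA -> word).")
  }
  if ("rank" %in% names(ranked)) ranked <- arrange(ranked, .data$rank)
  leading <- head(ranked$gene_id, n_leading)
  out <- purrr::imap_dfr(words, function(w, mirna) {
    carriers <- occurrences %>%
      filter(.data$word == !!toupper(w), .data$present) %>%
      pull("gene_id")
    hit <- intersect(leading, carriers)
    tibble(mirna = mirna, gene_id = hit, word = toupper(w),
           rank = match(hit, ranked$gene_id))
  })
  new_scr_targets(arrange(out, .data$mirna, .data$rank), "down")
}

#' Upregulated (de-repressed) SCR-containing targets
#'
#' In samples where the miRNAs are lost, their targets are de-repressed:
#' selects genes with log2 fold change strictly greater than `fc_threshold`
#' whose 3'UTR carries the SCR word. A gene at exactly the threshold is
#' excluded.
#'
#' @param ranked Tibble with `gene_id` and `log2fc`.
#' @param occurrences Occurrence index from [scan_occurrences()].
#' @param words Named character vector, miRNA name -> SCR word.
#' @param fc_threshold log2 fold-change threshold; default 0.5.
#' @return A `scr_targets` tibble with attribute `direction = "up"`.
#' @export
select_up_targets <- function(ranked, occurrences, words, fc_threshold = 0.5) {
  assert_cols(ranked, c("gene_id", "log2fc"), "ranked")
  assert_cols(occurrences, c("gene_id", "word", "present"), "occurrences")
  if (is.null(names(words)) || any(!nzchar(names(words)))) {
    abort_config("`words` must be a named vector (miRNA -> word).")
  }
  up <- ranked %>% filter(.data$log2fc > fc_threshold)
  out <- purrr::imap_dfr(words, function(w, mirna) {
    carriers <- occurrences %>%
      filter(.data$word == !!toupper(w), .data$present) %>%
      pull("gene_id")
    hit <- up %>% filter(.data$gene_id %in% carriers)
    tibble(mirna = mirna, gene_id = hit$gene_id, word = toupper(w),
           log2fc = hit$log2fc)
  })
  new_scr_targets(out, "up")
}

#' Set-algebra summary from target-set counts
#'
#' Inclusion-exclusion on two target sets given only their sizes and overlap:
#' `union = n_a + n_b - n_overlap`, with the union also expressed as a
#' percentage of a reference list length (e.g. the 1400-gene leading edge).
#' Vectorised over its arguments.
#'
#' @param n_a,n_b Per-set sizes.
#' @param n_overlap Size of the intersection.
#' @param list_length Reference list length for the percentage, or `NA`.
#' @return Tibble `n_a`, `n_b`, `n_overlap`, `n_total` (before
#'   de-duplication), `n_union`, `list_length`, `union_pct`.
#' @examples
#' summarize_target_counts(197, 793, 158, 1400) # union 832, 59.4%
#' @export
summarize_target_counts <- function(n_a, n_b, n_overlap, list_length = NA_integer_) {
  if (any(n_overlap > pmin(n_a, n_b)) || any(n_overlap < 0)) {
    abort_data("overlap must lie between 0 and min(n_a, n_b).")
  }
  n_union <- n_a + n_b - n_overlap
  tibble(
    n_a = as.integer(n_a), n_b = as.integer(n_b),
    n_overlap = as.integer(n_overlap),
    n_total = as.integer(n_a + n_b),
    n_union = as.integer(n_union),
    list_length = as.integer(list_length),
    union_pct = 100 * n_union / list_length
  )
}

#' Summarise the set algebra of two target sets
#'
#' Computes per-miRNA set sizes, their overlap, the de-duplicated union and
#' the union as a percentage of the reference list, via inclusion-exclusion.
#'
#' @param targets A `scr_targets` tibble containing exactly two miRNAs, or a
#'   list of two `scr_targets` of the same direction.
#' @param list_length Reference list length (e.g. leading-edge size for
#'   downregulated targets).
#' @return One-row tibble: `mirna_a`, `mirna_b` plus the columns of
#'   [summarize_target_counts()].
#' @export
summarize_targets <- function(targets, list_length = NA_integer_) {
  if (is.list(targets) && !is.data.frame(targets)) {
    dirs <- unique(vapply(targets, function(t) attr(t, "direction") %||% NA_character_,
                          character(1)))
    if (length(dirs) > 1) abort_data("target sets must share a direction.")
    targets <- bind_rows(lapply(targets, as_tibble))
  }
  assert_cols(targets, c("mirna", "gene_id"), "targets")
  mirnas <- unique(targets$mirna)
  if (length(mirnas) != 2) {
    abort_data("summarize_targets expects exactly two miRNA target sets.")
  }
  a <- unique(targets$gene_id[targets$mirna == mirnas[1]])
  b <- unique(targets$gene_id[targets$mirna == mirnas[2]])
  counts <- summarize_target_counts(length(a), length(b),
                                    length(intersect(a, b)), list_length)
  dplyr::bind_cols(tibble(mirna_a = mirnas[1], mirna_b = mirnas[2]), counts)
}

#' Hypergeometric over-representation analysis
#'
#' For each named gene set, tests whether the target list overlaps it more
#' than expected by chance in the stated universe: with universe size `N`,
#' set size `K`, target size `n` and overlap `x`, `p = P(X >= x)` for
#' `X ~ Hypergeometric(N, K, n)`; Benjamini-Hochberg adjusted across sets and
#' ranked by p-value.
#'
#' @param target_genes Character vector of target gene ids (or a
#'   `scr_targets` tibble, whose unique `gene_id`s are used).
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of universe gene ids; target and sets are
#'   intersected with it, and the target must be contained in it.
#' @return Tibble `set`, `n_set`, `n_target`, `n_overlap`, `p_value`,
#'   `p_adjusted`, sorted by `p_value`.
#' @export
ora <- function(target_genes, gene_sets, universe) {
  if (is.data.frame(target_genes)) target_genes <- target_genes$gene_id
  target_genes <- unique(target_genes)
  universe <- unique(universe)
  if (!all(target_genes %in% universe)) {
    abort_data("target genes must be a subset of the universe.")
  }
  if (length(gene_sets) == 0) {
    return(tibble(set = character(), n_set = integer(), n_target = integer(),
                  n_overlap = integer(), p_value = numeric(), p_adjusted = numeric()))
  }
  if (is.null(names(gene_sets))) abort_data("`gene_sets` must be named.")
  N <- length(universe)
  n <- length(target_genes)
  res <- purrr::imap_dfr(gene_sets, function(genes, set_name) {
    K <- length(intersect(unique(genes), universe))
    x <- length(intersect(target_genes, genes))
    tibble(
      set = set_name, n_set = K, n_target = n, n_overlap = x,
      p_value = phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  res %>%
    mutate(p_adjusted = p.adjust(.data$p_value, method = "BH")) %>%
    arrange(.data$p_value, .data$set)
}
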