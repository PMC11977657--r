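# Seed-complementary-region derivation and 3'UTR occurrence scanning.

#' Define one or more mature microRNAs
#'
#' Builds the miRNA table used throughout the package. The seed region is the
#' 5' end of the mature sequence (positions 1-8 by default, with the canonical
#' seed word at positions 2-7); target recognition in 3'UTRs is dominated by
#' Watson-Crick pairing to this region, so its DNA reverse complements (the
#' seed complementary regions, SCRs) are what we scan for.
#'
#' @param name Character vector of miRNA labels (e.g. `"miR-100-5p"`).
#' @param mature_seq Mature sequences, 5' to 3', RNA alphabet (A/C/G/U).
#' @param seed_from,seed_to 1-based inclusive bounds of the seed region on the
#'   mature sequence. Defaults cover the full 1-8 nt seed.
#' @return A tibble with one row per miRNA: `name`, `mature_seq`, `seed_from`,
#'   `seed_to`.
#' @examples
#' mirna_table("miR-100-5p", "AACCCGUAGAUCCGAACUUGUG")
#' @export
mirna_table <- function(name, mature_seq, seed_from = 1L, seed_to = 8L) {
  mature_seq <- toupper(mature_seq)
  out <- tibble(
    name = as.character(name),
    mature_seq = mature_seq,
    seed_from = as.integer(seed_from),
    seed_to = as.integer(seed_to)
  )
  bad <- grepl("[^ACGU]", out$mature_seq)
  if (any(bad)) {
    abort_data(sprintf(
      "mature_seq must use the RNA alphabet A/C/G/U; offending: %s",
      paste(out$name[bad], collapse = ", ")
    ))
  }
  if (any(nchar(out$mature_seq) < 8)) {
    abort_data("mature sequences must be at least 8 nt long.")
  }
  if (any(out$seed_from < 1 | out$seed_to > nchar(out$mature_seq) |
            out$seed_from >= out$seed_to)) {
    abort_data("seed span must lie within the mature sequence bounds.")
  }
  out
}

#' Default SCR element spans over a seed region
#'
#' All contiguous sub-spans of the seed region with lengths 6, 7 and 8: for the
#' full 1-8 seed these are 1-6, 2-7, 3-8 (6-mers), 1-7, 2-8 (7-mers) and 1-8
#' (the 8-mer) -- six elements per miRNA.
#'
#' @param seed_from,seed_to 1-based inclusive seed bounds.
#' @param lengths Element lengths to enumerate.
#' @return List of integer pairs `c(start, end)` (positions on the miRNA).
#' @export
default_element_spans <- function(seed_from = 1L, seed_to = 8L, lengths = 6:8) {
  spans <- list()
  for (len in lengths) {
    starts <- seq.int(seed_from, seed_to - len + 1L)
    for (s in starts) spans[[length(spans) + 1L]] <- c(s, s + len - 1L)
  }
  spans
}

rna_to_dna <- function(x) chartr("U", "T", x)

revcomp_dna <- function(x) {
  vapply(
    x,
    function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1),
    USE.NAMES = FALSE
  )
}

#' Derive seed-complementary-region (SCR) element words
#'
#' For each miRNA and each seed sub-span, computes the DNA word complementary
#' to that stretch of the seed: the seed sub-sequence is transcribed U->T and
#' reverse-complemented, giving the uppercase DNA word a target 3'UTR must
#' contain. The canonical single-word SCR is the 2-7 element (e.g. `ACGGGT`
#' for miR-100-5p, `TCAGGG` for miR-125b-5p); the default six-element set
#' covers every contiguous 6-8 nt sub-span of the 1-8 seed.
#'
#' @param mirnas Tibble from [mirna_table()].
#' @param element_spec List of integer pairs `c(start, end)` (1-based,
#'   inclusive, positions on the miRNA) or `NULL` for the six default spans of
#'   each miRNA's seed region.
#' @return Tibble with columns `mirna`, `label` (e.g. `"m2-7"`), `seed_start`,
#'   `seed_end`, `word`.
#' @examples
#' mi <- mirna_table("miR-100-5p", "AACCCGUAGAUCCGAACUUGUG")
#' derive_scr_elements(mi, element_spec = list(c(2L, 7L)))
#' @export
derive_scr_elements <- function(mirnas, element_spec = NULL) {
  assert_cols(mirnas, c("name", "mature_seq", "seed_from", "seed_to"), "mirnas")
  purrr::pmap_dfr(mirnas, function(name, mature_seq, seed_from, seed_to, ...) {
    spans <- element_spec %||% default_element_spans(seed_from, seed_to)
    purrr::map_dfr(spans, function(sp) {
      s <- as.integer(sp[1]); e <- as.integer(sp[2])
      if (s < seed_from || e > seed_to || s >= e) {
        abort_data(sprintf(
          "element span %d-%d lies outside the %s seed span %d-%d.",
          s, e, name, seed_from, seed_to
        ))
      }
      sub <- substr(mature_seq, s, e)
      tibble(
        mirna = name,
        label = sprintf("m%d-%d", s, e),
        seed_start = s,
        seed_end = e,
        word = revcomp_dna(rna_to_dna(sub))
      )
    })
  })
}

#' Canonical SCR word (seed positions 2-7) per miRNA
#'
#' @param mirnas Tibble from [mirna_table()].
#' @return Named character vector of 6-mer DNA words, names = miRNA names.
#' @export
canonical_scr_words <- function(mirnas) {
  el <- derive_scr_elements(mirnas, element_spec = list(c(2L, 7L)))
  setNames(el$word, el$mirna)
}

#' Scan a 3'UTR universe for word occurrences
#'
#' Counts overlapping occurrences of each DNA word in each sequence (sliding
#' window; a 4-mer occurs 4 times in `"AAAAAAA"`). `N` bases never match.
#' Matching is case-insensitive: sequences are uppercased on ingestion.
#'
#' @param utrs Tibble with columns `gene_id`, `sequence` (DNA, A/C/G/T/N), or
#'   a named character vector.
#' @param words Character vector of uppercase DNA words, each at least 4 nt.
#' @return Tibble `gene_id`, `word`, `count`, `present` (one row per gene x
#'   word; `present = count > 0`).
#' @export
scan_occurrences <- function(utrs, words) {
  if (is.character(utrs) && !is.null(names(utrs))) {
    utrs <- tibble(gene_id = names(utrs), sequence = unname(utrs))
  }
  assert_cols(utrs, c("gene_id", "sequence"), "utrs")
  if (anyDuplicated(utrs$gene_id)) abort_data("gene_ids must be unique.")
  words <- toupper(words)
  if (length(words) == 0) abort_data("`words` must contain at least one word.")
  if (any(nchar(words) < 4) || any(grepl("[^ACGT]", words))) {
    abort_data("words must be uppercase DNA of length >= 4.")
  }
  if (nrow(utrs) == 0) {
    return(tibble(gene_id = character(), word = character(),
                  count = integer(), present = logical()))
  }
  seqs <- toupper(utrs$sequence)
  if (any(!nzchar(seqs))) abort_data("sequences must be non-empty.")
  subject <- Biostrings::DNAStringSet(seqs)
  purrr::map_dfr(unique(words), function(w) {
    cnt <- Biostrings::vcountPattern(w, subject, fixed = TRUE)
    tibble(gene_id = utrs$gene_id, word = w, count = cnt, present = cnt > 0L)
  })
}

#' Background presence rate of a word in the universe
#'
#' Fraction of universe genes whose 3'UTR contains the word at least once --
#' the background rate against which leading-edge enrichment is judged
#' (e.g. 2768 of 8706 genes carrying `TCAGGG` is 31.8%).
#'
#' @param occurrences Tibble from [scan_occurrences()].
#' @param word Single DNA word present in the index.
#' @param universe_size Number of genes in the universe; defaults to the
#'   number of distinct genes in `occurrences`.
#' @return One-row tibble: `word`, `n_present`, `universe_size`, `rate`
#'   (fraction) and `percent` (rate x 100).
#' @export
background_presence_rate <- function(occurrences, word, universe_size = NULL) {
  assert_cols(occurrences, c("gene_id", "word", "present"), "occurrences")
  word <- toupper(word)
  hits <- occurrences %>% filter(.data$word == !!word)
  if (nrow(hits) == 0) abort_data(sprintf("word %s is not in the occurrence index.", word))
  universe_size <- universe_size %||% n_distinct(occurrences$gene_id)
  if (universe_size <= 0) abort_data("universe_size must be positive.")
  n_present <- sum(hits$present)
  tibble(
    word = word,
    n_present = n_present,
    universe_size = as.integer(universe_size),
    rate = n_present / universe_size,
    percent = 100 * n_present / universe_size
  )
}
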