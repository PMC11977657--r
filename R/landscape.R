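# Binned hypergeometric enrichment landscapes, SSSS integration, and CPDV
# change-point cut selection.

#' Hypergeometric word-enrichment landscape over a ranked gene list
#'
#' At every bin boundary `k * bin_width` along the ranked list (rank 1 = most
#' downregulated), tests whether genes carrying each word are over- or
#' under-represented among the leading `n = k * bin_width` genes relative to
#' the whole list. With `N` genes in total, `K` of them carrying the word and
#' `x` carriers among the leading set, the enrichment p-value is
#' `P(X >= x)` and the depletion p-value `P(X <= x)` for
#' `X ~ Hypergeometric(N, K, n)`. The signed score is the smaller tail's
#' `-log10 p`, positive for enrichment in the leading (downregulated) set and
#' negative for depletion.
#'
#' @param ranked Ranked tibble with `gene_id` (and optionally `rank`, used to
#'   order if present) as produced by [collapse_and_rank()].
#' @param occurrences Occurrence index from [scan_occurrences()] covering
#'   every ranked gene.
#' @param words Words to profile; default all words in the index.
#' @param bin_width Genes per bin; default 200.
#' @param p_floor Lower bound applied to tail p-values before the log
#'   transform; default 1e-300.
#' @param min_count A gene counts as a carrier when its occurrence count is at
#'   least `min_count`; default 1 (binary presence).
#' @return A `scr_landscape` tibble: `bin`, `n_leading`, `word`, `x` (leading
#'   carriers), `K` (universe carriers), `enrich_p`, `deplete_p`,
#'   `signed_score`. Attributes: `bin_width`, `n_genes`.
#' @export
hypergeometric_landscape <- function(ranked, occurrences, words = NULL,
                                     bin_width = 200, p_floor = 1e-300,
                                     min_count = 1L) {
  assert_cols(ranked, "gene_id", "ranked")
  assert_cols(occurrences, c("gene_id", "word", "count"), "occurrences")
  if ("rank" %in% names(ranked)) ranked <- arrange(ranked, .data$rank)
  genes <- ranked$gene_id
  N <- length(genes)
  if (bin_width > N) abort_config("bin_width exceeds the ranked list length.")
  if (bin_width < 1) abort_config("bin_width must be at least 1.")
  words <- words %||% unique(occurrences$word)
  missing_words <- setdiff(words, occurrences$word)
  if (length(missing_words) > 0) {
    abort_data(sprintf("word(s) absent from the occurrence index: %s",
                       paste(missing_words, collapse = ", ")))
  }
  if (!all(genes %in% occurrences$gene_id)) {
    abort_data("every ranked gene must be present in the occurrence index.")
  }
  n_bins <- N %/% bin_width
  n_leading <- seq_len(n_bins) * bin_width
  out <- purrr::map_dfr(words, function(w) {
    cnt <- occurrences %>% filter(.data$word == !!w)
    cnt <- unname(setNames(cnt$count, cnt$gene_id)[genes])
    pres <- cnt >= min_count
    K <- sum(pres)
    x <- cumsum(pres)[n_leading]
    if (K == 0) {
      message(sprintf("word %s occurs in no ranked gene; landscape is flat zero.", w))
      return(tibble(
        bin = seq_len(n_bins), n_leading = n_leading, word = w,
        x = 0L, K = 0L, enrich_p = 1, deplete_p = 1, signed_score = 0
      ))
    }
    enrich_p <- phyper(x - 1, K, N - K, n_leading, lower.tail = FALSE)
    deplete_p <- phyper(x, K, N - K, n_leading, lower.tail = TRUE)
    score <- ifelse(
      enrich_p <= deplete_p,
      -log10(pmax(enrich_p, p_floor)),
      log10(pmax(deplete_p, p_floor))
    )
    tibble(
      bin = seq_len(n_bins), n_leading = n_leading, word = w,
      x = as.integer(x), K = as.integer(K),
      enrich_p = enrich_p, deplete_p = deplete_p, signed_score = score
    )
  })
  structure(out,
            class = c("scr_landscape", class(tibble())),
            bin_width = as.integer(bin_width), n_genes = N)
}

#' Integrate element landscapes into the single summed significance score
#'
#' The SSSS for a miRNA is, per bin, the sum of the signed `-log10 p` scores
#' across the miRNA's SCR element words (default six elements), giving one
#' curve per miRNA that summarises enrichment of the whole seed region. A
#' Fisher-combination alternative is available: the smaller-tail p-values of
#' the elements are combined by `-2 * sum(log p)` against a chi-squared
#' distribution with `2k` degrees of freedom and the combined `-log10 p`
#' takes the sign of the summed signed scores.
#'
#' @param landscape A `scr_landscape` from [hypergeometric_landscape()].
#' @param elements Element table from [derive_scr_elements()] (`mirna`,
#'   `word`).
#' @param method `"sum"` (default) or `"fisher"`.
#' @return A `scr_ssss` tibble: `mirna`, `bin`, `n_leading`, `ssss`.
#' @export
ssss_integration <- function(landscape, elements, method = c("sum", "fisher")) {
  method <- match.arg(method)
  assert_cols(landscape, c("bin", "n_leading", "word", "signed_score"), "landscape")
  assert_cols(elements, c("mirna", "word"), "elements")
  missing_words <- setdiff(elements$word, landscape$word)
  if (length(missing_words) > 0) {
    abort_data(sprintf("element word(s) missing from the landscape: %s",
                       paste(missing_words, collapse = ", ")))
  }
  joined <- elements %>%
    select("mirna", "word") %>%
    inner_join(as_tibble(landscape), by = "word",
               relationship = "many-to-many")
  out <- joined %>%
    group_by(.data$mirna, .data$bin, .data$n_leading) %>%
    summarise(
      ssss = if (method == "sum") {
        sum(.data$signed_score)
      } else {
        p_used <- pmin(.data$enrich_p, .data$deplete_p)
        stat <- -2 * sum(log(p_used))
        p_comb <- stats::pchisq(stat, df = 2 * length(p_used), lower.tail = FALSE)
        sign_comb <- if (sum(.data$signed_score) >= 0) 1 else -1
        sign_comb * -log10(max(p_comb, 1e-300))
      },
      .groups = "drop"
    ) %>%
    arrange(.data$mirna, .data$bin)
  structure(out,
            class = c("scr_ssss", class(tibble())),
            bin_width = attr(landscape, "bin_width"),
            n_genes = attr(landscape, "n_genes"),
            method = method)
}

#' Select a leading-edge cut by change-point delta value (CPDV)
#'
#' Progressing left to right along a per-bin `-log10 p`-scale curve, the CPDV
#' of bin `i` is its value minus the minimum value over the next `lookahead`
#' bins (window truncated at the end of the curve); the final bin, with an
#' empty window, gets `-Inf` and is never selected. The selected bin is the
#' CPDV argmax (first bin on ties); on a flat curve every CPDV is zero and bin
#' 1 is selected. The leading-edge gene count is `selected_bin * bin_width`:
#' with 200-gene bins, bin 7 cuts at the 1400 most downregulated genes.
#'
#' @param curve Numeric vector of per-bin values, or a `scr_ssss` /
#'   `scr_landscape`-style tibble holding a single curve in a value column.
#' @param lookahead Number of following bins the minimum is taken over;
#'   default 5.
#' @param bin_width Genes per bin; taken from the curve's attribute when
#'   available.
#' @param value_col Column holding the curve when `curve` is a data frame;
#'   guessed among `ssss`, `signed_score`, `value`.
#' @return A `scr_cutpoint` list: `table` (tibble `bin`, `value`, `cpdv`),
#'   `selected_bin`, `n_leading`, `lookahead`, `bin_width`.
#' @export
cpdv_select <- function(curve, lookahead = 5L, bin_width = NULL, value_col = NULL) {
  if (is.data.frame(curve)) {
    bin_width <- bin_width %||% attr(curve, "bin_width")
    value_col <- value_col %||% intersect(c("ssss", "signed_score", "value"),
                                          names(curve))[1]
    if (is.na(value_col) || is.null(value_col)) {
      abort_data("cannot locate the value column of `curve`.")
    }
    if ("mirna" %in% names(curve) && n_distinct(curve$mirna) > 1) {
      abort_data("`curve` holds several miRNAs; pass one curve at a time.")
    }
    if ("bin" %in% names(curve)) curve <- arrange(curve, .data$bin)
    values <- curve[[value_col]]
  } else {
    values <- as.numeric(curve)
  }
  n <- length(values)
  if (n < 2) abort_data("the curve must have at least 2 bins.")
  if (lookahead < 1) abort_config("lookahead must be at least 1.")
  cpdv <- vapply(seq_len(n), function(i) {
    if (i == n) return(-Inf)
    win <- values[(i + 1):min(i + lookahead, n)]
    values[i] - min(win)
  }, numeric(1))
  selected <- which.max(cpdv)
  structure(
    list(
      table = tibble(bin = seq_len(n), value = values, cpdv = cpdv),
      selected_bin = as.integer(selected),
      n_leading = if (!is.null(bin_width)) as.integer(selected * bin_width) else NA_integer_,
      lookahead = as.integer(lookahead),
      bin_width = if (!is.null(bin_width)) as.integer(bin_width) else NA_integer_
    ),
    class = "scr_cutpoint"
  )
}

#' @export
print.scr_cutpoint <- function(x, ...) {
  cat(sprintf(
    "<scr_cutpoint> selected bin %d (CPDV %.3f)%s, lookahead %d\n",
    x$selected_bin, x$table$cpdv[x$selected_bin],
    if (!is.na(x$n_leading)) sprintf(", leading edge %d genes", x$n_leading) else "",
    x$lookahead
  ))
  invisible(x)
}

#' @export
tidy.scr_cutpoint <- function(x, ...) x$table

#' @export
glance.scr_cutpoint <- function(x, ...) {
  tibble(
    selected_bin = x$selected_bin,
    n_leading = x$n_leading,
    cpdv = x$table$cpdv[x$selected_bin],
    lookahead = x$lookahead,
    bin_width = x$bin_width
  )
}
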