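# Small fixtures built in code and shared across test files.

make_detection_fixture <- function(seed = 3) {
  # 100 clear signal probes, 50 probes drawn from the control distribution,
  # 100 negative controls
  withr::with_seed(seed, {
    n_samp <- 4
    nc <- matrix(rnorm(100 * n_samp, 100, 10), nrow = 100)
    null_like <- matrix(rnorm(50 * n_samp, 100, 10), nrow = 50)
    signal <- matrix(rnorm(100 * n_samp, 200, 10), nrow = 100)
  })
  intensities <- rbind(signal, null_like, nc)
  expr <- tibble::as_tibble(as.data.frame(intensities))
  names(expr) <- sprintf("S%d", 1:4)
  expr <- dplyr::bind_cols(
    tibble::tibble(probe_id = c(sprintf("SIG%03d", 1:100),
                                sprintf("NUL%03d", 1:50),
                                sprintf("NEG%03d", 1:100))),
    expr
  )
  probe_info <- tibble::tibble(
    probe_id = expr$probe_id,
    is_negative_control = grepl("^NEG", expr$probe_id)
  )
  list(expr = expr, probe_info = probe_info)
}
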