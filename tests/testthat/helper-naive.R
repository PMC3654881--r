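# Independent naive maximal-primitive-tandem-run scan for plain strings.
# Third implementation, sharing no code with the engine or the brute-force
# oracle: direct substring comparison, divisor-free primitivity by rotation
# counting, contiguous copy counting.

naive_primitive <- function(f) {
  p <- nchar(f)
  # f is primitive iff all p rotations are distinct
  rots <- vapply(seq_len(p), function(s) {
    paste0(substr(f, s, p), substr(f, 1, s - 1))
  }, character(1))
  length(unique(rots)) == p
}

naive_tandem_scan <- function(s) {
  n <- nchar(s)
  rows <- list()
  for (p in seq_len(n %/% 2)) {
    for (i in seq_len(n - 2 * p + 1)) {
      f <- substr(s, i, i + p - 1)
      # maximal: no identical copy immediately to the left
      if (i - p >= 1 && substr(s, i - p, i - 1) == f) next
      if (!naive_primitive(f)) next
      l <- 1L
      while (i + (l + 1) * p - 1 <= n &&
        substr(s, i + l * p, i + (l + 1) * p - 1) == f) {
        l <- l + 1L
      }
      if (l >= 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = i, factor = f, copies = l, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, c(
    list(data.frame(start = integer(), factor = character(), copies = integer())),
    rows
  ))
  out[order(out$start, nchar(out$factor), out$factor), , drop = FALSE]
}

random_string <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# comparable plain data frame from a wtr_repeats tibble
repeats_key <- function(rs) {
  df <- data.frame(
    start = rs$start, factor = rs$factor, copies = rs$copies,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$start, nchar(df$factor), df$factor), , drop = FALSE]
  rownames(df) <- NULL
  df
}
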