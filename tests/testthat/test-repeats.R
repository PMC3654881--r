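mk_class <- function(factor, positions, probs = rep(1, length(positions))) {
  tibble::tibble(factor = factor, position = as.integer(positions), prob = probs)
}

test_that("detect_runs finds maximal arithmetic chains with difference p", {
  out <- detect_runs(mk_class("AT", c(1, 3, 5, 7)))
  expect_identical(out$start, 1L)
  expect_identical(out$copies, 4L)
  expect_identical(out$end, 8L)

  expect_identical(nrow(detect_runs(mk_class("GAT", c(1, 5)))), 0L)

  out <- detect_runs(mk_class("A", c(2, 3, 7, 8, 9)))
  expect_identical(out$start, c(2L, 7L))
  expect_identical(out$copies, c(2L, 3L))

  # interleaved overlapping occurrences must not break a chain:
  # AB occurring at 1,2,3 contains the tandem chains 1,3 and (singleton) 2
  out <- detect_runs(mk_class("AB", c(1, 2, 3), c(0.25, 0.25, 0.25)))
  expect_identical(out$start, 1L)
  expect_identical(out$copies, 2L)
})

test_that("is_primitive rejects powers of a shorter string", {
  expect_false(is_primitive("ATAT"))
  expect_true(is_primitive("AT"))
  expect_false(is_primitive("AAA"))
  expect_true(is_primitive("A"))
  expect_true(is_primitive("ATA"))
  expect_identical(is_primitive(c("ABCABC", "ABCAB")), c(FALSE, TRUE))
  expect_error(is_primitive(""), class = "wtr_value_error")
  # agrees with the oracle's rotation-based test on random strings
  set.seed(5)
  for (rep in 1:50) {
    f <- random_string(sample(1:8, 1), c("A", "B"))
    expect_identical(is_primitive(f), wtr:::oracle_primitive(f))
  }
})

test_that("assembled report keeps maximal primitive runs only", {
  rs <- find_tandem_repeats(wseq_from_string("ATATATAT"), 0.5)
  expect_true(any(rs$start == 1 & rs$factor == "AT" & rs$copies == 4))
  expect_false(any(rs$factor == "ATAT"))
  expect_true(any(rs$start == 2 & rs$factor == "TA" & rs$copies == 3))
  # sub-runs like (3, AT, 3) are not reported
  expect_identical(nrow(dplyr::filter(rs, factor == "AT")), 1L)

  expect_identical(repeats_key(find_tandem_repeats(wseq_from_string("AAC"), 0.5)),
    data.frame(start = 1L, factor = "A", copies = 2L))

  # the worked 5-position example agrees with the brute-force oracle
  X <- example_wseq()
  expect_identical(
    repeats_key(find_tandem_repeats(X, 0.3)),
    repeats_key(brute_force_tandem_repeats(X, 0.3))
  )
})

test_that("leftmost_only suppresses rotations nested in an earlier run", {
  rs <- find_tandem_repeats(wseq_from_string("ATATATAT"), 0.5, leftmost_only = TRUE)
  expect_identical(rs$factor, "AT")
  rs <- find_tandem_repeats(wseq_from_string("GGATATATATGG"), 0.5, leftmost_only = TRUE)
  expect_true(any(rs$factor == "G" & rs$copies == 2))
  expect_identical(dplyr::filter(rs, period == 2)$factor, "AT")
})

test_that("reported runs are maximal, tile without overlap, and meet the threshold", {
  set.seed(23)
  for (rep in 1:15) {
    ws <- simulate_wseq(24, max_chars_per_pos = 2)
    min_prob <- sample(c(0.1, 0.3), 1)
    rs <- find_tandem_repeats(ws, min_prob)
    expect_identical(anyDuplicated(paste(rs$start, rs$factor)), 0L)
    for (r in seq_len(nrow(rs))) {
      p <- rs$period[r]
      starts <- rs$start[r] + p * (seq_len(rs$copies[r]) - 1L)
      # copies tile contiguously: windows [s, s+p-1] abut exactly
      expect_identical(rs$end[r], rs$start[r] + rs$copies[r] * p - 1L)
      # every copy is a real factor at its own start
      for (s in starts) {
        expect_true(is_real_factor(ws, s, rs$factor[r], min_prob))
      }
      expect_equal(rs$copy_probs[[r]],
        vapply(starts, factor_weight, numeric(1), ws = ws, f = rs$factor[r]),
        tolerance = 1e-9)
      # maximality: one more period left or right fails occurrence or threshold
      left <- rs$start[r] - p
      if (left >= 1) {
        expect_false(is_real_factor(ws, left, rs$factor[r], min_prob))
      }
      right <- rs$start[r] + rs$copies[r] * p
      if (right + p - 1 <= wseq_n(ws)) {
        expect_false(is_real_factor(ws, right, rs$factor[r], min_prob))
      }
    }
  }
})

test_that("report writers emit the documented TSV and GFF3 layouts", {
  rs <- find_tandem_repeats(wseq_from_string("ATATATAT"), 0.5, leftmost_only = TRUE)
  lines <- write_repeats(rs)
  expect_identical(lines[1],
    "start\tend\tfactor\tperiod\tcopies\tmin_copy_prob\tcopy_probs")
  expect_identical(lines[2], "1\t8\tAT\t2\t4\t1.0\t1.0;1.0;1.0;1.0")

  expect_identical(write_repeats(find_tandem_repeats(wseq_from_string("AC"), 0.5)),
    "start\tend\tfactor\tperiod\tcopies\tmin_copy_prob\tcopy_probs")

  # two repeats sort by start then period
  rs <- find_tandem_repeats(wseq_from_string("AATAT"), 0.5)
  body <- write_repeats(rs)[-1]
  starts <- as.integer(vapply(strsplit(body, "\t"), `[[`, "", 1))
  expect_false(is.unsorted(starts))

  path <- tempfile(fileext = ".tsv")
  write_repeats(rs, path)
  back <- utils::read.delim(path)
  expect_identical(back$start, rs$start)
  expect_identical(back$factor, rs$factor)

  gff <- write_repeats_gff3(rs, seqid = "seq1")
  expect_identical(gff[1], "##gff-version 3")
  expect_identical(length(gff), nrow(rs) + 1L)
  fields <- strsplit(gff[2], "\t")[[1]]
  expect_identical(length(fields), 9L)
  expect_identical(fields[3], "tandem_repeat")
  expect_match(fields[9], "^factor=")
})

test_that("glance summarises a repeat report", {
  g <- glance(find_tandem_repeats(wseq_from_string("ATATATAT"), 0.5))
  expect_identical(g$n_repeats, 2L)
  expect_identical(g$max_copies, 4L)
  expect_identical(g$max_period, 2L)
  g0 <- glance(find_tandem_repeats(wseq_from_string("AC"), 0.5))
  expect_identical(g0$n_repeats, 0L)
})

test_that("autoplot returns ggplot objects for sequences and reports", {
  expect_s3_class(ggplot2::autoplot(example_wseq()), "ggplot")
  expect_s3_class(
    ggplot2::autoplot(find_tandem_repeats(wseq_from_string("ATATATAT"), 0.5)),
    "ggplot"
  )
  expect_s3_class(
    ggplot2::autoplot(find_tandem_repeats(wseq_from_string("AC"), 0.5)),
    "ggplot"
  )
})
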