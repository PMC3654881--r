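#' Find all tandem repeats in a weighted sequence
#'
#' A tandem repeat is a triple (start, factor, copies): `copies` >= 2 adjacent,
#' non-overlapping occurrences of `factor`, spaced exactly its length apart,
#' each with cumulative probability at least `min_prob`. The engine builds the
#' stage-1 partition of occurrence positions, iteratively refines it one
#' character at a time up to period `floor(n/2)`, and scans every class's
#' ordered occurrence list for maximal arithmetic chains whose common
#' difference equals the factor length. Only maximal runs of primitive factors
#' are reported: a run of a non-primitive factor g^m is always subsumed by the
#' run of its primitive root g.
#'
#' Rotated runs (e.g. (2, TA, 3) inside ATATATAT alongside (1, AT, 4)) are
#' distinct factors' maximal runs and are reported; `leftmost_only = TRUE`
#' suppresses a run that lies inside an earlier-starting run of the same
#' period.
#'
#' @param ws A `wseq` object.
#' @param min_prob Probability threshold in (0, 1\] (the model's 1/k): every
#'   copy of a reported repeat individually meets it.
#' @param max_period Largest factor length to consider; defaults to
#'   `floor(n/2)` and is capped there.
#' @param leftmost_only Suppress runs contained in an earlier run of the same
#'   period (rotations).
#' @param max_classes Abort if a refinement stage would create more candidate
#'   classes than this (see [refine_partition()]).
#' @return A `wtr_repeats` tibble sorted by (start, period, factor) with
#'   columns `start`, `end` (1-based inclusive), `factor`, `period`, `copies`,
#'   `min_copy_prob` and a list column `copy_probs` holding the cumulative
#'   probability of each copy.
#' @examples
#' find_tandem_repeats(wseq_from_string("ATATATAT"), min_prob = 0.5)
#' @export
find_tandem_repeats <- function(ws, min_prob, max_period = NULL,
                                leftmost_only = FALSE, max_classes = 1e6) {
  stopifnot(inherits(ws, "wseq"), is.numeric(min_prob), min_prob > 0)
  n <- wseq_n(ws)
  maxp <- n %/% 2L
  if (!is.null(max_period)) {
    stopifnot(max_period >= 1)
    maxp <- min(maxp, as.integer(max_period))
  }
  runs <- list()
  state <- build_e1(ws, min_prob)
  while (nrow(state) > 0 && partition_p(state) <= maxp) {
    runs[[length(runs) + 1L]] <- detect_runs(state)
    if (isTRUE(getOption("wtr.verbose"))) {
      rlang::inform(sprintf(
        "stage p = %d: %d class(es), %d occurrence(s), %d run(s)",
        partition_p(state), dplyr::n_distinct(state$factor), nrow(state),
        nrow(runs[[length(runs)]])
      ))
    }
    if (partition_p(state) == maxp) break
    state <- refine_partition(ws, state, min_prob, max_classes = max_classes)
  }
  res <- dplyr::bind_rows(c(list(empty_repeats()), runs))
  res <- dplyr::filter(res, is_primitive(.data$factor))
  res <- dplyr::distinct(res, .data$start, .data$factor, .keep_all = TRUE)
  res <- dplyr::arrange(res, .data$start, .data$period, .data$factor)
  if (leftmost_only) {
    res <- drop_rotations(res)
  }
  new_repeats(res, n = n, min_prob = min_prob)
}

#' Detect tandem runs inside equivalence classes
#'
#' Scans each class's strictly increasing occurrence list for maximal
#' arithmetic chains with common difference exactly the factor length p. Each
#' chain of l >= 2 positions is one tandem run of l copies; chains of length 1
#' yield nothing. Chains are tracked within each residue class of position mod
#' p: in a weighted sequence a factor may also occur at positions that overlap
#' a run's copies, and such interleaved occurrences must not break the chain
#' (on plain strings a primitive factor cannot interleave its own tandem
#' copies, so there this reduces to plain adjacent-gap scanning). Because a
#' class holds every qualifying occurrence of its factor, chain maximality is
#' run maximality.
#'
#' @param cls A tibble with columns `factor`, `position`, `prob`: one class or
#'   a whole partition state.
#' @return A tibble of runs (same columns as [find_tandem_repeats()]), without
#'   the primitivity filter.
#' @export
detect_runs <- function(cls) {
  tbl <- tibble::as_tibble(as.data.frame(cls))
  if (nrow(tbl) == 0) {
    return(empty_repeats())
  }
  tbl <- dplyr::mutate(tbl, .res = .data$position %% nchar(.data$factor))
  tbl <- dplyr::arrange(tbl, .data$factor, .data$.res, .data$position)
  tbl <- dplyr::group_by(tbl, .data$factor, .data$.res)
  tbl <- dplyr::mutate(tbl,
    .gap = .data$position - dplyr::lag(.data$position),
    .chain = cumsum(is.na(.data$.gap) | .data$.gap != nchar(.data$factor))
  )
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$factor, .data$.res, .data$.chain),
    start = .data$position[[1]],
    copies = dplyr::n(),
    copy_probs = list(.data$prob),
    min_copy_prob = min(.data$prob),
    .groups = "drop"
  )
  out <- dplyr::filter(out, .data$copies >= 2L)
  out <- dplyr::mutate(out,
    start = as.integer(.data$start),
    copies = as.integer(.data$copies),
    period = nchar(.data$factor),
    end = .data$start + .data$copies * .data$period - 1L
  )
  out <- dplyr::select(out, "start", "end", "factor", "period", "copies",
    "min_copy_prob", "copy_probs")
  dplyr::arrange(out, .data$start, .data$period, .data$factor)
}

#' Is a string primitive?
#'
#' A string is primitive when it is not a smaller string repeated m >= 2
#' times. Non-primitive factors are filtered from repeat reports: if f = g^m
#' tandemly repeats with every copy above threshold, every g-copy's weight is
#' at least the containing f-copy's weight, so the primitive root's run is
#' always reported instead and nothing is lost.
#'
#' @param f Character vector of non-empty strings.
#' @return Logical vector.
#' @examples
#' is_primitive(c("AT", "ATAT", "AAA"))
#' @export
is_primitive <- function(f) {
  if (any(!nzchar(f))) {
    rlang::abort("empty string has no primitive root", class = "wtr_value_error")
  }
  vapply(f, function(s) {
    p <- nchar(s)
    if (p == 1L) {
      return(TRUE)
    }
    for (d in seq_len(p %/% 2L)) {
      if (p %% d == 0L && strrep(substr(s, 1L, d), p %/% d) == s) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

empty_repeats <- function() {
  tibble::tibble(
    start = integer(), end = integer(), factor = character(),
    period = integer(), copies = integer(),
    min_copy_prob = double(), copy_probs = list()
  )
}

new_repeats <- function(tbl, n = NA_integer_, min_prob = NA_real_) {
  structure(tbl, wseq_n = n, min_prob = min_prob,
    class = c("wtr_repeats", class(tibble::tibble())))
}

#' @export
print.wtr_repeats <- function(x, ...) {
  cat(sprintf(
    "# Tandem repeats: %d run(s)%s\n", nrow(x),
    if (!is.na(attr(x, "wseq_n", exact = TRUE) %||% NA)) {
      sprintf(" in a weighted sequence of length %d (min_prob = %g)",
        attr(x, "wseq_n", exact = TRUE), attr(x, "min_prob", exact = TRUE))
    } else ""
  ))
  NextMethod()
}

# suppress runs contained in an earlier-starting run of the same period
drop_rotations <- function(res) {
  if (nrow(res) < 2) {
    return(res)
  }
  keep <- rep(TRUE, nrow(res))
  for (r in seq_len(nrow(res))) {
    contained <- res$period == res$period[r] &
      res$start < res$start[r] &
      res$start + res$period > res$start[r] &
      res$end >= res$end[r] - res$period + 1L
    if (any(contained & keep)) keep[r] <- FALSE
  }
  res[keep, ]
}

#' Write a repeat report as TSV or GFF3
#'
#' `write_repeats()` writes a TSV with header
#' `start end factor period copies min_copy_prob copy_probs` (copy
#' probabilities joined with `;`), `end` being 1-based inclusive.
#' `write_repeats_gff3()` emits one `tandem_repeat` feature per run with
#' `factor`, `copies` and `copy_probs` attributes for genome-browser use.
#'
#' @param rs A `wtr_repeats` tibble.
#' @param path Output path, or `NULL` to return the lines invisibly unwritten.
#' @param seqid Sequence name used in the GFF3 first column.
#' @return Invisibly, the formatted lines.
#' @export
write_repeats <- function(rs, path = NULL) {
  header <- paste(c("start", "end", "factor", "period", "copies",
    "min_copy_prob", "copy_probs"), collapse = "\t")
  body <- if (nrow(rs) == 0) character() else {
    vapply(seq_len(nrow(rs)), function(r) {
      paste(
        rs$start[r], rs$end[r], rs$factor[r], rs$period[r], rs$copies[r],
        format_prob(rs$min_copy_prob[r]),
        paste(format_prob(rs$copy_probs[[r]]), collapse = ";"),
        sep = "\t"
      )
    }, character(1))
  }
  lines <- c(header, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_repeats
#' @export
write_repeats_gff3 <- function(rs, path = NULL, seqid = "wseq") {
  body <- if (nrow(rs) == 0) character() else {
    vapply(seq_len(nrow(rs)), function(r) {
      paste(
        seqid, "wtr", "tandem_repeat", rs$start[r], rs$end[r],
        format_prob(rs$min_copy_prob[r]), ".", ".",
        sprintf("factor=%s;copies=%d;copy_probs=%s",
          rs$factor[r], rs$copies[r],
          paste(format_prob(rs$copy_probs[[r]]), collapse = ",")),
        sep = "\t"
      )
    }, character(1))
  }
  lines <- c("##gff-version 3", body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Summarise a repeat report
#'
#' @param x A `wtr_repeats` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of runs, distinct factors, largest period,
#'   largest copy number, and the smallest per-copy probability seen.
#' @method glance wtr_repeats
#' @export
glance.wtr_repeats <- function(x, ...) {
  tibble::tibble(
    n_repeats = nrow(x),
    n_factors = dplyr::n_distinct(x$factor),
    max_period = if (nrow(x)) max(x$period) else NA_integer_,
    max_copies = if (nrow(x)) max(x$copies) else NA_integer_,
    min_copy_prob = if (nrow(x)) min(x$min_copy_prob) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
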