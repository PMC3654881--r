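#' Read and write the .wseq text format
#'
#' The `.wseq` format is a TSV with one position per line:
#' `<1-based index><TAB><char>:<prob>[,<char>:<prob>...]`, lines sorted by
#' index. Lines starting with `#` are comments; blank lines are ignored.
#' Probabilities are decimal literals; characters with probability 0 are
#' dropped on read; per-position sums are validated against a 1e-6 tolerance
#' and out-of-tolerance input is rejected (weights are never silently
#' renormalised, since downstream thresholds depend on absolute values).
#'
#' @param path Path to a `.wseq` file (`read_wseq`) or output path
#'   (`write_wseq`).
#' @param text Optional character vector of lines, used instead of `path`.
#' @param ws A `wseq` object.
#' @return `read_wseq()` returns a validated `wseq`. `write_wseq()` invisibly
#'   returns `path`; `format_wseq()` returns the lines as a character vector.
#'   Writing is an exact inverse of reading up to 1e-9 per weight.
#' @examples
#' lines <- format_wseq(example_wseq())
#' identical(wseq_n(read_wseq(text = lines)), 5L)
#' @export
read_wseq <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) {
    rlang::abort("no positions found in .wseq input", class = "wtr_parse_error")
  }
  rows <- lapply(keep, function(ln) parse_wseq_line(lines[[ln]], ln))
  tbl <- dplyr::bind_rows(rows)
  if (is.unsorted(unique(tbl$position))) {
    rlang::abort("positions must appear in increasing order",
      class = "wtr_parse_error")
  }
  weighted_sequence(tbl)
}

parse_wseq_line <- function(line, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !grepl("^[0-9]+$", parts[[1]])) {
    rlang::abort(
      sprintf("line %d: expected '<index>\\t<char>:<prob>,...', got %s",
        lineno, deparse(line)),
      class = "wtr_parse_error"
    )
  }
  pos <- as.integer(parts[[1]])
  entries <- strsplit(parts[[2]], ",", fixed = TRUE)[[1]]
  ok <- grepl("^.:[0-9.eE+-]+$", entries)
  probs <- suppressWarnings(as.numeric(sub("^.:", "", entries)))
  if (length(entries) == 0 || any(!ok) || anyNA(probs)) {
    rlang::abort(sprintf("line %d: malformed char:prob entry", lineno),
      class = "wtr_parse_error")
  }
  tibble::tibble(
    position = pos,
    char = substr(entries, 1L, 1L),
    prob = probs
  )
}

#' @rdname read_wseq
#' @export
write_wseq <- function(ws, path) {
  writeLines(format_wseq(ws), path)
  invisible(path)
}

#' @rdname read_wseq
#' @export
format_wseq <- function(ws) {
  stopifnot(inherits(ws, "wseq"))
  by_pos <- split(ws, ws$position)
  vapply(by_pos, function(d) {
    paste0(
      d$position[[1]], "\t",
      paste0(d$char, ":", format_prob(d$prob), collapse = ",")
    )
  }, character(1), USE.NAMES = FALSE)
}

# decimal literal that always shows a decimal point (weight-1 chars stay explicit)
format_prob <- function(p) {
  out <- vapply(p, function(x) sprintf("%.12g", x), character(1))
  plain <- !grepl("[.e]", out)
  out[plain] <- paste0(out[plain], ".0")
  out
}

#' Convert a multiple sequence alignment to a weighted sequence
#'
#' Each alignment column becomes one weighted position: the weight of a
#' character is its count in the column divided by the number of non-gap
#' symbols there. The gap character `-` never enters the alphabet; a column of
#' only gaps is an error. This column-frequency rule is the package's own
#' convention for compressing an alignment into a probability profile.
#'
#' @param alignment Character vector of aligned rows (equal lengths, gaps as
#'   `-`), or a named character vector as returned by [read_msa()].
#' @return A `wseq` whose length equals the alignment width.
#' @examples
#' msa_to_wseq(c("A-", "AC", "AC"))
#' @export
msa_to_wseq <- function(alignment) {
  alignment <- as.character(alignment)
  if (length(alignment) < 1L) {
    rlang::abort("alignment needs at least one row", class = "wtr_validation_error")
  }
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) {
    rlang::abort("alignment rows have unequal lengths", class = "wtr_shape_error")
  }
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  cols <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0) {
      rlang::abort(sprintf("alignment column %d contains only gaps", j),
        class = "wtr_validation_error")
    }
    counts <- table(col)
    tibble::tibble(
      position = j,
      char = names(counts),
      prob = as.numeric(counts) / length(col)
    )
  })
  weighted_sequence(dplyr::bind_rows(cols))
}

#' Read a pre-aligned multi-FASTA file
#'
#' @param path Path to a FASTA file of equal-length aligned sequences.
#' @return A named character vector of rows, suitable for [msa_to_wseq()].
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Tidy a weighted sequence into a plain tibble
#'
#' @param x A `wseq` object.
#' @param ... Unused.
#' @return A tibble with columns `position`, `char`, `prob` and no extra
#'   attributes.
#' @method tidy wseq
#' @export
tidy.wseq <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}
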