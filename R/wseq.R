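#' Weighted sequences
#'
#' A weighted sequence X\[1, n\] is a sequence of n positions where each position
#' holds a probability distribution over the characters of an alphabet, rather
#' than a single character. `weighted_sequence()` builds one from a long tibble
#' with one row per (position, character) pair carrying a positive probability;
#' per-position probabilities must sum to 1 (tolerance 1e-6). Characters with
#' probability zero are simply absent.
#'
#' @param x A data frame with columns `position` (1-based integer, every index
#'   from 1 to n present at least once), `char` (single-character string) and
#'   `prob` (probability in (0, 1\]).
#' @return A `wseq` object: a tibble sorted by (position, char) with attributes
#'   `n` (length) and `alphabet` (sorted character vector of all characters
#'   occurring with positive probability).
#' @examples
#' ws <- weighted_sequence(tibble::tibble(
#'   position = c(1L, 1L, 2L),
#'   char = c("A", "C", "G"),
#'   prob = c(0.5, 0.5, 1)
#' ))
#' wseq_n(ws)
#' @export
weighted_sequence <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("position", "char", "prob")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "`x` must have columns position, char, prob; missing: ",
      paste(missing_cols, collapse = ", ")
    ), class = "wtr_validation_error")
  }
  x <- dplyr::select(x, dplyr::all_of(required))
  x$position <- as.integer(x$position)
  x$prob <- as.double(x$prob)
  validate_wseq_tbl(x)
  # zero-weight characters are not stored: "occurs" means prob > 0
  x <- dplyr::filter(x, .data$prob > 0)
  x <- dplyr::arrange(x, .data$position, .data$char)
  new_wseq(x)
}

new_wseq <- function(x) {
  structure(
    x,
    n = max(x$position),
    alphabet = sort(unique(x$char)),
    class = c("wseq", class(tibble::tibble()))
  )
}

validate_wseq_tbl <- function(x, tol = 1e-6) {
  if (nrow(x) == 0) {
    rlang::abort("a weighted sequence needs at least one position",
      class = "wtr_validation_error")
  }
  if (anyNA(x$position) || anyNA(x$char) || anyNA(x$prob)) {
    rlang::abort("missing values in position/char/prob",
      class = "wtr_validation_error")
  }
  if (any(x$prob < 0)) {
    rlang::abort("negative probability", class = "wtr_validation_error")
  }
  if (any(x$prob > 1 + tol)) {
    rlang::abort("probability greater than 1", class = "wtr_validation_error")
  }
  if (any(nchar(x$char) != 1L)) {
    rlang::abort("`char` entries must be single characters",
      class = "wtr_validation_error")
  }
  n <- max(x$position)
  if (min(x$position) < 1L) {
    rlang::abort("positions must be >= 1", class = "wtr_validation_error")
  }
  got <- sort(unique(x$position))
  if (length(got) != n || any(got != seq_len(n))) {
    rlang::abort("every position 1..n must carry a distribution",
      class = "wtr_validation_error")
  }
  if (anyDuplicated(x[c("position", "char")]) > 0) {
    rlang::abort("duplicate (position, char) pair", class = "wtr_validation_error")
  }
  sums <- tapply(x$prob, x$position, sum)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf(
        "per-position probabilities must sum to 1 (tolerance %g); position %s sums to %.8f",
        tol, names(sums)[bad[1]], sums[bad[1]]
      ),
      class = "wtr_validation_error"
    )
  }
  invisible(x)
}

#' @export
print.wseq <- function(x, ...) {
  cat(sprintf(
    "# A weighted sequence: n = %d, alphabet = {%s}\n",
    wseq_n(x), paste(wseq_alphabet(x), collapse = ",")
  ))
  NextMethod()
}

#' Length and alphabet of a weighted sequence
#'
#' @param ws A `wseq` object.
#' @return `wseq_n()`: the number of positions n. `wseq_alphabet()`: the sorted
#'   character vector of symbols with positive weight anywhere in the sequence.
#' @export
wseq_n <- function(ws) {
  attr(ws, "n", exact = TRUE) %||% max(ws$position)
}

#' @rdname wseq_n
#' @export
wseq_alphabet <- function(ws) {
  attr(ws, "alphabet", exact = TRUE) %||% sort(unique(ws$char))
}

#' Build a deterministic weighted sequence from a plain string
#'
#' Every position gets a single character with probability 1, so thresholded
#' analyses reduce to ordinary (non-weighted) string analyses.
#'
#' @param s A single non-empty string.
#' @return A `wseq` object of length `nchar(s)`.
#' @examples
#' ws <- wseq_from_string("ATATATAT")
#' factor_weight(ws, 1, "ATAT")
#' @export
wseq_from_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nchar(s) >= 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  weighted_sequence(tibble::tibble(
    position = seq_along(chars),
    char = chars,
    prob = 1
  ))
}

#' The five-position worked-example weighted sequence
#'
#' A small DNA weighted sequence used throughout the documentation and tests:
#' position 1 is \{A:0.5, C:0.25, G:0.25\}, position 2 is \{G:1\}, position 3 is
#' \{A:0.6, C:0.4\}, position 4 is uniform over \{A,C,G,T\}, and position 5 is
#' \{C:1\}. With threshold 0.3, AGA is a real factor at position 1
#' (0.5 x 1 x 0.6 = 0.3) while CAC at position 3 is not (0.4 x 0.25 x 1 = 0.1).
#'
#' @return A `wseq` object with n = 5 and alphabet \{A,C,G,T\}.
#' @examples
#' factor_weight(example_wseq(), 2, "GAT")
#' @export
example_wseq <- function() {
  weighted_sequence(tibble::tibble(
    position = c(1L, 1L, 1L, 2L, 3L, 3L, 4L, 4L, 4L, 4L, 5L),
    char = c("A", "C", "G", "G", "A", "C", "A", "C", "G", "T", "C"),
    prob = c(0.5, 0.25, 0.25, 1, 0.6, 0.4, 0.25, 0.25, 0.25, 0.25, 1)
  ))
}

#' Character and factor weights
#'
#' `char_weight()` returns the probability of character `c` at position `i`
#' (0 if absent). `factor_weight()` returns the cumulative weight of a factor
#' `f` anchored at position `i`: the product of the per-position character
#' probabilities along `f`. `is_real_factor()` tests whether that cumulative
#' weight reaches the threshold `min_prob` (the model's 1/k),
#' using a small absolute guard (1e-12) so exact-boundary products are not lost
#' to floating-point rounding.
#'
#' @param ws A `wseq` object.
#' @param i 1-based anchor position.
#' @param c A single character.
#' @param f A factor (plain string); the empty string has weight 1.
#' @param min_prob Probability threshold in (0, 1\].
#' @return `char_weight()` and `factor_weight()` return a probability in
#'   \[0, 1\]; `is_real_factor()` returns a logical.
#' @examples
#' X <- example_wseq()
#' factor_weight(X, 2, "GAT") # 1 * 0.6 * 0.25 = 0.15
#' is_real_factor(X, 1, "AGA", min_prob = 0.3) # 0.3 >= 0.3
#' @export
char_weight <- function(ws, i, c) {
  i <- as.integer(i)
  n <- wseq_n(ws)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n) {
    rlang::abort(sprintf("position %s out of range [1, %d]", i, n),
      class = "wtr_index_error")
  }
  hit <- ws$prob[ws$position == i & ws$char == c]
  if (length(hit) == 0) 0 else hit[[1]]
}

#' @rdname char_weight
#' @export
factor_weight <- function(ws, i, f) {
  i <- as.integer(i)
  stopifnot(length(i) == 1L, length(f) == 1L, is.character(f))
  n <- wseq_n(ws)
  m <- nchar(f)
  if (i < 1L || i > n) {
    rlang::abort(sprintf("position %d out of range [1, %d]", i, n),
      class = "wtr_index_error")
  }
  if (m == 0L) {
    return(1)
  }
  if (i + m - 1L > n) {
    rlang::abort(
      sprintf("factor of length %d at position %d overruns sequence end (n = %d)", m, i, n),
      class = "wtr_index_error"
    )
  }
  chars <- strsplit(f, "", fixed = TRUE)[[1]]
  idx <- match(
    paste(i + seq_len(m) - 1L, chars),
    paste(ws$position, ws$char)
  )
  if (anyNA(idx)) {
    return(0)
  }
  prod(ws$prob[idx])
}

#' @rdname char_weight
#' @export
is_real_factor <- function(ws, i, f, min_prob) {
  stopifnot(is.numeric(min_prob), length(min_prob) == 1L, min_prob > 0)
  factor_weight(ws, i, f) >= min_prob - 1e-12
}

#' @importFrom rlang %||% .data
NULL
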