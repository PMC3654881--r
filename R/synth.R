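#' Simulate a random weighted sequence
#'
#' Each position independently draws between 1 and `max_chars_per_pos` distinct
#' characters and a probability vector over them from a symmetric Dirichlet
#' with concentration `concentration` (1 = flat over the simplex; large values
#' give near-uniform weights, small values near-deterministic positions). This
#' emulates the profile-like weighted sequences obtained from multiple
#' alignments: most positions are dominated by one residue, with a minority of
#' genuinely ambiguous columns.
#'
#' @param n Sequence length (>= 1).
#' @param alphabet Character vector of symbols (default DNA).
#' @param max_chars_per_pos Largest number of distinct characters per position
#'   (1 gives a deterministic sequence, all weights 1).
#' @param concentration Positive Dirichlet concentration parameter.
#' @param seed Optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return A `wseq` object of length `n`.
#' @examples
#' simulate_wseq(10, seed = 42)
#' @export
simulate_wseq <- function(n, alphabet = c("A", "C", "G", "T"),
                          max_chars_per_pos = 2, concentration = 1,
                          seed = NULL) {
  stopifnot(
    n >= 1, length(alphabet) >= 1,
    max_chars_per_pos >= 1, max_chars_per_pos <= length(alphabet),
    concentration > 0
  )
  local_seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    k <- sample.int(max_chars_per_pos, 1L)
    chars <- sort(sample(alphabet, k))
    w <- dirichlet1(k, concentration)
    tibble::tibble(position = i, char = chars, prob = w)
  })
  weighted_sequence(dplyr::bind_rows(rows))
}

# one draw from a symmetric Dirichlet, redrawing the (measure-zero, but
# floating-point-possible) degenerate cases so every stored weight is > 0
dirichlet1 <- function(k, concentration) {
  if (k == 1L) {
    return(1)
  }
  repeat {
    g <- stats::rgamma(k, shape = concentration)
    s <- sum(g)
    if (s > 0 && all(g / s > 1e-9)) {
      return(g / s)
    }
  }
}

local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) {
    return(invisible())
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  withr::defer(
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    },
    envir = env
  )
  set.seed(seed)
  invisible()
}

#' Plant a tandem repeat into a weighted sequence
#'
#' Overwrites the window `start .. start + copies * nchar(factor) - 1` so that
#' each character of each copy carries weight `copy_prob^(1/nchar(factor))`,
#' making every copy's cumulative weight exactly `copy_prob`; the residual
#' mass at each position is spread evenly over the remaining alphabet
#' characters. By construction [find_tandem_repeats()] recovers a run of the
#' planted factor covering the window whenever `copy_prob >= min_prob` (for a
#' non-primitive factor, the run reported is its primitive root's).
#'
#' @param ws A `wseq` object.
#' @param factor The factor to plant (plain string over the sequence
#'   alphabet).
#' @param start 1-based start of the first copy.
#' @param copies Number of adjacent copies (>= 2).
#' @param copy_prob Target cumulative weight of each copy, in (0, 1\].
#' @return A new `wseq` with the window overwritten.
#' @examples
#' ws <- plant_tandem_repeat(simulate_wseq(20, seed = 1), "AG", 3, 4, 0.49)
#' find_tandem_repeats(ws, min_prob = 0.49)
#' @export
plant_tandem_repeat <- function(ws, factor, start, copies, copy_prob) {
  p <- nchar(factor)
  n <- wseq_n(ws)
  stopifnot(p >= 1, copies >= 2, copy_prob > 0, copy_prob <= 1, start >= 1)
  if (start + copies * p - 1L > n) {
    rlang::abort(
      sprintf("planted window [%d, %d] overruns sequence end (n = %d)",
        start, start + copies * p - 1L, n),
      class = "wtr_index_error"
    )
  }
  alphabet <- union(wseq_alphabet(ws), strsplit(factor, "", fixed = TRUE)[[1]])
  w <- copy_prob^(1 / p)
  if (w < 1 && length(alphabet) < 2L) {
    rlang::abort("need at least two alphabet characters to spread residual mass",
      class = "wtr_validation_error")
  }
  chars <- strsplit(factor, "", fixed = TRUE)[[1]]
  window <- lapply(seq_len(copies * p) - 1L, function(off) {
    pos <- start + off
    ch <- chars[[off %% p + 1L]]
    if (w >= 1) {
      tibble::tibble(position = pos, char = ch, prob = 1)
    } else {
      others <- setdiff(alphabet, ch)
      tibble::tibble(
        position = pos,
        char = c(ch, others),
        prob = c(w, rep((1 - w) / length(others), length(others)))
      )
    }
  })
  rest <- dplyr::filter(
    tidy(ws),
    .data$position < start | .data$position > start + copies * p - 1L
  )
  weighted_sequence(dplyr::bind_rows(c(list(rest), window)))
}
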