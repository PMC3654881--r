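# Equivalence-class partitioning over a weighted sequence.
#
# A stage-p partition state holds, for every length-p factor f that is a real
# factor somewhere, the ordered list of (position, probability) pairs where it
# occurs with probability >= min_prob. States are plain tibbles with columns
# (factor, position, prob) and an attribute `p`; classes are the per-factor
# groups. Refining a state extends every occurrence one character to the right
# and regroups by the appended character, so the stage-p work is proportional
# to the number of surviving occurrences.

PROB_EPS <- 1e-12

new_partition <- function(tbl, p) {
  tbl <- dplyr::arrange(tbl, .data$factor, .data$position)
  structure(tbl, p = as.integer(p),
    class = c("wtr_partition", class(tibble::tibble())))
}

#' Stage of a partition state
#'
#' @param state A `wtr_partition` object.
#' @return The common factor length p of the state's classes.
#' @export
partition_p <- function(state) attr(state, "p", exact = TRUE)

#' @export
print.wtr_partition <- function(x, ...) {
  cat(sprintf(
    "# Partition state at p = %d: %d class(es), %d occurrence(s)\n",
    partition_p(x), dplyr::n_distinct(x$factor), nrow(x)
  ))
  NextMethod()
}

#' Build the stage-1 partition
#'
#' For every alphabet character, the class of all positions where that
#' character occurs with probability at least `min_prob`, in increasing
#' position order. Classes with fewer than two occurrences are pruned: a
#' tandem repeat needs at least two copies and refinement only shrinks
#' classes, so singletons can never contribute.
#'
#' @param ws A `wseq` object.
#' @param min_prob Probability threshold (the model's 1/k).
#' @return A `wtr_partition` at p = 1 with columns `factor`, `position`,
#'   `prob`.
#' @examples
#' build_e1(example_wseq(), min_prob = 0.3)
#' @export
build_e1 <- function(ws, min_prob) {
  stopifnot(inherits(ws, "wseq"), is.numeric(min_prob), min_prob > 0)
  tbl <- tibble::tibble(
    factor = ws$char,
    position = ws$position,
    prob = ws$prob
  )
  tbl <- dplyr::filter(tbl, .data$prob >= min_prob - PROB_EPS)
  new_partition(prune_singletons(tbl), p = 1L)
}

prune_singletons <- function(tbl) {
  dplyr::filter(dplyr::group_by(tbl, .data$factor), dplyr::n() >= 2L) |>
    dplyr::ungroup()
}

# Core extension step shared by extend_class() and refine_partition().
# tbl: occurrences of length-p factors; returns length-(p+1) candidates with
# incremental probabilities, occurrences below threshold or overrunning the
# sequence end dropped, singleton candidate classes pruned.
extend_occurrences <- function(ws, tbl, p, min_prob, max_classes = Inf) {
  if (nrow(tbl) == 0) {
    return(tbl[0, ])
  }
  ext <- dplyr::inner_join(
    dplyr::mutate(tbl, .ext = .data$position + p),
    tibble::as_tibble(as.data.frame(ws)),
    by = c(".ext" = "position"),
    suffix = c("", ".char"),
    relationship = "many-to-many"
  )
  ext <- dplyr::mutate(ext, prob = .data$prob * .data$prob.char)
  ext <- dplyr::filter(ext, .data$prob >= min_prob - PROB_EPS)
  if (nrow(ext) > 0) {
    # lexicographic order of the appended character gives deterministic output
    ext <- dplyr::mutate(ext, factor = paste0(.data$factor, .data$char))
    n_classes <- dplyr::n_distinct(ext$factor)
    if (n_classes > max_classes) {
      rlang::abort(
        sprintf("class cap exceeded at p = %d: %d candidate classes > max_classes = %g",
          p + 1L, n_classes, max_classes),
        class = "wtr_class_cap_error"
      )
    }
  }
  prune_singletons(dplyr::select(ext, "factor", "position", "prob"))
}

#' Extend one equivalence class by one character
#'
#' Takes the class of a length-(p-1) factor f and produces, for every alphabet
#' character s, the candidate class of fs containing each occurrence i of f
#' whose extended product prob(i) * weight of s at position i + p - 1 still
#' meets `min_prob`. Occurrences whose window would overrun the sequence end
#' are dropped; candidate classes with fewer than two occurrences are
#' discarded.
#'
#' @param ws A `wseq` object.
#' @param cls A tibble with columns `factor`, `position`, `prob` holding one
#'   class (a single factor string).
#' @param min_prob Probability threshold.
#' @return A tibble of the surviving extended classes (possibly zero rows).
#' @export
extend_class <- function(ws, cls, min_prob) {
  stopifnot(length(unique(cls$factor)) <= 1L)
  p <- if (nrow(cls) == 0) 0L else nchar(cls$factor[[1]])
  extend_occurrences(ws, tibble::as_tibble(as.data.frame(cls)), p, min_prob)
}

#' Refine a partition state from stage p to stage p + 1
#'
#' Applies [extend_class()] to every class of the state at once (the work is
#' proportional to the total number of occurrences in the state). Returns an
#' empty state when no candidate class survives thresholding and singleton
#' pruning.
#'
#' @param ws A `wseq` object.
#' @param state A `wtr_partition` at stage p.
#' @param min_prob Probability threshold.
#' @param max_classes Abort (condition class `wtr_class_cap_error`) if the
#'   number of candidate classes at the next stage exceeds this cap; guards
#'   against the exponential worst case where every character occurs at every
#'   position.
#' @return A `wtr_partition` at stage p + 1.
#' @examples
#' s1 <- build_e1(wseq_from_string("ATATATAT"), 0.5)
#' refine_partition(wseq_from_string("ATATATAT"), s1, 0.5)
#' @export
refine_partition <- function(ws, state, min_prob, max_classes = 1e6) {
  p <- partition_p(state)
  out <- extend_occurrences(
    ws, tibble::as_tibble(as.data.frame(state)), p, min_prob,
    max_classes = max_classes
  )
  new_partition(out, p = p + 1L)
}
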