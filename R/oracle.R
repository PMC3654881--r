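# Brute-force reference implementation. Deliberately written without the
# partition engine: factors are enumerated by depth-first search over the
# characters present at each position, occurrence lists are collected per
# factor string, and runs are found by stepping through each list one period
# at a time. Shares only factor-weight semantics (product of per-position
# character weights, threshold with the same 1e-12 guard) with the engine.

#' Brute-force tandem-repeat search
#'
#' Enumerates, for every period up to `max_period` and every anchor position,
#' every string whose cumulative weight meets `min_prob` (depth-first over the
#' characters present per position, pruning as soon as the running product
#' drops below threshold), then scans each factor's occurrence list for
#' maximal arithmetic chains of difference equal to the factor length, filters
#' non-primitive factors and returns the same table shape as
#' [find_tandem_repeats()]. Intended as an independent test oracle for short
#' sequences (roughly n <= 30); cost grows with the number of real factors,
#' in the worst case exponentially in the period.
#'
#' @param ws A `wseq` object.
#' @param min_prob Probability threshold.
#' @param max_period Largest period to enumerate; defaults to `floor(n/2)` and
#'   is capped there.
#' @param max_factors Abort (condition class `wtr_resource_error`) once more
#'   than this many (factor, occurrence) records have been enumerated.
#' @return A `wtr_repeats` tibble, ordered like [find_tandem_repeats()].
#' @examples
#' brute_force_tandem_repeats(wseq_from_string("ATATATAT"), 0.5)
#' @export
brute_force_tandem_repeats <- function(ws, min_prob, max_period = NULL,
                                       max_factors = 1e6) {
  stopifnot(inherits(ws, "wseq"), is.numeric(min_prob), min_prob > 0)
  n <- wseq_n(ws)
  maxp <- n %/% 2L
  if (!is.null(max_period)) maxp <- min(maxp, as.integer(max_period))
  pos_chars <- lapply(seq_len(n), function(i) ws$char[ws$position == i])
  pos_probs <- lapply(seq_len(n), function(i) ws$prob[ws$position == i])

  occ <- new.env(parent = emptyenv()) # factor -> list(pos = int vec, prob = dbl vec)
  count <- 0L
  record <- function(f, i, pr) {
    count <<- count + 1L
    if (count > max_factors) {
      rlang::abort(
        sprintf("brute-force enumeration exceeded %g real-factor records", max_factors),
        class = "wtr_resource_error"
      )
    }
    cur <- occ[[f]]
    if (is.null(cur)) {
      occ[[f]] <- list(pos = i, prob = pr)
    } else {
      occ[[f]] <- list(pos = c(cur$pos, i), prob = c(cur$prob, pr))
    }
  }
  dfs <- function(i, j, f, pr) {
    # extend the factor anchored at i by the characters present at position j
    if (j > n || nchar(f) >= maxp) {
      return(invisible())
    }
    cs <- pos_chars[[j]]
    ps <- pos_probs[[j]]
    for (idx in seq_along(cs)) {
      pr2 <- pr * ps[[idx]]
      if (pr2 >= min_prob - 1e-12) {
        f2 <- paste0(f, cs[[idx]])
        record(f2, i, pr2)
        dfs(i, j + 1L, f2, pr2)
      }
    }
  }
  if (maxp >= 1L) {
    for (i in seq_len(n)) dfs(i, i, "", 1)
  }

  rows <- list()
  for (f in ls(occ)) {
    p <- nchar(f)
    if (!oracle_primitive(f)) next
    ent <- occ[[f]]
    ord <- order(ent$pos)
    pos <- ent$pos[ord]
    prob <- ent$prob[ord]
    # a run starts at any occurrence not preceded by one exactly p earlier
    for (s_idx in seq_along(pos)) {
      s <- pos[[s_idx]]
      if ((s - p) %in% pos) next
      chain <- s
      q <- s + p
      while (q %in% pos) {
        chain <- c(chain, q)
        q <- q + p
      }
      if (length(chain) >= 2L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          start = as.integer(s),
          end = as.integer(s + length(chain) * p - 1L),
          factor = f,
          period = p,
          copies = length(chain),
          min_copy_prob = min(prob[match(chain, pos)]),
          copy_probs = list(prob[match(chain, pos)])
        )
      }
    }
  }
  out <- dplyr::bind_rows(c(list(empty_repeats()), rows))
  out <- dplyr::arrange(out, .data$start, .data$period, .data$factor)
  new_repeats(out, n = n, min_prob = min_prob)
}

# primitivity via the rotation lemma: f is non-primitive exactly when f occurs
# inside f+f at an interior offset (different test from the engine's divisor
# enumeration, on purpose)
oracle_primitive <- function(f) {
  p <- nchar(f)
  if (p == 1L) {
    return(TRUE)
  }
  doubled <- paste0(f, f)
  for (off in seq_len(p - 1L)) {
    if (substr(doubled, off + 1L, off + p) == f) {
      return(FALSE)
    }
  }
  TRUE
}
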