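# Confidence-bounded binding / enrichment scoring of phage clones (SLISY),
# 0-100 normalization, ranking and backbone selection.

#' Approximate 95% confidence bounds on a read count
#'
#' For a count n the bounds are n +/- 2*sqrt(n) (normal approximation to
#' the Poisson), the lower bound floored at 0.
#' @param n non-negative integer count(s).
#' @return data.frame with columns \code{n}, \code{lower}, \code{upper}.
#' @examples
#' count_ci(100)  # lower 80, upper 120
#' @export
count_ci <- function(n) {
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n)))
    stopf("counts must be non-negative integers")
  data.frame(n = n, lower = pmax(0, n - 2 * sqrt(n)),
             upper = n + 2 * sqrt(n))
}

#' Scoring configuration
#'
#' @param pseudocount denominator floor epsilon > 0 applied to zero-count
#'   denominators (in reads/molecules); keeps ratios finite.
#' @param use_ci apply the stringency rule: lower bound for TRBC2-bound
#'   counts, upper bound for TRBC1-bound counts. Off = point estimates.
#' @param normalization only \code{"minmax"} (linear map to [0, 100]).
#' @param selection_rule \code{"max_min_of_normalized"} (rank by the
#'   smaller of the two normalized scores, descending) or
#'   \code{"top_k_by_binding"}.
#' @param k number of clones selected.
#' @export
score_config <- function(pseudocount = 1, use_ci = TRUE,
                         normalization = "minmax",
                         selection_rule = c("max_min_of_normalized",
                                            "top_k_by_binding"),
                         k = 5L) {
  stopifnot(pseudocount > 0, normalization == "minmax", is_count(k), k >= 1)
  list(pseudocount = pseudocount, use_ci = isTRUE(use_ci),
       normalization = normalization,
       selection_rule = match.arg(selection_rule), k = as.integer(k))
}

#' Binding ratio of a clone
#'
#' Ratio of the clone's count in the TRBC2+-cell-bound pool to its count
#' in the TRBC1+-cell-bound pool. With \code{use_ci} on, the stringent
#' form is used: the lower confidence bound of the TRBC2 count over the
#' upper bound of the TRBC1 count; the denominator is floored at
#' \code{pseudocount}.
#'
#' @param n_trbc2,n_trbc1 clone counts in the two bound pools (vectors).
#' @param config a \code{\link{score_config}}.
#' @return numeric ratio(s), >= 0.
#' @examples
#' binding_ratio(100, 100)  # 80/120
#' @export
binding_ratio <- function(n_trbc2, n_trbc1, config = score_config()) {
  if (config$use_ci) {
    num <- count_ci(n_trbc2)$lower
    den <- count_ci(n_trbc1)$upper
  } else {
    num <- n_trbc2
    den <- n_trbc1
  }
  num / pmax(den, config$pseudocount)
}

#' Enrichment ratio of a clone
#'
#' Ratio of the clone's fraction among all clones bound to TRBC2+ cells
#' to its fraction in the input library. With \code{use_ci} on, the lower
#' confidence bound is applied to the TRBC2-bound clone count; input
#' counts are point estimates. The input fraction is floored at
#' \code{pseudocount / N_input_total}.
#'
#' @param n_trbc2 clone count(s) in the TRBC2-bound pool.
#' @param N_trbc2_total total assigned molecules in the TRBC2-bound pool.
#' @param n_input clone count(s) in the input library sample.
#' @param N_input_total total assigned molecules in the input sample.
#' @param config a \code{\link{score_config}}.
#' @return numeric ratio(s), >= 0.
#' @export
enrichment_ratio <- function(n_trbc2, N_trbc2_total, n_input,
                             N_input_total, config = score_config()) {
  if (N_trbc2_total <= 0 || N_input_total <= 0)
    stopf("sample totals must be positive")
  num <- if (config$use_ci) count_ci(n_trbc2)$lower else n_trbc2
  (num / N_trbc2_total) /
    (pmax(n_input, config$pseudocount) / N_input_total)
}

#' Min-max normalize ratios onto a 0-100 scale
#'
#' Linear map sending the minimum to 0 and the maximum to 100. If all
#' finite values are equal the result is all zeros (degenerate case).
#' @param x numeric vector with at least one finite value.
#' @return numeric vector on [0, 100].
#' @export
normalize_scores <- function(x) {
  if (!length(x) || !any(is.finite(x)))
    stopf("need at least one finite ratio to normalize")
  rng <- range(x[is.finite(x)])
  if (diff(rng) == 0) return(rep(0, length(x)))
  100 * (x - rng[1]) / diff(rng)
}

role_column <- function(counts, role) {
  s <- names(counts$roles)[counts$roles == role]
  if (length(s) != 1L)
    stopf("need exactly one sample with role '%s' (found %d)", role,
          length(s))
  s
}

#' Score all clones of a library from a count table
#'
#' Computes, for every clone (including the parent entry), the
#' confidence-bounded binding ratio and enrichment ratio, their 0-100
#' min-max normalized values, and the rank under the configured selection
#' rule (default: descending by the smaller of the two normalized scores,
#' ties broken by descending binding ratio, then clone ID).
#'
#' @param counts a \code{\link{clone_counts}} with one sample for each of
#'   the roles \code{input_library}, \code{trbc2_bound},
#'   \code{trbc1_bound}.
#' @param config a \code{\link{score_config}}.
#' @return object of class \code{slisy_scores} (a data.frame): columns
#'   \code{clone_id}, \code{n_input}, \code{n_trbc2}, \code{n_trbc1},
#'   \code{binding_ratio}, \code{enrichment_ratio}, \code{binding_norm},
#'   \code{enrichment_norm}, \code{rank}; rows in rank order.
#' @export
score_clones <- function(counts, config = score_config()) {
  stopifnot(inherits(counts, "clone_counts"))
  n_in <- counts$counts[, role_column(counts, "input_library")]
  n2 <- counts$counts[, role_column(counts, "trbc2_bound")]
  n1 <- counts$counts[, role_column(counts, "trbc1_bound")]
  N2 <- sum(n2); N_in <- sum(n_in)
  br <- binding_ratio(n2, n1, config)
  er <- enrichment_ratio(n2, N2, n_in, N_in, config)
  sc <- data.frame(clone_id = rownames(counts$counts),
                   n_input = unname(n_in), n_trbc2 = unname(n2),
                   n_trbc1 = unname(n1),
                   binding_ratio = unname(br),
                   enrichment_ratio = unname(er),
                   stringsAsFactors = FALSE)
  sc$binding_norm <- normalize_scores(sc$binding_ratio)
  sc$enrichment_norm <- normalize_scores(sc$enrichment_ratio)
  key <- switch(config$selection_rule,
                max_min_of_normalized = pmin(sc$binding_norm,
                                             sc$enrichment_norm),
                top_k_by_binding = sc$binding_norm)
  ord <- order(-key, -sc$binding_ratio, sc$clone_id)
  sc <- sc[ord, , drop = FALSE]
  sc$rank <- seq_len(nrow(sc))
  rownames(sc) <- NULL
  attr(sc, "config") <- config
  class(sc) <- c("slisy_scores", "data.frame")
  sc
}

#' @export
print.slisy_scores <- function(x, n = 10L, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("SLISY clone scores: %d clones (%s bounds, rule %s)\n",
              nrow(x), if (cfg$use_ci) "stringent" else "point",
              cfg$selection_rule))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... and %d more clones\n", nrow(x) - n))
  invisible(x)
}

#' Rank clones and select the next round's candidates
#'
#' @param scores a \code{slisy_scores} object.
#' @param k number of clones to select (default from the scoring config).
#' @return list with \code{ranked} (clone IDs in rank order) and
#'   \code{selected} (the top k).
#' @export
rank_select <- function(scores, k = NULL) {
  stopifnot(inherits(scores, "slisy_scores"))
  k <- k %||% attr(scores, "config")$k
  ranked <- scores$clone_id
  list(ranked = ranked, selected = utils::head(ranked, k))
}

#' Write scores to CSV
#' @param scores a \code{slisy_scores}.
#' @param path CSV path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}
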