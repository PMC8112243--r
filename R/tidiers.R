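# broom-style tidiers for the package's fitted objects.

#' Tidy an EM reassignment fit
#'
#' @param x A [em_fit()] result.
#' @param ... Unused.
#' @return Tibble of per-locus mixture proportions.
#' @export
tidy.herv_em <- function(x, ...) {
  x$proportions
}

#' @rdname tidy.herv_em
#' @return For `glance()`: one-row tibble with iteration count, convergence
#'   flag, final penalized log-likelihood, fragment and locus totals.
#' @export
glance.herv_em <- function(x, ...) {
  tibble(
    n_fragments = x$n_fragments,
    n_loci = x$n_loci,
    n_iter = x$n_iter,
    converged = x$converged,
    log_posterior = x$loglik[length(x$loglik)]
  )
}

#' Tidy a Jaccard filtering result
#'
#' @param x A [jaccard_threshold()] result.
#' @param ... Unused.
#' @return The threshold/similarity curve as a tibble.
#' @export
tidy.herv_filter <- function(x, ...) {
  x$curve
}

#' @rdname tidy.herv_filter
#' @export
glance.herv_filter <- function(x, ...) {
  tibble(
    s_star = x$s_star,
    n_input = x$n_input,
    n_retained = x$n_retained,
    max_similarity = max(x$curve$similarity)
  )
}

#' Tidy an overlap permutation test
#'
#' @param x A [overlap_permutation_test()] result.
#' @param ... Unused.
#' @return The null intersection-size histogram as a tibble.
#' @export
tidy.herv_overlap_test <- function(x, ...) {
  x$null_histogram
}

#' @rdname tidy.herv_overlap_test
#' @export
glance.herv_overlap_test <- function(x, ...) {
  tibble(
    observed_overlap = x$observed_overlap,
    null_mean = x$null_mean,
    null_max = x$null_max,
    n_exceed = x$n_exceed,
    n_perm = x$n_perm,
    p_empirical = x$p_empirical,
    p_is_upper_bound = x$p_is_upper_bound
  )
}

#' Glance at a DE-vs-null distance test
#'
#' @param x A [distance_null_test()] result.
#' @param ... Unused.
#' @return One-row tibble with the U statistic, p-value, group sizes and
#'   medians.
#' @export
glance.herv_distance_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    n_de = x$n_de,
    n_non_de = x$n_non_de,
    median_distance_de = x$median_distance_de,
    median_distance_non_de = x$median_distance_non_de,
    method = x$method
  )
}

#' @rdname glance.herv_distance_test
#' @return For `tidy()`: per-HERV distances with their group label.
#' @export
tidy.herv_distance_test <- function(x, ...) {
  bind_rows(
    tibble(group = "de", distance_bp = x$distances_de),
    tibble(group = "non_de", distance_bp = x$distances_non_de)
  )
}
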