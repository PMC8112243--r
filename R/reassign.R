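#' Fit the Bayesian mixture model that reassigns ambiguous fragments
#'
#' Fragments aligning to several HERV loci of one family are resolved with a
#' mixture model over candidate loci fitted by expectation-maximization.
#' Alignment scores enter through the weight
#' `w(f, l) = exp(lambda * (score(f, l) - max_score(f)))`, so only the
#' within-fragment score differences matter. The E-step computes
#' responsibilities `r(f, l) proportional to pi_l * w(f, l)` over the
#' fragment's candidates; the M-step is the MAP update under a symmetric
#' Dirichlet prior, `pi_l proportional to sum_f r(f, l) + theta_prior /
#' n_loci`. Iteration stops when the relative change in the penalized
#' log-likelihood drops below `tol` or after `max_iter` iterations.
#'
#' @param alignments Tibble with columns `fragment_id`, `locus_id`, `score`;
#'   one row per candidate alignment, no duplicated (fragment, locus) pair,
#'   every fragment with at least one candidate.
#' @param max_iter Iteration cap (default 200).
#' @param theta_prior Total Dirichlet pseudo-count, split uniformly across
#'   loci (default 200,000 — strong shrinkage toward uniform proportions).
#' @param tol Relative penalized log-likelihood change for early stop.
#' @param lambda Score-to-weight scale (default 0.1).
#' @param reassign_mode `"best"` assigns each fragment wholly to its
#'   highest-responsibility locus (ties broken by lowest `locus_id`);
#'   `"average"` distributes fractional counts by responsibility.
#' @return Object of class `herv_em`: proportions `pi` per locus, sparse
#'   responsibilities, the penalized log-likelihood trace, iteration count
#'   and convergence flag.
#' @seealso [reassign_to_counts()] for the resulting per-locus counts.
#' @export
em_fit <- function(alignments, max_iter = 200, theta_prior = 200000,
                   tol = 1e-6, lambda = 0.1,
                   reassign_mode = c("best", "average")) {
  reassign_mode <- match.arg(reassign_mode)
  stopifnot(max_iter >= 1, theta_prior >= 0, tol > 0)
  aln <- as_tibble(alignments)
  if (!all(c("fragment_id", "locus_id", "score") %in% names(aln))) {
    abort("`alignments` needs fragment_id, locus_id, score columns.")
  }
  if (nrow(aln) == 0) abort("No fragments to reassign.")
  if (any(!is.finite(aln$score))) abort("Non-finite alignment score.")
  if (anyDuplicated(aln[c("fragment_id", "locus_id")])) {
    abort("Duplicated (fragment, locus) candidate pair.")
  }

  frag <- factor(aln$fragment_id)
  locus_ids <- sort(unique(aln$locus_id))
  loc <- match(aln$locus_id, locus_ids)
  n_frag <- nlevels(frag)
  n_loc <- length(locus_ids)
  fi <- as.integer(frag)

  w <- exp(lambda * (aln$score - stats::ave(aln$score, fi, FUN = max)))
  theta <- theta_prior / n_loc

  pi <- rep(1 / n_loc, n_loc)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  r <- NULL
  repeat {
    iter <- iter + 1L
    num <- pi[loc] * w
    denom <- rowsum(num, fi, reorder = TRUE)[, 1]
    r <- num / denom[fi]
    ll <- sum(log(denom)) + theta * sum(log(pi))
    loglik <- c(loglik, ll)
    mass <- rowsum(r, loc, reorder = TRUE)[, 1]
    # rowsum drops absent locus indices; rebuild full-length vector
    full_mass <- numeric(n_loc)
    full_mass[sort(unique(loc))] <- mass
    pi <- (full_mass + theta) / (n_frag + theta * n_loc)
    if (iter > 1) {
      prev <- loglik[iter - 1]
      if (abs(ll - prev) / (abs(prev) + 1e-12) < tol) {
        converged <- TRUE
        break
      }
    }
    if (iter >= max_iter) break
  }

  structure(
    list(
      proportions = tibble(locus_id = locus_ids, pi = pi),
      responsibilities = tibble(
        fragment_id = as.character(frag), locus_id = locus_ids[loc], r = r
      ),
      n_fragments = n_frag,
      n_loci = n_loc,
      n_iter = iter,
      converged = converged,
      loglik = loglik,
      reassign_mode = reassign_mode,
      config = list(max_iter = max_iter, theta_prior = theta_prior,
                    tol = tol, lambda = lambda)
    ),
    class = "herv_em"
  )
}

#' @export
print.herv_em <- function(x, ...) {
  cat(
    "<herv_em> ", x$n_fragments, " fragments over ", x$n_loci, " loci; ",
    x$n_iter, " iterations (", if (x$converged) "converged" else "iteration cap",
    "), mode = ", x$reassign_mode, "\n",
    sep = ""
  )
  invisible(x)
}

#' Turn an EM fit into per-locus fragment counts
#'
#' In `best` mode each fragment is assigned wholly to its
#' maximum-responsibility locus (ties broken deterministically by lowest
#' `locus_id`), giving integer counts that sum to the fragment total. In
#' `average` mode fractional responsibilities are summed per locus.
#'
#' @param fit A [em_fit()] result.
#' @param mode Override the fit's reassignment mode.
#' @return Tibble with `locus_id` and `count` for every locus seen in the
#'   alignments (zero-count loci included).
#' @export
reassign_to_counts <- function(fit, mode = NULL) {
  stopifnot(inherits(fit, "herv_em"))
  mode <- mode %||% fit$reassign_mode
  mode <- match.arg(mode, c("best", "average"))
  r <- fit$responsibilities
  if (mode == "average") {
    counts <- r %>%
      group_by(.data$locus_id) %>%
      summarise(count = sum(.data$r), .groups = "drop")
  } else {
    # within each fragment take the max-responsibility locus; responsibilities
    # are scanned in locus_id order so the first max wins ties (lowest id)
    best <- r %>%
      arrange(.data$fragment_id, .data$locus_id) %>%
      group_by(.data$fragment_id) %>%
      summarise(locus_id = .data$locus_id[which.max(.data$r)], .groups = "drop")
    counts <- best %>%
      group_by(.data$locus_id) %>%
      summarise(count = as.numeric(n()), .groups = "drop")
  }
  all_loci <- fit$proportions$locus_id
  out <- left_join(tibble(locus_id = all_loci), counts, by = "locus_id")
  out$count[is.na(out$count)] <- 0
  out
}
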