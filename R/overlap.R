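#' Permutation test for cross-dataset overlap of DE feature sets
#'
#' How surprising is the observed intersection of the two datasets' DE sets?
#' Each permutation redraws `|de1|` identifiers uniformly without replacement
#' from dataset 1's expressed universe and `|de2|` from dataset 2's, and
#' records the intersection size. The empirical p-value uses the add-one
#' rule, `p = (n_exceed + 1) / (n_perm + 1)`, so it is never zero; with no
#' exceedances among 200,000 permutations it equals 1/200,001 (< 5e-6) and
#' is reported as an upper bound.
#'
#' @param universe1,universe2 Expressed feature identifiers per dataset
#'   (shared identifier space; the universes may be nested, identical, or
#'   partially overlapping).
#' @param de1,de2 DE subsets of the corresponding universes.
#' @param n_perm Number of permutations (default 200,000).
#' @param seed Optional RNG seed for reproducible permutations.
#' @return Object of class `herv_overlap_test`: `observed_overlap`,
#'   `null_mean`, `null_max`, `n_exceed` (permutations with overlap >=
#'   observed), `p_empirical`, `p_is_upper_bound`, and the full null
#'   histogram.
#' @export
overlap_permutation_test <- function(universe1, universe2, de1, de2,
                                     n_perm = 200000, seed = NULL) {
  stopifnot(n_perm >= 1)
  universe1 <- unique(universe1)
  universe2 <- unique(universe2)
  if (length(setdiff(de1, universe1)) > 0) abort("de1 is not a subset of universe1.")
  if (length(setdiff(de2, universe2)) > 0) abort("de2 is not a subset of universe2.")
  k1 <- length(unique(de1))
  k2 <- length(unique(de2))
  n1 <- length(universe1)
  n2 <- length(universe2)
  if (k1 > n1 || k2 > n2) abort("DE set larger than its universe.")

  observed <- length(intersect(de1, de2))
  # positions of universe2 ids within universe1; NA marks ids outside the
  # shared space, which can never contribute to an intersection
  map2 <- match(universe2, universe1)
  in_shared <- !is.na(map2)

  null_overlap <- with_seed(seed, {
    memb <- logical(n1)
    out <- integer(n_perm)
    for (b in seq_len(n_perm)) {
      s1 <- sample.int(n1, k1)
      s2 <- sample.int(n2, k2)
      memb[s1] <- TRUE
      s2 <- s2[in_shared[s2]]
      out[b] <- sum(memb[map2[s2]])
      memb[s1] <- FALSE
    }
    out
  })

  n_exceed <- sum(null_overlap >= observed)
  structure(
    list(
      observed_overlap = observed,
      null_mean = mean(null_overlap),
      null_max = max(null_overlap),
      n_exceed = n_exceed,
      n_perm = n_perm,
      p_empirical = (n_exceed + 1) / (n_perm + 1),
      p_is_upper_bound = n_exceed == 0,
      null_histogram = {
        tab <- table(null_overlap)
        tibble(overlap = as.integer(names(tab)), n = as.integer(tab))
      },
      sizes = list(n1 = n1, n2 = n2, k1 = k1, k2 = k2),
      seed = seed
    ),
    class = "herv_overlap_test"
  )
}

#' @export
print.herv_overlap_test <- function(x, ...) {
  cat(
    "<herv_overlap_test> observed overlap = ", x$observed_overlap,
    "; null mean = ", signif(x$null_mean, 4),
    ", null max = ", x$null_max, " over ", x$n_perm, " permutations\n",
    "  p_empirical ", if (x$p_is_upper_bound) "< " else "= ",
    signif(x$p_empirical, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Fisher's exact test of DE-rate association between two datasets
#'
#' Builds the 2x2 table `[[n_de1, n_expr1 - n_de1], [n_de2, n_expr2 -
#' n_de2]]` (DE vs not, by dataset) and runs the two-sided exact test.
#'
#' @param n_de1,n_expr1 DE and expressed feature counts in dataset 1.
#' @param n_de2,n_expr2 Same for dataset 2.
#' @return One-row tibble: the four cells, `odds_ratio` (conditional MLE)
#'   and the two-sided `p_value`.
#' @export
fisher_de_association <- function(n_de1, n_expr1, n_de2, n_expr2) {
  if (n_de1 > n_expr1 || n_de2 > n_expr2) abort("n_de cannot exceed n_expr.")
  tab <- matrix(c(n_de1, n_expr1 - n_de1, n_de2, n_expr2 - n_de2),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) abort("Negative cell in the 2x2 table.")
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(
    n_de1 = n_de1, n_not_de1 = n_expr1 - n_de1,
    n_de2 = n_de2, n_not_de2 = n_expr2 - n_de2,
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value
  )
}

#' Cross-dataset fold-change correlation
#'
#' Pearson correlation of per-feature log2 fold changes across two DE
#' results, over all shared features or restricted to features DE in either
#' dataset.
#'
#' @param de1,de2 [nb_de_test()] results (or tibbles with `feature_id`,
#'   `log2fc` and, for the restriction, `is_de`).
#' @param restrict_to `"all"` shared features or `"de_union"` (features DE
#'   in either dataset).
#' @return One-row tibble: `restrict_to`, `n_features`, `pearson_r`.
#' @export
cross_dataset_correlation <- function(de1, de2,
                                      restrict_to = c("all", "de_union")) {
  restrict_to <- match.arg(restrict_to)
  joined <- dplyr::inner_join(
    select(as_tibble(de1), "feature_id", lfc1 = "log2fc", de1 = "is_de"),
    select(as_tibble(de2), "feature_id", lfc2 = "log2fc", de2 = "is_de"),
    by = "feature_id"
  )
  if (restrict_to == "de_union") {
    joined <- filter(joined, .data$de1 | .data$de2)
  }
  if (nrow(joined) < 3) abort("Fewer than 3 shared features after restriction.")
  if (stats::sd(joined$lfc1) == 0 || stats::sd(joined$lfc2) == 0) {
    abort("Zero-variance fold changes: correlation undefined.")
  }
  tibble(
    restrict_to = restrict_to,
    n_features = nrow(joined),
    pearson_r = cor(joined$lfc1, joined$lfc2)
  )
}
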