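#' Rank-based gene-set enrichment on importance scores
#'
#' Tests, per gene set, whether the importance scores (typically condition
#' betas from [fit_condition_model()]) of set members differ in distribution
#' from those of all other scored features — a two-sided Wilcoxon rank-sum
#' (Mann-Whitney U) test by default, or the two-sample Kolmogorov-Smirnov
#' statistic. p-values are BH-adjusted across tested sets and sets with
#' fewer than `min_set_size` scored members are skipped (their names are
#' kept in the `skipped_sets` attribute). Scores are signed, so the reported
#' direction (`up` when the member median exceeds the background median) is
#' meaningful.
#'
#' @param scores Data frame with `feature_id` and a score column (`score`,
#'   or `beta` as produced by [fit_condition_model()]).
#' @param sets A `gene_sets` tibble (see [read_gmt()]).
#' @param method `"rank_sum"` (default) or `"ks"`.
#' @param q_threshold Significance threshold on the BH q-value (default 0.1).
#' @param min_set_size Minimum scored members for a set to be tested
#'   (default 5).
#' @param de_ids Optional DE feature identifiers used to report each set's
#'   DE member fraction.
#' @return Tibble of class `herv_enrichment`: per set `n_members_scored`,
#'   `statistic`, `p_value`, `q_value`, `direction`, `frac_de`,
#'   `median_score_in_set`, `median_score_background`, `significant`.
#' @export
score_enrichment <- function(scores, sets, method = c("rank_sum", "ks"),
                             q_threshold = 0.1, min_set_size = 5,
                             de_ids = NULL) {
  method <- match.arg(method)
  stopifnot(q_threshold > 0, q_threshold < 1)
  scores <- as_tibble(scores)
  score_col <- if ("score" %in% names(scores)) "score" else "beta"
  if (!all(c("feature_id", score_col) %in% names(scores))) {
    abort("`scores` needs feature_id and score (or beta) columns.")
  }
  s <- setNames(scores[[score_col]], scores$feature_id)
  if (length(s) == 0) abort("Empty score vector.")

  rows <- vector("list", nrow(sets))
  skipped <- character(0)
  for (i in seq_len(nrow(sets))) {
    members <- intersect(sets$members[[i]], names(s))
    if (length(members) < min_set_size) {
      skipped <- c(skipped, sets$set_name[i])
      next
    }
    inset <- s[members]
    outset <- s[setdiff(names(s), members)]
    if (length(outset) == 0) {
      skipped <- c(skipped, sets$set_name[i])
      next
    }
    ht <- if (method == "rank_sum") {
      suppressWarnings(wilcox.test(inset, outset, alternative = "two.sided"))
    } else {
      suppressWarnings(ks.test(inset, outset, alternative = "two.sided"))
    }
    rows[[i]] <- tibble(
      set_name = sets$set_name[i],
      n_members_scored = length(members),
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      median_score_in_set = median(inset),
      median_score_background = median(outset),
      frac_de = if (is.null(de_ids)) NA_real_ else mean(members %in% de_ids)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    abort("No gene set has enough scored members to test.")
  }
  out$q_value <- bh_adjust(out$p_value)
  out$direction <- ifelse(out$median_score_in_set > out$median_score_background,
                          "up", "down")
  out$significant <- out$q_value < q_threshold
  out <- select(
    out, "set_name", "n_members_scored", "statistic", "p_value", "q_value",
    "direction", "frac_de", "median_score_in_set", "median_score_background",
    "significant"
  )
  structure(out, class = c("herv_enrichment", class(tibble())),
            method = method, q_threshold = q_threshold,
            skipped_sets = skipped)
}

#' Fisher overrepresentation of DE features in gene sets
#'
#' One-sided (enrichment) Fisher's exact test per set on the 2x2 table of DE
#' membership: `[[|DE n set|, |DE \ set|], [|set \ DE|, |universe \ (DE u
#' set)|]]`, BH-adjusted across sets.
#'
#' @param de_ids DE feature identifiers (subset of `universe`).
#' @param universe Expressed feature identifiers.
#' @param sets A `gene_sets` tibble.
#' @param q_threshold Significance threshold (default 0.1).
#' @param min_set_size Minimum in-universe members for a set to be tested.
#' @return Tibble of class `herv_enrichment`-like shape: per set the table
#'   cells, `odds_ratio`, `p_value`, `q_value`, `frac_de`, `significant`.
#' @export
overrepresentation_test <- function(de_ids, universe, sets,
                                    q_threshold = 0.1, min_set_size = 1) {
  stopifnot(q_threshold > 0, q_threshold < 1)
  universe <- unique(universe)
  if (length(universe) == 0) abort("Empty universe.")
  de_ids <- unique(de_ids)
  if (length(setdiff(de_ids, universe)) > 0) {
    abort("de_ids must be a subset of the universe.")
  }
  rows <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    members <- intersect(sets$members[[i]], universe)
    if (length(members) < min_set_size) next
    a <- length(intersect(de_ids, members))
    b <- length(de_ids) - a
    c_ <- length(members) - a
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "greater")
    rows[[i]] <- tibble(
      set_name = sets$set_name[i],
      n_in_universe = length(members),
      n_de_in_set = a,
      odds_ratio = unname(ft$estimate),
      p_value = ft$p.value,
      frac_de = a / length(members)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("No gene set has members in the universe.")
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < q_threshold
  structure(out, class = c("herv_enrichment", class(tibble())),
            method = "fisher_overrepresentation", q_threshold = q_threshold)
}
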