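#' Median-of-ratios size factors
#'
#' The DESeq-style normalization convention: the factor for sample j is the
#' median over features of `count[i, j] / geomean_i`, where the geometric
#' mean is taken across samples and only features with a positive geometric
#' mean (positive in every sample) contribute. Factors are not rescaled
#' afterwards. When no feature is positive in all samples — common for
#' sparse HERV matrices — the geometric mean falls back to positive entries
#' only and the median is taken over a feature's positive ratios.
#'
#' @param counts Counts tibble (`feature_id` + one column per sample).
#' @return Tibble with `sample_id` and `size_factor`. A warning (not an
#'   error) is raised when the geometric mean of the factors leaves
#'   `[0.5, 2]`, which usually indicates badly behaved input.
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 1) abort("No samples in counts.")
  logm <- log(m)
  geo <- rowMeans(logm) # -Inf whenever any sample has a zero
  use <- is.finite(geo)
  if (any(use)) {
    sf <- apply(logm[use, , drop = FALSE] - geo[use], 2, median)
  } else {
    # fallback: geometric mean over positive entries only
    pos <- m > 0
    any_pos <- rowSums(pos) > 0
    if (!any(any_pos)) abort("Cannot compute size factors: all counts are zero.")
    geo_pos <- rowSums(ifelse(pos, logm, 0)) / pmax(rowSums(pos), 1)
    ratio <- logm[any_pos, , drop = FALSE] - geo_pos[any_pos]
    ratio[!pos[any_pos, , drop = FALSE]] <- NA
    sf <- apply(ratio, 2, median, na.rm = TRUE)
    if (anyNA(sf)) abort("Cannot compute size factors: a sample has no positive counts.")
  }
  sf <- exp(sf)
  gm <- exp(mean(log(sf)))
  if (gm < 0.5 || gm > 2) {
    warn(sprintf("Geometric mean of size factors is %.3f (outside [0.5, 2]).", gm))
  }
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Normalize counts by size factors
#'
#' @param counts Counts tibble.
#' @param sf Size-factor tibble from [size_factors()] (computed if `NULL`).
#' @return Tibble of normalized (real-valued) counts with the same shape.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  sf <- sf %||% size_factors(counts)
  m <- as_count_matrix(counts)
  fac <- sf$size_factor[match(colnames(m), sf$sample_id)]
  if (anyNA(fac)) abort("Size factors missing for some samples.")
  matrix_to_counts(sweep(m, 2, fac, "/"))
}

#' Jaccard-similarity filtering threshold for replicated counts
#'
#' Data-driven low-signal filtering: candidate thresholds `s` are `s_len`
#' values evenly spaced on a log scale in `[s_min, s_max]` (defaults 1, 200,
#' 100). For each `s`, normalized counts are binarized as `value > s` and the
#' similarity is the mean over conditions of the mean pairwise Jaccard index
#' between that condition's replicate presence vectors (the Jaccard index of
#' two all-zero vectors is defined as 1). The chosen threshold `s_star`
#' maximizes this replicate-to-replicate similarity (ties go to the smallest
#' threshold); features whose maximum normalized count exceeds `s_star` are
#' retained.
#'
#' @param counts Counts tibble.
#' @param samples Sample metadata tibble (`sample_id`, `condition`); every
#'   condition needs at least two replicates.
#' @param s_min,s_max,s_len Threshold grid (defaults 1, 200, 100).
#' @param normalization `"median_of_ratios"` (default) or `"none"`.
#' @param grid `"log"` (default) or `"linear"` spacing of thresholds.
#' @return Object of class `herv_filter`: `s_star`, the `curve` tibble
#'   (`threshold`, `similarity`), `retained_ids`, and bookkeeping counts.
#' @export
jaccard_threshold <- function(counts, samples, s_min = 1, s_max = 200,
                              s_len = 100,
                              normalization = c("median_of_ratios", "none"),
                              grid = c("log", "linear")) {
  normalization <- match.arg(normalization)
  grid <- match.arg(grid)
  if (!(s_min > 0 && s_min < s_max)) abort("Need 0 < s_min < s_max.")
  if (s_len < 2) abort("s_len must be >= 2.")
  samples <- check_samples(counts, samples)
  samples <- filter(samples, .data$sample_id %in% names(counts))
  reps <- table(samples$condition)
  if (any(reps < 2)) {
    abort(paste0(
      "Each condition needs >= 2 replicates; got ",
      paste(names(reps), reps, sep = "=", collapse = ", ")
    ))
  }

  norm <- if (normalization == "median_of_ratios") {
    normalize_counts(counts)
  } else {
    counts
  }
  m <- as_count_matrix(norm)

  thresholds <- if (grid == "log") {
    exp(seq(log(s_min), log(s_max), length.out = s_len))
  } else {
    seq(s_min, s_max, length.out = s_len)
  }

  cond_cols <- split(samples$sample_id, samples$condition)
  similarity <- vapply(thresholds, function(s) {
    B <- m > s
    mean(vapply(cond_cols, function(cols) {
      prs <- combn(cols, 2, simplify = FALSE)
      mean(vapply(prs, function(p) {
        u <- B[, p[1]]
        v <- B[, p[2]]
        un <- sum(u | v)
        if (un == 0) 1 else sum(u & v) / un
      }, 0))
    }, 0))
  }, 0)

  s_star <- thresholds[which.max(similarity)] # first max = smallest s on ties
  retained <- rownames(m)[apply(m, 1, max) > s_star]

  structure(
    list(
      s_star = s_star,
      curve = tibble(threshold = thresholds, similarity = similarity),
      retained_ids = retained,
      n_input = nrow(m),
      n_retained = length(retained),
      config = list(s_min = s_min, s_max = s_max, s_len = s_len,
                    normalization = normalization, grid = grid)
    ),
    class = "herv_filter"
  )
}

#' @export
print.herv_filter <- function(x, ...) {
  cat(
    "<herv_filter> s* = ", signif(x$s_star, 4), "; retained ",
    x$n_retained, " / ", x$n_input, " features\n",
    sep = ""
  )
  invisible(x)
}

#' Apply a filter result to a counts tibble
#'
#' @param counts Counts tibble.
#' @param flt A [jaccard_threshold()] result (or a character vector of
#'   feature ids to keep).
#' @return The filtered counts tibble.
#' @export
filter_counts <- function(counts, flt) {
  keep <- if (inherits(flt, "herv_filter")) flt$retained_ids else flt
  filter(counts, .data$feature_id %in% keep)
}
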