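# Internal helpers shared across modules.

# Convert a counts tibble (feature_id + one column per sample) to a numeric
# matrix with feature rownames. Values must be non-negative and finite.
as_count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (!"feature_id" %in% names(counts)) {
    abort("`counts` must have a `feature_id` column.")
  }
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature_id
  if (anyNA(m)) abort("`counts` contains NA values; replace them before use.")
  if (any(m < 0)) abort("`counts` contains negative values.")
  m
}

matrix_to_counts <- function(m) {
  out <- as_tibble(m, rownames = "feature_id")
  out
}

# Validate sample metadata against a counts tibble and return it with
# condition as character. Every sample column must be covered.
check_samples <- function(counts, samples) {
  if (!all(c("sample_id", "condition") %in% names(samples))) {
    abort("`samples` must have `sample_id` and `condition` columns.")
  }
  sample_cols <- setdiff(names(counts), "feature_id")
  missing <- setdiff(sample_cols, samples$sample_id)
  if (length(missing) > 0) {
    abort(paste0(
      "Samples present in counts but absent from metadata: ",
      paste(missing, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(samples$condition), c("case", "control"))
  if (length(bad) > 0) {
    abort(paste0("Unknown condition labels: ", paste(bad, collapse = ", ")))
  }
  samples
}

# Gap between two 0-based half-open intervals; 0 when they touch or overlap.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start2 - end1, start1 - end2))
}

# Deterministic RNG scope: run `expr` under `seed` without disturbing the
# caller's RNG stream. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
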