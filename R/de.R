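#' Benjamini-Hochberg step-up adjustment
#'
#' Maps p-values to q-values controlling the false discovery rate:
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` on the sorted p-values, mapped back
#' to input order and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for differential expression
#'
#' Per-feature case/control comparison on size-factor-normalized counts. The
#' dispersion `alpha` in `var = mu + alpha * mu^2` is estimated by the method
#' of moments within conditions and floored at `dispersion_floor`. The effect
#' is `log2fc = log2((mean_case + c) / (mean_control + c))` with pseudo-mean
#' `c` (default 0.5) for stability at zero counts; its standard error comes
#' from the delta method applied to the NB variance of each group mean. The
#' two-sided normal (Wald) p-value is BH-adjusted and a feature is flagged DE
#' when `q < alpha` and `|log2fc| >= lfc_threshold`.
#'
#' @param counts Counts tibble (pre-filtered; see [jaccard_threshold()]).
#' @param samples Sample metadata (`sample_id`, `condition`), both conditions
#'   with at least two samples.
#' @param sf Size factors from [size_factors()]; computed when `NULL`.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_threshold Minimum |log2 fold change| for the DE flag
#'   (default 1).
#' @param dispersion_floor Lower bound on the moment dispersion estimate.
#' @param pseudo_mean Pseudo-mean `c` added to group means (default 0.5).
#' @return Tibble of class `herv_de` with per-feature `base_mean`, `log2fc`
#'   (case over control), `se_log2fc`, `p_value`, `q_value`, `is_de` and
#'   `direction` (`up`/`down`/`none`).
#' @export
nb_de_test <- function(counts, samples, sf = NULL, alpha = 0.05,
                       lfc_threshold = 1, dispersion_floor = 1e-8,
                       pseudo_mean = 0.5) {
  stopifnot(alpha > 0, alpha < 1, lfc_threshold >= 0)
  samples <- check_samples(counts, samples)
  sf <- sf %||% size_factors(counts)
  y <- as_count_matrix(normalize_counts(counts, sf))

  case_cols <- samples$sample_id[samples$condition == "case"]
  ctrl_cols <- samples$sample_id[samples$condition == "control"]
  if (length(case_cols) < 2 || length(ctrl_cols) < 2) {
    abort("Both conditions need at least 2 samples.")
  }
  y1 <- y[, case_cols, drop = FALSE]
  y0 <- y[, ctrl_cols, drop = FALSE]
  n1 <- ncol(y1)
  n0 <- ncol(y0)
  m1 <- rowMeans(y1)
  m0 <- rowMeans(y0)
  v1 <- apply(y1, 1, var)
  v0 <- apply(y0, 1, var)

  # method-of-moments dispersion pooled across the two conditions:
  # var = mu + alpha mu^2  =>  alpha = (var - mu) / mu^2
  denom <- m1^2 + m0^2
  a_hat <- ifelse(denom > 0, ((v1 - m1) + (v0 - m0)) / denom, dispersion_floor)
  a_hat <- pmax(a_hat, dispersion_floor)

  c0 <- pseudo_mean
  log2fc <- log2((m1 + c0) / (m0 + c0))
  var_m1 <- (m1 + a_hat * m1^2) / n1
  var_m0 <- (m0 + a_hat * m0^2) / n0
  se <- sqrt((var_m1 / (m1 + c0)^2 + var_m0 / (m0 + c0)^2)) / log(2)

  z <- ifelse(se > 0, log2fc / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(z)), 1)
  q <- bh_adjust(p)
  is_de <- q < alpha & abs(log2fc) >= lfc_threshold
  direction <- dplyr::case_when(
    is_de & log2fc > 0 ~ "up",
    is_de & log2fc < 0 ~ "down",
    .default = "none"
  )

  out <- tibble(
    feature_id = rownames(y),
    base_mean = unname(rowMeans(y)),
    log2fc = unname(log2fc),
    se_log2fc = unname(se),
    p_value = unname(p),
    q_value = unname(q),
    is_de = unname(is_de),
    direction = unname(direction)
  )
  structure(
    out,
    class = c("herv_de", class(tibble())),
    de_config = list(alpha = alpha, lfc_threshold = lfc_threshold,
                     dispersion_floor = dispersion_floor,
                     pseudo_mean = pseudo_mean)
  )
}

#' Summarize a differential-expression result
#'
#' Reports DE feature counts in both threshold regimes: significance only
#' (`q < alpha`, any fold change) and significance plus the fold-change
#' threshold (the `is_de` flag).
#'
#' @param res A [nb_de_test()] result.
#' @return One-row tibble: `n_tested`, `n_sig`/`n_sig_up`/`n_sig_down`
#'   (q-threshold only) and `n_de`/`n_up`/`n_down` (with the lfc threshold).
#' @export
summarize_de <- function(res) {
  cfg <- attr(res, "de_config") %||% list(alpha = 0.05)
  sig <- res$q_value < cfg$alpha
  tibble(
    n_tested = nrow(res),
    n_sig = sum(sig),
    n_sig_up = sum(sig & res$log2fc > 0),
    n_sig_down = sum(sig & res$log2fc < 0),
    n_de = sum(res$is_de),
    n_up = sum(res$direction == "up"),
    n_down = sum(res$direction == "down")
  )
}

#' Extract the identifiers flagged DE
#'
#' @param res A [nb_de_test()] result.
#' @return Character vector of `feature_id` with `is_de = TRUE`.
#' @export
de_ids <- function(res) {
  res$feature_id[res$is_de]
}
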