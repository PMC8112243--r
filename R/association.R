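#' Per-feature condition model: betas used as importance scores
#'
#' Ordinary least squares of transformed expression on a case indicator, one
#' model per feature. The beta coefficient (case effect on the
#' log2-normalized scale) is the importance score consumed by
#' [score_enrichment()]; p-values are two-sided t-tests and q-values are BH
#' across features.
#'
#' @param counts Counts tibble.
#' @param samples Sample metadata (`sample_id`, `condition`).
#' @param sf Size factors (computed when `NULL`; ignored for the CPM
#'   transform).
#' @param transform `"log2_norm_plus1"` (default): `log2(count / size_factor
#'   + 1)`; or `"log2_cpm_plus1"`: `log2(count / library_size * 1e6 + 1)`.
#' @return Tibble of class `herv_betas`: `feature_id`, `beta`, `se`,
#'   `p_value`, `q_value`.
#' @export
fit_condition_model <- function(counts, samples, sf = NULL,
                                transform = c("log2_norm_plus1", "log2_cpm_plus1")) {
  transform <- match.arg(transform)
  samples <- check_samples(counts, samples)
  t_mat <- transform_counts(counts, sf, transform)
  x <- as.numeric(samples$condition[match(colnames(t_mat), samples$sample_id)] == "case")
  if (length(x) < 3) abort("Need at least 3 samples in total.")
  if (length(unique(x)) < 2) abort("Both conditions must be present.")

  X <- cbind(intercept = 1, case = x)
  xtx_inv <- solve(crossprod(X))
  df <- length(x) - 2L

  fit_one <- function(yrow) {
    f <- stats::lm.fit(X, yrow)
    beta <- unname(f$coefficients["case"])
    rss <- sum(f$residuals^2)
    # guard exact fits against floating-point residual dust
    if (rss < 1e-10 * (sum(yrow^2) + 1)) {
      return(c(beta, 0, if (abs(beta) > 1e-9) 0 else 1))
    }
    se <- sqrt(rss / df * xtx_inv["case", "case"])
    p <- 2 * pt(-abs(beta / se), df)
    c(beta, se, p)
  }
  res <- t(apply(t_mat, 1, fit_one))
  out <- tibble(
    feature_id = rownames(t_mat),
    beta = unname(res[, 1]),
    se = unname(res[, 2]),
    p_value = unname(res[, 3]),
    q_value = unname(bh_adjust(res[, 3]))
  )
  structure(out, class = c("herv_betas", class(tibble())),
            transform = transform)
}

transform_counts <- function(counts, sf, transform) {
  m <- as_count_matrix(counts)
  if (transform == "log2_cpm_plus1") {
    lib <- colSums(m)
    if (any(lib == 0)) abort("Sample with zero library size.")
    log2(sweep(m, 2, lib, "/") * 1e6 + 1)
  } else {
    sf <- sf %||% size_factors(counts)
    fac <- sf$size_factor[match(colnames(m), sf$sample_id)]
    if (anyNA(fac)) abort("Size factors missing for some samples.")
    log2(sweep(m, 2, fac, "/") + 1)
  }
}

#' Pairwise HERV-gene association models
#'
#' For each requested (HERV, gene) pair, fits an ordinary least-squares model
#' of transformed gene expression on transformed HERV expression across the
#' shared samples, plus the Spearman rank correlation of the same values.
#' q-values are BH-adjusted within the tested pair family only (matching the
#' restriction of pairs to physical neighbourhoods).
#'
#' @param counts_gene,counts_herv Counts tibbles for genes and HERV loci over
#'   the same samples (identical sample columns required).
#' @param samples Sample metadata.
#' @param pairs Tibble (or data frame) with columns `herv_id`, `gene_id`.
#' @param sf_gene,sf_herv Optional size factors per matrix.
#' @param transform Expression transform, see [fit_condition_model()].
#' @param q_threshold Significance threshold on the BH q-value (default 0.05).
#' @return Tibble of class `herv_assoc`: per pair `beta` (slope of gene on
#'   HERV), `se`, `p_value`, `q_value`, `spearman_rho`, `significant`.
#' @export
fit_pair_association <- function(counts_gene, counts_herv, samples, pairs,
                                 sf_gene = NULL, sf_herv = NULL,
                                 transform = c("log2_norm_plus1", "log2_cpm_plus1"),
                                 q_threshold = 0.05) {
  transform <- match.arg(transform)
  stopifnot(q_threshold > 0, q_threshold < 1)
  pairs <- as_tibble(pairs)
  if (!all(c("herv_id", "gene_id") %in% names(pairs))) {
    abort("`pairs` needs herv_id and gene_id columns.")
  }
  g_cols <- setdiff(names(counts_gene), "feature_id")
  h_cols <- setdiff(names(counts_herv), "feature_id")
  if (!setequal(g_cols, h_cols)) {
    abort("Sample columns differ between the gene and HERV matrices.")
  }
  samples <- check_samples(counts_gene, samples)

  tg <- transform_counts(counts_gene, sf_gene, transform)
  th <- transform_counts(counts_herv, sf_herv, transform)
  th <- th[, colnames(tg), drop = FALSE]

  miss_g <- setdiff(unique(pairs$gene_id), rownames(tg))
  miss_h <- setdiff(unique(pairs$herv_id), rownames(th))
  if (length(miss_g) > 0 || length(miss_h) > 0) {
    abort(paste0(
      "Pairs reference unknown features: ",
      paste(head(c(miss_g, miss_h), 5), collapse = ", ")
    ))
  }

  n <- ncol(tg)
  df <- n - 2L
  res <- purrr::pmap(pairs[c("herv_id", "gene_id")], function(herv_id, gene_id) {
    xv <- th[herv_id, ]
    yv <- tg[gene_id, ]
    sxx <- sum((xv - mean(xv))^2)
    if (sxx == 0) {
      return(tibble(herv_id = herv_id, gene_id = gene_id, beta = NA_real_,
                    se = NA_real_, p_value = 1, spearman_rho = NA_real_))
    }
    beta <- sum((xv - mean(xv)) * (yv - mean(yv))) / sxx
    a <- mean(yv) - beta * mean(xv)
    rss <- sum((yv - a - beta * xv)^2)
    if (rss < 1e-10 * (sum(yv^2) + 1)) {
      se <- 0
      p <- if (abs(beta) > 1e-9) 0 else 1
    } else {
      se <- sqrt(rss / df / sxx)
      p <- 2 * pt(-abs(beta / se), df)
    }
    rho <- suppressWarnings(cor(xv, yv, method = "spearman"))
    tibble(herv_id = herv_id, gene_id = gene_id, beta = beta, se = se,
           p_value = p, spearman_rho = rho)
  })
  out <- bind_rows(res)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < q_threshold
  structure(out, class = c("herv_assoc", class(tibble())),
            q_threshold = q_threshold, transform = transform)
}

#' Rank the strongest significant associations
#'
#' Significant pairs sorted by |Spearman rho| descending, ties by q-value
#' ascending, truncated to the top `k`.
#'
#' @param res A [fit_pair_association()] result.
#' @param k Number of pairs to keep.
#' @return Tibble of at most `k` rows.
#' @export
rank_top_associations <- function(res, k) {
  stopifnot(k >= 1)
  res %>%
    filter(.data$significant) %>%
    arrange(dplyr::desc(abs(.data$spearman_rho)), .data$q_value) %>%
    head(k)
}
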