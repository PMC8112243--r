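test_that("condition betas recover exact shifts and flat features", {
  # transformed value is log2(count + 1) under unit size factors
  m <- rbind(
    rep(15, 8),                    # flat
    c(rep(15, 4), rep(3, 4))       # exact shift of 2 on the log2(x+1) scale
  )
  counts <- counts_tbl(m)
  cond <- rep(c("case", "control"), each = 4)
  cb <- fit_condition_model(counts, samples_tbl(cond), sf = unit_sf(counts))
  expect_equal(cb$beta[1], 0)
  expect_equal(cb$p_value[1], 1)
  expect_equal(cb$beta[2], 2)
  expect_lt(cb$p_value[2], 1e-12)
})

test_that("condition betas match the closed-form simple-regression oracle", {
  m <- matrix(c(12, 7, 9, 4, 3, 1), nrow = 1)
  counts <- counts_tbl(m)
  cond <- c("case", "case", "case", "control", "control", "control")
  cb <- fit_condition_model(counts, samples_tbl(cond), sf = unit_sf(counts))

  y <- log2(m[1, ] + 1)
  x <- as.numeric(cond == "case")
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  resid <- y - (mean(y) - beta_hat * mean(x)) - beta_hat * x
  se_hat <- sqrt(sum(resid^2) / 4 / sum((x - mean(x))^2))
  p_hat <- 2 * pt(-abs(beta_hat / se_hat), df = 4)
  expect_equal(cb$beta, beta_hat, tolerance = 1e-12)
  expect_equal(cb$se, se_hat, tolerance = 1e-12)
  expect_equal(cb$p_value, p_hat, tolerance = 1e-12)
})

test_that("pair associations hit exact endpoints and rank correctly", {
  withr::local_seed(41)
  base <- rnbinom(12, mu = 200, size = 10)
  cg <- counts_tbl(rbind(G1 = base, G2 = rev(base)), feature_ids = c("G1", "G2"))
  ch <- counts_tbl(rbind(H1 = base), feature_ids = "H1")
  samples <- samples_tbl(rep(c("case", "control"), each = 6))
  pairs <- tibble::tibble(herv_id = c("H1", "H1"), gene_id = c("G1", "G2"))
  res <- fit_pair_association(cg, ch, samples, pairs,
                              sf_gene = unit_sf(cg), sf_herv = unit_sf(ch))
  r1 <- res[res$gene_id == "G1", ]
  expect_equal(r1$beta, 1, tolerance = 1e-12)
  expect_equal(r1$spearman_rho, 1)

  ranked <- rank_top_associations(
    structure(
      tibble::tibble(
        herv_id = c("a", "b", "c"), gene_id = c("x", "y", "z"),
        beta = 1, se = 0.1, p_value = 0.001,
        q_value = c(0.01, 0.001, 0.01),
        spearman_rho = c(0.9, 0.5, 0.5),
        significant = TRUE
      ),
      class = c("herv_assoc", class(tibble::tibble()))
    ),
    k = 5
  )
  expect_equal(ranked$herv_id, c("a", "b", "c")) # tie broken by smaller q
  expect_equal(nrow(rank_top_associations(ranked, k = 2)), 2)
})

test_that("null pairs are calibrated and planted shared effects are recovered", {
  withr::local_seed(23)
  n <- 48
  samples <- samples_tbl(rep(c("case", "control"), each = n / 2))
  # 300 independent null pairs
  cg <- counts_tbl(matrix(rnbinom(300 * n, mu = 100, size = 10), 300),
                   feature_ids = sprintf("G%03d", 1:300))
  ch <- counts_tbl(matrix(rnbinom(300 * n, mu = 50, size = 10), 300),
                   feature_ids = sprintf("H%03d", 1:300))
  pairs <- tibble::tibble(herv_id = sprintf("H%03d", 1:300),
                          gene_id = sprintf("G%03d", 1:300))
  res <- fit_pair_association(cg, ch, samples, pairs,
                              sf_gene = unit_sf(cg), sf_herv = unit_sf(ch))
  rate <- mean(res$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 0.01)
  expect_lte(mean(res$significant), 0.02)

  # planted: gene and HERV share a condition effect
  cond <- as.numeric(samples$condition == "case")
  g_link <- rnbinom(n, mu = 100 * 2^(2 * cond), size = 10)
  h_link <- rnbinom(n, mu = 50 * 2^(2 * cond), size = 10)
  cg2 <- counts_tbl(rbind(as.matrix(cg[-1]), GL = g_link),
                    feature_ids = c(cg$feature_id, "GL"))
  ch2 <- counts_tbl(rbind(as.matrix(ch[-1]), HL = h_link),
                    feature_ids = c(ch$feature_id, "HL"))
  res2 <- fit_pair_association(
    cg2, ch2, samples,
    dplyr::bind_rows(pairs, tibble::tibble(herv_id = "HL", gene_id = "GL")),
    sf_gene = unit_sf(cg2), sf_herv = unit_sf(ch2)
  )
  linked <- res2[res2$herv_id == "HL", ]
  expect_true(linked$significant)
  expect_gt(linked$spearman_rho, 0.5)
})

test_that("pair association is invariant to joint sample permutation and monotone transforms", {
  withr::local_seed(52)
  n <- 20
  samples <- samples_tbl(rep(c("case", "control"), each = n / 2))
  cg <- counts_tbl(matrix(rnbinom(5 * n, mu = 80, size = 5), 5),
                   feature_ids = sprintf("G%d", 1:5))
  ch <- counts_tbl(matrix(rnbinom(5 * n, mu = 40, size = 5), 5),
                   feature_ids = sprintf("H%d", 1:5))
  pairs <- tibble::tibble(herv_id = sprintf("H%d", 1:5),
                          gene_id = sprintf("G%d", 1:5))
  res <- fit_pair_association(cg, ch, samples, pairs,
                              sf_gene = unit_sf(cg), sf_herv = unit_sf(ch))

  perm <- sample(names(cg)[-1])
  cg_p <- cg[c("feature_id", perm)]
  ch_p <- ch[c("feature_id", perm)]
  res_p <- fit_pair_association(cg_p, ch_p, samples, pairs,
                                sf_gene = unit_sf(cg), sf_herv = unit_sf(ch))
  expect_equal(res$beta, res_p$beta, tolerance = 1e-12)
  expect_equal(res$spearman_rho, res_p$spearman_rho)

  # scaling HERV counts is monotone on the transformed scale: rho unchanged
  ch_s <- dplyr::mutate(ch, dplyr::across(-feature_id, ~ .x * 7))
  res_s <- fit_pair_association(cg, ch_s, samples, pairs,
                                sf_gene = unit_sf(cg), sf_herv = unit_sf(ch))
  expect_equal(res$spearman_rho, res_s$spearman_rho)

  expect_error(
    fit_pair_association(cg[1:3], ch, samples, pairs),
    "Sample columns"
  )
})

test_that("condition betas track DE fold changes on planted data", {
  cfg <- tiny_cfg(n_genes = 500, n_hervs = 20, frac_de_genes = 0.15,
                  mean_log_mu = log(300), sd_log_mu = 0.6, herv_mu_scale = 1,
                  n_case = c(30, 10), n_control = c(30, 10))
  st <- simulate_study(cfg)
  d1 <- st$datasets$dataset1
  de <- nb_de_test(d1$counts, d1$samples)
  cb <- fit_condition_model(d1$counts, d1$samples)
  shared <- intersect(de$feature_id, cb$feature_id)
  rc <- cor(
    de$log2fc[match(shared, de$feature_id)],
    cb$beta[match(shared, cb$feature_id)],
    method = "spearman"
  )
  expect_gt(rc, 0.9)
})
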