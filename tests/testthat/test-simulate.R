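test_that("the generator is deterministic given the configuration", {
  cfg <- tiny_cfg()
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1$annotation$genes, a2$annotation$genes)
  expect_identical(a1$annotation$hervs, a2$annotation$hervs)
  expect_identical(a1$truth, a2$truth)

  c1 <- simulate_counts(cfg, a1$annotation, a1$truth)
  c2 <- simulate_counts(cfg, a2$annotation, a2$truth)
  expect_identical(c1$datasets$dataset1$counts, c2$datasets$dataset1$counts)
  expect_identical(c1$truth$features, c2$truth$features)

  g1 <- simulate_gene_sets(cfg, c1$truth)
  g2 <- simulate_gene_sets(cfg, c2$truth)
  expect_identical(g1$sets$members, g2$sets$members)

  cfg_b <- tiny_cfg(seed = 202)
  a3 <- simulate_annotation(cfg_b)
  expect_false(identical(a1$annotation$hervs$start, a3$annotation$hervs$start))
})

test_that("proximity linkage probability 1 forces a DE gene near every DE HERV", {
  cfg <- tiny_cfg(proximity_link_prob = 1)
  a <- simulate_annotation(cfg)
  linked <- unique(a$truth$links$herv_id)
  expect_setequal(linked, a$truth$de_hervs_ds1)
  expect_true(all(a$truth$links$distance <= cfg$link_dist_bp))
  expect_true(all(a$truth$links$gene_id %in% a$truth$de_genes_ds1))
  # and the recorded distances agree with the placed coordinates
  h <- a$annotation$hervs
  g <- a$annotation$genes
  for (i in seq_len(min(nrow(a$truth$links), 20))) {
    lk <- a$truth$links[i, ]
    hv <- h[h$locus_id == lk$herv_id, ]
    gn <- g[g$gene_id == lk$gene_id, ]
    gap <- max(0, gn$start - hv$end, hv$start - gn$end)
    expect_equal(gap, lk$distance)
  }

  cfg0 <- tiny_cfg(proximity_link_prob = 0)
  a0 <- simulate_annotation(cfg0)
  expect_equal(nrow(a0$truth$links), 0)
})

test_that("null simulations concentrate case/control mean ratios near 1", {
  cfg <- tiny_cfg(
    lfc_magnitude = 0, n_genes = 400, n_hervs = 20,
    n_case = c(50, 10), n_control = c(50, 10),
    mean_log_mu = log(300), sd_log_mu = 0.4, herv_mu_scale = 1
  )
  a <- simulate_annotation(cfg)
  cc <- simulate_counts(cfg, a$annotation, a$truth)
  d1 <- cc$datasets$dataset1
  m <- as.matrix(d1$counts[-1])
  case <- d1$samples$condition == "case"
  ratio <- rowMeans(m[, case]) / rowMeans(m[, !case])
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.25)
})

test_that("planted fold changes shift case means by the planted factor", {
  cfg <- tiny_cfg(
    n_case = c(60, 10), n_control = c(60, 10),
    library_size_range = c(1, 1),
    mean_log_mu = log(200), sd_log_mu = 0.3, herv_mu_scale = 1
  )
  a <- simulate_annotation(cfg)
  cc <- simulate_counts(cfg, a$annotation, a$truth)
  tr <- cc$truth$features
  d1 <- cc$datasets$dataset1
  m <- as.matrix(d1$counts[-1])
  case <- d1$samples$condition == "case"
  idx <- which(tr$de_ds1 & abs(tr$lfc_ds1) > 0.5)
  obs_lfc <- log2(rowMeans(m[idx, case]) / rowMeans(m[idx, !case]))
  # NB sampling error at n = 60, dispersion 0.1: se(lfc) ~ 0.06-0.1
  expect_lt(median(abs(obs_lfc - tr$lfc_ds1[idx])), 0.12)
})

test_that("shared_de_frac = 1 with equal DE counts copies dataset 1's DE set", {
  cfg <- tiny_cfg(shared_de_frac = 1)
  a <- simulate_annotation(cfg)
  cc <- simulate_counts(cfg, a$annotation, a$truth)
  tr <- cc$truth
  expect_setequal(tr$de_genes_ds2, tr$de_genes_ds1)
  expect_setequal(tr$de_hervs_ds2, tr$de_hervs_ds1)
  # shared features keep the same planted effect
  f <- tr$features
  expect_identical(f$lfc_ds2[f$de_ds1], f$lfc_ds1[f$de_ds1])
})

test_that("fragment generation conserves counts and honours the ambiguity knobs", {
  cfg <- tiny_cfg(n_hervs = 40, ambiguity_group_size = 4, best_hit_prob = 1,
                  herv_mu_scale = 0.2)
  st <- simulate_study(cfg, fragments = TRUE,
                       fragment_samples = "DS1_S01")
  fr <- st$fragments[["DS1_S01"]]
  herv_counts <- dplyr::filter(
    st$datasets$dataset1$counts,
    feature_id %in% st$annotation$hervs$locus_id
  )
  # conservation: per-locus true-origin tallies equal the count column
  tally <- table(fr$origins$true_locus)
  cvec <- stats::setNames(herv_counts$DS1_S01, herv_counts$feature_id)
  expect_true(all(cvec[names(tally)] == as.integer(tally)))
  expect_equal(sum(cvec), nrow(fr$origins))

  # best_hit_prob = 1: the true locus has the strictly best score
  joined <- dplyr::inner_join(fr$alignments, fr$origins, by = "fragment_id")
  worst <- joined |>
    dplyr::group_by(fragment_id) |>
    dplyr::summarise(
      ok = score[locus_id == true_locus[1]][1] > max(score[locus_id != true_locus[1]], -Inf),
      .groups = "drop"
    )
  expect_true(all(worst$ok))

  # ambiguity_group_size = 1: every fragment has exactly one candidate
  cfg1 <- tiny_cfg(n_hervs = 30, ambiguity_group_size = 1, herv_mu_scale = 0.2)
  st1 <- simulate_study(cfg1, fragments = TRUE, fragment_samples = "DS1_S01")
  al1 <- st1$fragments[["DS1_S01"]]$alignments
  expect_true(all(table(al1$fragment_id) == 1))

  expect_error(
    simulate_fragments(tiny_cfg(n_hervs = 40, ambiguity_group_size = 41),
                       st$annotation, st$datasets$dataset1),
    "exceeds"
  )
})

test_that("planted gene sets are enriched in upregulated DE genes", {
  cfg <- tiny_cfg()
  st <- simulate_study(cfg)
  tr <- st$truth$features
  de_up <- tr$feature_id[tr$type == "gene" & tr$de_ds1 & tr$lfc_ds1 > 0]
  for (nm in st$truth$enriched_sets) {
    members <- st$gene_sets$members[[which(st$gene_sets$set_name == nm)]]
    expect_gte(mean(members %in% de_up), 0.75)
  }
  # background sets sit near the global DE-up rate
  bg <- setdiff(st$gene_sets$set_name, st$truth$enriched_sets)
  rates <- vapply(bg, function(nm) {
    mean(st$gene_sets$members[[which(st$gene_sets$set_name == nm)]] %in% de_up)
  }, 0)
  expect_lt(mean(rates), 0.3)

  expect_error(
    simulate_study(tiny_cfg(frac_de_genes = 0.01, set_size_range = c(40, 50))),
    "Not enough"
  )
})
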