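make_scores <- function(values, prefix = "F") {
  tibble::tibble(
    feature_id = sprintf("%s%03d", prefix, seq_along(values)),
    score = values
  )
}

one_set <- function(members, name = "S1") {
  structure(
    tibble::tibble(set_name = name, description = "t", members = list(members)),
    class = c("gene_sets", class(tibble::tibble()))
  )
}

test_that("sets holding the top scores match the exact rank-sum enumeration", {
  withr::local_seed(19)
  for (rep in 1:6) {
    n <- sample(8:12, 1)
    k <- sample(2:4, 1)
    vals <- sample(seq(0.1, 10, by = 0.1), n) # tie-free
    scores <- make_scores(vals)
    members <- scores$feature_id[order(-vals)][1:k] # the top-k scorers
    res <- score_enrichment(scores, one_set(members), min_set_size = 2)
    expect_equal(
      res$p_value,
      oracle_mw_p(vals[match(members, scores$feature_id)],
                  vals[-match(members, scores$feature_id)]),
      tolerance = 1e-12
    )
    expect_equal(res$direction, "up")
  }
})

test_that("null sets reject at the nominal rate", {
  withr::local_seed(29)
  vals <- rnorm(400)
  scores <- make_scores(vals)
  n_sets <- 400
  sets <- structure(
    tibble::tibble(
      set_name = sprintf("NULL%03d", 1:n_sets),
      description = "null",
      members = replicate(n_sets, sample(scores$feature_id, 20),
                          simplify = FALSE)
    ),
    class = c("gene_sets", class(tibble::tibble()))
  )
  res <- score_enrichment(scores, sets)
  rate <- mean(res$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sets) + 0.015)
  expect_equal(nrow(res), n_sets)
})

test_that("planted 75%-DE-up sets are significant, up, with high DE fraction", {
  withr::local_seed(37)
  n_bg <- 800
  de_up <- sprintf("DE%03d", 1:80)
  bg <- sprintf("BG%03d", 1:n_bg)
  scores <- dplyr::bind_rows(
    tibble::tibble(feature_id = bg, score = rnorm(n_bg, 0, 0.3)),
    tibble::tibble(feature_id = de_up, score = rnorm(80, 2, 0.5))
  )
  planted <- lapply(1:5, function(i) {
    c(sample(de_up, 30), sample(bg, 10))
  })
  background <- replicate(50, sample(c(bg, de_up), 40), simplify = FALSE)
  sets <- structure(
    tibble::tibble(
      set_name = c(sprintf("PL%02d", 1:5), sprintf("BG%02d", 1:50)),
      description = "t",
      members = c(planted, background)
    ),
    class = c("gene_sets", class(tibble::tibble()))
  )
  res <- score_enrichment(scores, sets, q_threshold = 0.1, de_ids = de_up)
  pl <- res[res$set_name %in% sprintf("PL%02d", 1:5), ]
  expect_true(all(pl$significant))
  expect_true(all(pl$direction == "up"))
  expect_true(all(pl$frac_de >= 0.75))
})

test_that("rank-based enrichment is invariant to monotone score transforms and set order", {
  withr::local_seed(43)
  scores <- make_scores(rnorm(100))
  sets <- structure(
    tibble::tibble(
      set_name = c("A", "B", "C"),
      description = "t",
      members = list(
        sample(scores$feature_id, 15),
        sample(scores$feature_id, 25),
        sample(scores$feature_id, 10)
      )
    ),
    class = c("gene_sets", class(tibble::tibble()))
  )
  res <- score_enrichment(scores, sets)
  scores2 <- dplyr::mutate(scores, score = exp(score))
  res2 <- score_enrichment(scores2, sets)
  expect_equal(res$p_value, res2$p_value)

  res_rev <- score_enrichment(scores, sets[3:1, ])
  expect_equal(
    dplyr::arrange(tibble::as_tibble(res), set_name)$q_value,
    dplyr::arrange(tibble::as_tibble(res_rev), set_name)$q_value
  )

  # the KS alternative runs and agrees on the strongest signal
  res_ks <- score_enrichment(scores, sets, method = "ks")
  expect_true(all(res_ks$p_value >= 0 & res_ks$p_value <= 1))
})

test_that("small sets are skipped and diluting a set weakens its statistic", {
  scores <- make_scores(c(rnorm(50), rnorm(10, 3)))
  strong <- scores$feature_id[51:60]
  sets <- structure(
    tibble::tibble(
      set_name = c("STRONG", "TINY"),
      description = "t",
      members = list(strong, strong[1:2])
    ),
    class = c("gene_sets", class(tibble::tibble()))
  )
  res <- score_enrichment(scores, sets, min_set_size = 5)
  expect_equal(res$set_name, "STRONG")
  expect_equal(attr(res, "skipped_sets"), "TINY")

  withr::local_seed(53)
  p_diluted <- replicate(30, {
    vals <- c(rnorm(100), rnorm(10, 3))
    sc <- make_scores(vals)
    mem <- sc$feature_id[101:110]
    dil <- c(mem, sample(sc$feature_id[1:100], 40))
    s2 <- structure(
      tibble::tibble(set_name = c("M", "D"), description = "t",
                     members = list(mem, dil)),
      class = c("gene_sets", class(tibble::tibble()))
    )
    r <- score_enrichment(sc, s2)
    r$p_value[r$set_name == "D"] - r$p_value[r$set_name == "M"]
  })
  expect_gt(mean(p_diluted), 0)
})

test_that("overrepresentation matches the hypergeometric oracle", {
  universe <- sprintf("U%03d", 1:20)
  de <- universe[1:10]
  res <- overrepresentation_test(de, universe, one_set(de))
  # DE = set exactly: the minimal attainable p for those margins
  expect_equal(res$p_value, oracle_hyper_greater(10, 10, 10, 20))
  expect_lt(res$p_value, 1e-4)

  # DE rate inside the set equals the global rate
  even_set <- one_set(c(universe[1:5], universe[11:15]))
  res_even <- overrepresentation_test(de, universe, even_set)
  expect_gte(res_even$p_value, 0.5)

  withr::local_seed(61)
  for (rep in 1:10) {
    uni <- sprintf("U%03d", 1:sample(10:20, 1))
    de_i <- sample(uni, sample(2:6, 1))
    set_i <- sample(uni, sample(3:8, 1))
    r <- overrepresentation_test(de_i, uni, one_set(set_i))
    expect_equal(
      r$p_value,
      oracle_hyper_greater(length(intersect(de_i, set_i)), length(de_i),
                           length(set_i), length(uni)),
      tolerance = 1e-12
    )
  }
  expect_error(overrepresentation_test(de, character(0), one_set(de)), "universe")
  expect_error(overrepresentation_test("zzz", universe, one_set(de)), "subset")
})
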