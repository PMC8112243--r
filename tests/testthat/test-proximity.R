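simple_ann <- function() {
  genes <- dplyr::bind_rows(
    gene_row("G1", "chr1", 11200, 12000),
    gene_row("G2", "chr1", 40000, 60000, biotype = "lncRNA"),
    gene_row("G3", "chr2", 100000, 101000)
  )
  exons <- tibble::tibble(
    gene_id = c("G1", "G2"), chrom = "chr1",
    start = c(11200, 40000), end = c(11500, 41000)
  )
  hervs <- dplyr::bind_rows(
    herv_row("MER4_1p1.1", "chr1", 10000, 11000),   # 200 bp before G1
    herv_row("MER4_1p1.2", "chr1", 45000, 46000),   # inside G2, intron
    herv_row("MER4_1p1.3", "chr1", 40500, 40800),   # inside G2 exon
    herv_row("HERVK_2q1.1", "chr2", 200000, 201000) # nothing within 10 kb
  )
  mini_annotation(genes, hervs, exons)
}

test_that("window expansion finds proximal, intronic, exonic and absent genes", {
  prox <- find_nearest_genes(simple_ann())
  rec <- function(id) prox[prox$herv_id == id, ]

  r1 <- rec("MER4_1p1.1")
  expect_equal(r1$nearest_gene_id, "G1")
  expect_equal(r1$distance_bp, 200L)
  expect_equal(r1$relation, "proximal")

  r2 <- rec("MER4_1p1.2")
  expect_equal(r2$relation, "intronic")
  expect_equal(r2$distance_bp, 0L)
  expect_equal(r2$nearest_gene_id, "G2")

  r3 <- rec("MER4_1p1.3")
  expect_equal(r3$relation, "exonic")

  r4 <- rec("HERVK_2q1.1")
  expect_equal(r4$relation, "none_within_limit")
  expect_true(is.na(r4$nearest_gene_id))
})

test_that("a gene exactly at the window limit is out of reach", {
  genes <- gene_row("G1", "chr1", 21000, 22000)
  hervs <- herv_row("MER4_1", "chr1", 10000, 11000) # gap exactly 10,000
  prox <- find_nearest_genes(mini_annotation(genes, hervs))
  expect_equal(prox$relation, "none_within_limit")
  # one base closer and it is found
  genes2 <- gene_row("G1", "chr1", 20999, 22000)
  prox2 <- find_nearest_genes(mini_annotation(genes2, hervs))
  expect_equal(prox2$relation, "proximal")
  expect_equal(prox2$distance_bp, 9999L)
})

test_that("all overlapped elements are reported for multi-intersecting HERVs", {
  genes <- dplyr::bind_rows(
    gene_row("PC1", "chr1", 1000, 9000),
    gene_row("LNC1", "chr1", 4000, 5000, biotype = "lncRNA")
  )
  exons <- tibble::tibble(
    gene_id = c("PC1", "LNC1"), chrom = "chr1",
    start = c(1000, 4000), end = c(1200, 5000)
  )
  hervs <- herv_row("MER4_1", "chr1", 4200, 4800) # PC1 intron + LNC1 exon
  prox <- find_nearest_genes(mini_annotation(genes, hervs, exons))
  el <- prox$intersected[[1]]
  expect_equal(nrow(el), 2)
  expect_setequal(el$gene_id, c("PC1", "LNC1"))
  expect_equal(el$region[el$gene_id == "PC1"], "intron")
  expect_equal(el$region[el$gene_id == "LNC1"], "exon")
  expect_equal(prox$relation, "exonic")
  expect_equal(prox$n_intersected, 2)
})

test_that("reported distances match a brute-force all-pairs scan", {
  withr::local_seed(12)
  for (rep in 1:5) {
    genes <- gene_row(sprintf("G%02d", 1:25), "chr1",
                      start = sort(sample.int(2e5, 25)) * 3L, end = 0L)
    genes$end <- genes$start + sample(500:5000, 25, replace = TRUE)
    hervs <- herv_row(sprintf("MER4_%d", 1:10), "chr1",
                      start = sample.int(6e5, 10), end = 0L)
    hervs$end <- hervs$start + 800L
    ann <- mini_annotation(genes, hervs)
    prox <- find_nearest_genes(ann)
    for (i in seq_len(nrow(hervs))) {
      h <- ann$hervs[ann$hervs$locus_id == prox$herv_id[i], ]
      expected <- oracle_nearest_distance(h, ann$genes)
      if (is.na(expected)) {
        expect_equal(prox$relation[i], "none_within_limit")
      } else {
        expect_equal(prox$distance_bp[i], expected)
      }
    }
  }
})

test_that("results do not depend on gene storage order or a larger window", {
  withr::local_seed(4)
  genes <- gene_row(sprintf("G%02d", 1:15), "chr1",
                    start = sample.int(1e5, 15), end = 0L)
  genes$end <- genes$start + 1000L
  hervs <- herv_row(sprintf("MER4_%d", 1:6), "chr1",
                    start = sample.int(1e5, 6), end = 0L)
  hervs$end <- hervs$start + 500L
  a1 <- mini_annotation(genes, hervs)
  a2 <- mini_annotation(genes[sample.int(15), ], hervs)
  p1 <- find_nearest_genes(a1)
  p2 <- find_nearest_genes(a2)
  expect_equal(p1$nearest_gene_id, p2$nearest_gene_id)
  expect_equal(p1$distance_bp, p2$distance_bp)

  p_wide <- find_nearest_genes(a1, max_window_bp = 20000)
  found <- p1$relation != "none_within_limit"
  expect_equal(p_wide$nearest_gene_id[found], p1$nearest_gene_id[found])
  expect_equal(p_wide$distance_bp[found], p1$distance_bp[found])
})

test_that("intersection tallies count relations, biotypes and multiplicity", {
  prox <- find_nearest_genes(simple_ann())
  tally <- classify_intersections(prox)
  expect_equal(
    tally$relations$n,
    c(exonic = 1L, intronic = 1L, proximal = 1L, none_within_limit = 1L),
    ignore_attr = TRUE
  )
  expect_equal(tally$n_multi, 0)
  expect_equal(sum(tally$by_biotype$n), 2) # the two overlapping records

  empty <- classify_intersections(prox[0, ])
  expect_true(all(empty$relations$n == 0))
  expect_equal(empty$n_multi, 0)
})

test_that("complete separation of distances gives a tiny rank-sum p", {
  mk <- mk_prox
  res <- distance_null_test(mk(rep(0L, 20)), mk(rep(10001L, 20)))
  expect_lt(res$p_value, 1e-6)
  expect_lt(res$median_distance_de, res$median_distance_non_de)

  # exact small-sample agreement with the enumeration oracle (tie-free)
  withr::local_seed(2)
  for (rep in 1:8) {
    x <- sample.int(10000, sample(3:6, 1))
    y <- sample(10001:20000, sample(3:6, 1))
    res <- distance_null_test(mk(x), mk(y))
    expect_equal(res$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
  }

  # censoring turns unfound records into max_window + 1 distances
  res_c <- distance_null_test(
    mk(rep(0L, 10)),
    mk(rep(NA_integer_, 10), rel = "none_within_limit"),
    unfound = "censor", max_window_bp = 10000
  )
  expect_equal(res_c$median_distance_non_de, 10001)
  expect_error(
    distance_null_test(mk(integer(0)), mk(rep(1L, 3))),
    "at least one"
  )
})

test_that("the distance test is calibrated when both groups share a distribution", {
  withr::local_seed(77)
  n_rep <- 300
  p <- replicate(n_rep, {
    d1 <- sample.int(10000, 15)
    d2 <- sample.int(10000, 20)
    distance_null_test(mk_prox(d1), mk_prox(d2))$p_value
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})
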