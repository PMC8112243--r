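#' Configuration for a synthetic two-dataset HERV study
#'
#' Defines the study conditions emulated by the generator: two whole-blood
#' case/control datasets (default sizes 25/23 and 99/18), negative-binomial
#' counts with a minority of planted differentially expressed features that
#' are mostly upregulated, a planted cross-dataset overlap of DE sets, HERV
#' loci placed with tunable physical linkage to DE genes, HERV
#' family/coding/enhancer labels, and ambiguous multi-locus fragment
#' assignments within HERV families.
#'
#' @param seed Integer RNG seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @param n_chroms,chrom_length_bp Number and length (bp) of chromosomes.
#' @param n_genes,n_hervs Number of gene and HERV features.
#' @param n_case,n_control Length-2 integer vectors: cases and controls in
#'   datasets 1 and 2.
#' @param frac_de_genes,frac_de_hervs Fraction of features planted as DE.
#' @param frac_de_up Fraction of planted DE effects that are upregulated.
#' @param lfc_magnitude Planted |log2 fold change| for DE features.
#' @param nb_dispersion Negative-binomial dispersion alpha in
#'   `var = mu + alpha * mu^2`; constant across features. `0` gives Poisson.
#' @param mean_log_mu,sd_log_mu Log-normal baseline mean expression of genes.
#' @param herv_mu_scale Multiplier on baseline means for HERV loci (HERVs are
#'   expressed far below genes in whole blood; default 1/30).
#' @param library_size_range Range of per-sample size factors (uniform draw).
#' @param proximity_link_prob Probability that a planted DE HERV is placed
#'   within `link_dist_bp` of a planted DE gene.
#' @param link_dist_bp Linkage distance cap in bp.
#' @param shared_de_frac Fraction of dataset 2's planted DE features reused
#'   from dataset 1's DE set.
#' @param coding_rate,enhancer_rate Bernoulli rates of the HERV
#'   coding-potential and enhancer flags.
#' @param n_gene_sets,set_size_range,n_enriched_sets Gene-set collection
#'   shape; enriched sets draw `enrichment_frac` of members from DE-up genes.
#' @param enrichment_frac Minimum DE-up member fraction in enriched sets.
#' @param ambiguity_group_size Loci per shared-fragment family group.
#' @param best_hit_prob Probability that a fragment's true locus receives the
#'   strictly best alignment score among its candidates.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 20210427,
                       n_chroms = 4, chrom_length_bp = 3e7,
                       n_genes = 2000, n_hervs = 500,
                       n_case = c(25, 99), n_control = c(23, 18),
                       frac_de_genes = 0.05, frac_de_hervs = 0.05,
                       frac_de_up = 0.95,
                       lfc_magnitude = 1.5,
                       nb_dispersion = 0.1,
                       mean_log_mu = log(300), sd_log_mu = 1.2,
                       herv_mu_scale = 1 / 30,
                       library_size_range = c(0.7, 1.4),
                       proximity_link_prob = 0.5, link_dist_bp = 10000,
                       shared_de_frac = 0.4,
                       coding_rate = 0.10, enhancer_rate = 0.10,
                       n_gene_sets = 50, set_size_range = c(20, 60),
                       n_enriched_sets = 5, enrichment_frac = 0.75,
                       ambiguity_group_size = 3, best_hit_prob = 0.7) {
  cfg <- as.list(environment())
  fracs <- c(
    frac_de_genes, frac_de_hervs, frac_de_up, proximity_link_prob,
    shared_de_frac, coding_rate, enhancer_rate, enrichment_frac, best_hit_prob
  )
  if (any(fracs < 0 | fracs > 1)) abort("All fractions must lie in [0, 1].")
  if (any(c(n_case, n_control) < 2)) abort("n_case and n_control must be >= 2.")
  if (length(n_case) != 2 || length(n_control) != 2) {
    abort("n_case and n_control must have one entry per dataset (length 2).")
  }
  if (lfc_magnitude < 0) abort("lfc_magnitude must be non-negative.")
  if (nb_dispersion < 0) abort("nb_dispersion must be non-negative.")
  if (ambiguity_group_size < 1) abort("ambiguity_group_size must be >= 1.")
  if (n_enriched_sets > n_gene_sets) abort("n_enriched_sets exceeds n_gene_sets.")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome annotation with planted HERV-gene linkage
#'
#' Genes are placed uniformly with exon/intron structure. HERV loci that the
#' truth table designates DE are, with probability `proximity_link_prob`,
#' placed within `link_dist_bp` of a DE-designated gene (including intronic /
#' exonic placements); all other loci are placed uniformly. Families come
#' from a fixed catalogue (ERV-L, ERV3, MER4, HERV-H, HERV-K, HERV-L and
#' others) and coding/enhancer flags are Bernoulli.
#'
#' @param cfg A [sim_config()].
#' @return List with `annotation` (a [annotation()]) and `truth` (partial
#'   truth: dataset-1 DE designations and the planted `links` table of
#'   `herv_id`, `gene_id`, `distance`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_annotation_impl(cfg))
}

herv_family_catalogue <- c(
  "ERVL" = 0.17, "ERV3" = 0.14, "MER4" = 0.14, "HERVH" = 0.12,
  "HERVK" = 0.10, "HERVL" = 0.10, "ERV316A3" = 0.08, "HARLEQUIN" = 0.06,
  "LTR19" = 0.05, "HERVS" = 0.04
)

simulate_annotation_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  clen <- cfg$chrom_length_bp

  gene_len <- pmin(pmax(round(stats::rlnorm(cfg$n_genes, log(8000), 0.8)), 200), 2e5)
  if (any(gene_len >= clen)) abort("Chromosome too short to place requested genes.")
  gene_chrom <- sample(chroms, cfg$n_genes, replace = TRUE)
  gene_start <- vapply(gene_len, function(L) sample.int(clen - L, 1L) - 1L, 1L)
  genes <- tibble(
    gene_id = sprintf("G%05d", seq_len(cfg$n_genes)),
    symbol = sprintf("GENE%d", seq_len(cfg$n_genes)),
    biotype = sample(
      c("protein_coding", "lncRNA", "pseudogene", "other"),
      cfg$n_genes, replace = TRUE, prob = c(0.45, 0.35, 0.12, 0.08)
    ),
    chrom = gene_chrom,
    start = as.integer(gene_start),
    end = as.integer(gene_start + gene_len),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  )
  exons <- simulate_exons(genes)

  n_de_g <- round(cfg$frac_de_genes * cfg$n_genes)
  n_de_h <- round(cfg$frac_de_hervs * cfg$n_hervs)
  de_genes <- sort(sample(genes$gene_id, n_de_g))
  de_idx <- sort(sample.int(cfg$n_hervs, n_de_h))

  herv_len <- sample(500:3000, cfg$n_hervs, replace = TRUE)
  if (any(herv_len >= clen)) abort("Chromosome too short to place requested HERVs.")
  herv_chrom <- sample(chroms, cfg$n_hervs, replace = TRUE)
  herv_start <- vapply(herv_len, function(L) sample.int(clen - L, 1L) - 1L, 1L)

  # Linked placement: planted DE HERVs land near planted DE genes.
  de_gene_tbl <- filter(genes, .data$gene_id %in% de_genes)
  links <- list()
  if (n_de_h > 0 && nrow(de_gene_tbl) > 0 && cfg$proximity_link_prob > 0) {
    for (i in de_idx) {
      if (runif(1) >= cfg$proximity_link_prob) next
      g <- de_gene_tbl[sample.int(nrow(de_gene_tbl), 1L), ]
      L <- herv_len[i]
      if (runif(1) < 0.4) {
        # overlapping placement (intronic or exonic)
        s <- g$start + sample.int(max(1L, g$end - g$start), 1L) - 1L - sample.int(L, 1L) + 1L
      } else {
        gap <- sample.int(cfg$link_dist_bp, 1L) - 1L
        s <- if (runif(1) < 0.5) g$end + gap else g$start - gap - L
      }
      s <- max(0L, min(as.integer(s), clen - L))
      herv_chrom[i] <- g$chrom
      herv_start[i] <- s
      d <- interval_gap(s, s + L, g$start, g$end)
      if (d <= cfg$link_dist_bp) {
        links[[length(links) + 1L]] <- tibble(
          herv_idx = i, gene_id = g$gene_id, distance = as.integer(d)
        )
      }
    }
  }

  family <- sample(
    names(herv_family_catalogue), cfg$n_hervs,
    replace = TRUE, prob = herv_family_catalogue
  )
  band <- sprintf(
    "%s%s%d.%d",
    sub("chr", "", herv_chrom),
    ifelse(herv_start > clen / 2, "q", "p"),
    11L + (as.integer(herv_start) %/% max(1L, clen %/% 25L)),
    1L + (as.integer(herv_start) %/% 1000L) %% 3L
  )
  locus_id <- paste0(family, "_", band)
  # cytoband collisions get a letter suffix, mirroring ids like ERV316A3_3q27.3e
  dup_rank <- stats::ave(seq_along(locus_id), locus_id, FUN = seq_along)
  locus_id <- ifelse(dup_rank > 1, paste0(locus_id, letters[pmin(dup_rank - 1L, 26L)]), locus_id)
  if (anyDuplicated(locus_id)) {
    locus_id <- make.unique(locus_id, sep = "x")
  }

  hervs <- tibble(
    locus_id = locus_id,
    family = family,
    chrom = herv_chrom,
    start = as.integer(herv_start),
    end = as.integer(herv_start + herv_len),
    strand = sample(c("+", "-"), cfg$n_hervs, replace = TRUE),
    is_coding = runif(cfg$n_hervs) < cfg$coding_rate,
    in_enhancer = runif(cfg$n_hervs) < cfg$enhancer_rate
  )

  links <- if (length(links) > 0) {
    bind_rows(links) %>%
      mutate(herv_id = locus_id[.data$herv_idx], .before = 1) %>%
      select("herv_id", "gene_id", "distance")
  } else {
    tibble(herv_id = character(), gene_id = character(), distance = integer())
  }

  truth <- list(
    de_genes_ds1 = de_genes,
    de_hervs_ds1 = sort(locus_id[de_idx]),
    links = links
  )
  list(annotation = annotation(genes, hervs, exons), truth = truth)
}

simulate_exons <- function(genes) {
  out <- vector("list", nrow(genes))
  n_ex <- sample(1:6, nrow(genes), replace = TRUE)
  for (i in seq_len(nrow(genes))) {
    k <- n_ex[i]
    s <- genes$start[i]
    e <- genes$end[i]
    # carve k non-overlapping exons, one inside each of k equal blocks
    b <- floor(seq(s, e, length.out = k + 1))
    ex_s <- ex_e <- integer(k)
    for (j in seq_len(k)) {
      w <- b[j + 1] - b[j]
      len <- max(1L, min(w - 1L, round(w * runif(1, 0.2, 0.6))))
      off <- sample.int(max(1L, w - len), 1L) - 1L
      ex_s[j] <- b[j] + off
      ex_e[j] <- ex_s[j] + len
    }
    out[[i]] <- tibble(
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      start = as.integer(ex_s), end = as.integer(ex_e)
    )
  }
  bind_rows(out)
}

#' Simulate negative-binomial counts for both datasets
#'
#' Count of feature i in sample j is drawn from
#' `NB(mean = s_j * mu_i * 2^(lfc_i * case_j), dispersion = nb_dispersion)`
#' with size factor `s_j` uniform on `library_size_range`; `lfc_i = 0` for
#' non-planted features. Dataset 2 reuses `shared_de_frac` of dataset 1's
#' planted DE set and draws the remainder fresh, creating the planted
#' cross-dataset overlap.
#'
#' @param cfg A [sim_config()].
#' @param ann The [annotation()] from [simulate_annotation()].
#' @param truth The partial truth from [simulate_annotation()].
#' @return List with `datasets` (list of two `count_data` objects) and the
#'   completed `truth` (adds the per-feature table `features` with planted
#'   log2 fold changes and DE flags per dataset).
#' @export
simulate_counts <- function(cfg, ann, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "herv_annotation"))
  with_seed(cfg$seed + 1L, simulate_counts_impl(cfg, ann, truth))
}

simulate_counts_impl <- function(cfg, ann, truth) {
  feats <- tibble(
    feature_id = c(ann$genes$gene_id, ann$hervs$locus_id),
    type = rep(c("gene", "herv"), c(nrow(ann$genes), nrow(ann$hervs)))
  )
  n <- nrow(feats)
  feats$mu <- exp(rnorm(n, cfg$mean_log_mu, cfg$sd_log_mu)) *
    ifelse(feats$type == "herv", cfg$herv_mu_scale, 1)
  feats$mu <- pmax(feats$mu, 0.05)

  # planted |lfc| ~ Gamma with mean lfc_magnitude (shape 4: CV 0.5), so
  # effect sizes vary around the configured mean as in real studies
  draw_lfc <- function(k) {
    if (cfg$lfc_magnitude == 0) return(numeric(k))
    rgamma(k, shape = 4, rate = 4 / cfg$lfc_magnitude) *
      ifelse(runif(k) < cfg$frac_de_up, 1, -1)
  }
  de1 <- feats$feature_id %in% c(truth$de_genes_ds1, truth$de_hervs_ds1)
  feats$lfc_ds1 <- 0
  feats$lfc_ds1[de1] <- draw_lfc(sum(de1))
  feats$de_ds1 <- de1

  # dataset 2 planted DE: shared fraction from ds1, rest fresh, per class
  feats$de_ds2 <- FALSE
  feats$lfc_ds2 <- 0
  for (ty in c("gene", "herv")) {
    idx <- which(feats$type == ty)
    frac <- if (ty == "gene") cfg$frac_de_genes else cfg$frac_de_hervs
    n_de2 <- round(frac * length(idx))
    de1_idx <- idx[feats$de_ds1[idx]]
    n_shared <- min(round(cfg$shared_de_frac * n_de2), length(de1_idx))
    shared <- if (n_shared > 0) sample(de1_idx, n_shared) else integer()
    pool <- setdiff(idx, de1_idx)
    fresh <- if (n_de2 - n_shared > 0) sample(pool, min(n_de2 - n_shared, length(pool))) else integer()
    feats$de_ds2[c(shared, fresh)] <- TRUE
    feats$lfc_ds2[shared] <- feats$lfc_ds1[shared]
    feats$lfc_ds2[fresh] <- draw_lfc(length(fresh))
  }

  datasets <- lapply(1:2, function(d) {
    n_s <- cfg$n_case[d] + cfg$n_control[d]
    cond <- rep(c("case", "control"), c(cfg$n_case[d], cfg$n_control[d]))
    sf <- runif(n_s, cfg$library_size_range[1], cfg$library_size_range[2])
    lfc <- if (d == 1) feats$lfc_ds1 else feats$lfc_ds2
    mu <- outer(feats$mu, sf) * 2^(lfc %o% as.numeric(cond == "case"))
    m <- if (cfg$nb_dispersion > 0) {
      matrix(rnbinom(n * n_s, mu = mu, size = 1 / cfg$nb_dispersion), n, n_s)
    } else {
      matrix(stats::rpois(n * n_s, mu), n, n_s)
    }
    sample_id <- sprintf("DS%d_S%02d", d, seq_len(n_s))
    counts <- tibble(feature_id = feats$feature_id) %>%
      dplyr::bind_cols(as_tibble(`colnames<-`(m, sample_id)))
    structure(
      list(
        counts = counts,
        samples = tibble(sample_id = sample_id, condition = cond,
                         dataset = paste0("dataset", d))
      ),
      class = "count_data"
    )
  })
  names(datasets) <- c("dataset1", "dataset2")

  truth$features <- feats
  truth$de_genes_ds2 <- feats$feature_id[feats$de_ds2 & feats$type == "gene"]
  truth$de_hervs_ds2 <- feats$feature_id[feats$de_ds2 & feats$type == "herv"]
  list(datasets = datasets, truth = truth)
}

#' Simulate ambiguous fragment alignments for the reassignment stage
#'
#' HERV loci are partitioned into within-family groups of
#' `ambiguity_group_size`; every fragment originates from one true locus (as
#' many fragments per locus as its simulated count in the sample) and reports
#' candidate alignments to every locus in its group. The true locus receives
#' the strictly best alignment score with probability `best_hit_prob`;
#' otherwise another group member does. Scores are integers in [0, 100]; only
#' their relative order within a fragment is meaningful.
#'
#' @param cfg A [sim_config()].
#' @param ann The [annotation()].
#' @param counts A `count_data` object for one dataset.
#' @param sample_ids Samples to generate fragments for (default: all).
#' @return Named list per sample; each element has `alignments` (tibble
#'   `fragment_id`, `locus_id`, `score`) and `origins` (tibble `fragment_id`,
#'   `true_locus`).
#' @export
simulate_fragments <- function(cfg, ann, counts, sample_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "herv_annotation"))
  if (cfg$ambiguity_group_size > nrow(ann$hervs)) {
    abort("ambiguity_group_size exceeds the number of HERV loci.")
  }
  sample_ids <- sample_ids %||% counts$samples$sample_id
  groups <- herv_groups(ann$hervs, cfg$ambiguity_group_size)
  herv_counts <- filter(counts$counts, .data$feature_id %in% ann$hervs$locus_id)
  out <- lapply(seq_along(sample_ids), function(k) {
    sid <- sample_ids[k]
    if (!sid %in% names(herv_counts)) abort(paste0("Unknown sample: ", sid))
    cvec <- setNames(as.integer(round(herv_counts[[sid]])), herv_counts$feature_id)
    with_seed(cfg$seed + 1000L + match(sid, counts$samples$sample_id),
              simulate_fragments_one(cfg, groups, cvec))
  })
  names(out) <- sample_ids
  out
}

# Partition loci into within-family groups of (up to) the requested size.
herv_groups <- function(hervs, group_size) {
  split_ids <- split(sort(hervs$locus_id), herv_family(sort(hervs$locus_id)))
  groups <- list()
  for (ids in split_ids) {
    idx <- split(ids, ceiling(seq_along(ids) / group_size))
    groups <- c(groups, unname(idx))
  }
  membership <- rep(seq_along(groups), lengths(groups))
  names(membership) <- unlist(groups)
  list(groups = groups, membership = membership)
}

simulate_fragments_one <- function(cfg, groups, cvec) {
  aln <- list()
  org <- list()
  frag_counter <- 0L
  for (gi in seq_along(groups$groups)) {
    loci <- groups$groups[[gi]]
    k <- length(loci)
    cts <- cvec[loci]
    cts[is.na(cts)] <- 0L
    n_frag <- sum(cts)
    if (n_frag == 0L) next
    true_idx <- rep(seq_len(k), cts)
    # base scores in [0, 90]; strictly-best bonus of +5 on top of the max
    S <- matrix(sample.int(91L, k * n_frag, replace = TRUE) - 1L, nrow = k)
    if (k > 1) {
      best_is_true <- runif(n_frag) < cfg$best_hit_prob
      best_idx <- ifelse(
        best_is_true, true_idx,
        # a uniformly chosen candidate other than the true locus
        (true_idx - 1L + sample.int(k - 1L, n_frag, replace = TRUE)) %% k + 1L
      )
      mx <- apply(S, 2, max)
      S[cbind(best_idx, seq_len(n_frag))] <- pmin(100L, mx + 5L)
    }
    frag_id <- sprintf("F%07d", frag_counter + seq_len(n_frag))
    frag_counter <- frag_counter + n_frag
    aln[[length(aln) + 1L]] <- tibble(
      fragment_id = rep(frag_id, each = k),
      locus_id = rep(loci, times = n_frag),
      score = as.integer(S)
    )
    org[[length(org) + 1L]] <- tibble(fragment_id = frag_id, true_locus = loci[true_idx])
  }
  list(
    alignments = if (length(aln)) bind_rows(aln) else
      tibble(fragment_id = character(), locus_id = character(), score = integer()),
    origins = if (length(org)) bind_rows(org) else
      tibble(fragment_id = character(), true_locus = character())
  )
}

#' Simulate a gene-set collection with planted enriched sets
#'
#' Enriched sets draw at least `enrichment_frac` (default 75%) of their
#' members from planted upregulated DE genes; background sets draw members
#' uniformly from the gene universe.
#'
#' @param cfg A [sim_config()].
#' @param truth Completed truth from [simulate_counts()].
#' @return List with `sets` (a `gene_sets` tibble) and `enriched_set_names`.
#' @export
simulate_gene_sets <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(truth$features)) abort("truth must come from simulate_counts().")
  with_seed(cfg$seed + 2L, simulate_gene_sets_impl(cfg, truth))
}

simulate_gene_sets_impl <- function(cfg, truth) {
  genes <- filter(truth$features, .data$type == "gene")
  universe <- genes$feature_id
  de_up <- genes$feature_id[genes$de_ds1 & genes$lfc_ds1 > 0]
  sizes <- sample(cfg$set_size_range[1]:cfg$set_size_range[2],
                  cfg$n_gene_sets, replace = TRUE)
  enriched <- seq_len(cfg$n_enriched_sets)
  members <- vector("list", cfg$n_gene_sets)
  for (i in seq_len(cfg$n_gene_sets)) {
    if (i %in% enriched) {
      n_de <- ceiling(cfg$enrichment_frac * sizes[i])
      if (n_de > length(de_up)) {
        abort("Not enough planted DE-up genes to fill enriched sets.")
      }
      core <- sample(de_up, n_de)
      rest <- sample(setdiff(universe, core), sizes[i] - n_de)
      members[[i]] <- sample(c(core, rest))
    } else {
      members[[i]] <- sample(universe, sizes[i])
    }
  }
  set_name <- sprintf("PATH%03d", seq_len(cfg$n_gene_sets))
  sets <- structure(
    tibble(
      set_name = set_name,
      description = ifelse(seq_along(set_name) %in% enriched,
                           "planted enriched set", "background set"),
      members = members
    ),
    class = c("gene_sets", class(tibble()))
  )
  list(sets = sets, enriched_set_names = set_name[enriched])
}

#' Simulate a complete two-dataset synthetic study
#'
#' Convenience wrapper running [simulate_annotation()], [simulate_counts()]
#' and [simulate_gene_sets()] (and optionally [simulate_fragments()]) under
#' one configuration.
#'
#' @param cfg A [sim_config()].
#' @param fragments Generate fragment alignments for dataset 1? (default
#'   `FALSE`; they are only needed to exercise the EM reassignment stage).
#' @param fragment_samples Samples to generate fragments for when
#'   `fragments = TRUE` (default: the first two samples of dataset 1).
#' @return List of class `herv_study`: `config`, `annotation`, `datasets`,
#'   `gene_sets`, `truth` (with `enriched_sets`), and optionally `fragments`.
#' @export
simulate_study <- function(cfg = sim_config(), fragments = FALSE,
                           fragment_samples = NULL) {
  a <- simulate_annotation(cfg)
  cc <- simulate_counts(cfg, a$annotation, a$truth)
  gs <- simulate_gene_sets(cfg, cc$truth)
  truth <- cc$truth
  truth$enriched_sets <- gs$enriched_set_names
  out <- list(
    config = cfg,
    annotation = a$annotation,
    datasets = cc$datasets,
    gene_sets = gs$sets,
    truth = truth
  )
  if (fragments) {
    fragment_samples <- fragment_samples %||%
      head(cc$datasets$dataset1$samples$sample_id, 2)
    out$fragments <- simulate_fragments(
      cfg, a$annotation, cc$datasets$dataset1, fragment_samples
    )
  }
  structure(out, class = "herv_study")
}

#' Write a simulated study to disk
#'
#' Emits the annotation (GTF + BED), per-dataset counts and metadata TSVs,
#' the gene sets (GMT), truth tables (TSV) and, when present, sparse fragment
#' alignment TSVs — everything [run_pipeline()] consumes.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "herv_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  paths <- c(gtf = p("genes.gtf"), bed = p("hervs.bed"), gmt = p("gene_sets.gmt"))
  write_annotation(study$annotation, paths["gtf"], paths["bed"])
  write_gmt(study$gene_sets, paths["gmt"])
  for (d in names(study$datasets)) {
    cp <- p(paste0(d, "_counts.tsv"))
    mp <- p(paste0(d, "_samples.tsv"))
    write_counts(study$datasets[[d]], cp, mp)
    paths[paste0(d, "_counts")] <- cp
    paths[paste0(d, "_samples")] <- mp
  }
  readr::write_tsv(study$truth$features, p("truth_features.tsv"), progress = FALSE)
  readr::write_tsv(study$truth$links, p("truth_links.tsv"), progress = FALSE)
  writeLines(study$truth$enriched_sets, p("truth_enriched_sets.txt"))
  paths["truth_features"] <- p("truth_features.tsv")
  paths["truth_links"] <- p("truth_links.tsv")
  if (!is.null(study$fragments)) {
    for (sid in names(study$fragments)) {
      fp <- p(paste0("fragments_", sid, ".tsv"))
      readr::write_tsv(study$fragments[[sid]]$alignments, fp, progress = FALSE)
      paths[paste0("fragments_", sid)] <- fp
    }
  }
  invisible(paths)
}
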