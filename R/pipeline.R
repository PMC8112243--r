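#' Default pipeline configuration
#'
#' All stage parameters in one declarative list. Defaults are the standard
#' operating point of the workflow: filtering grid `s_min = 1`,
#' `s_max = 200`, `s_len = 100` with median-of-ratios normalization; DE at
#' FDR 0.05 with |log2 fold change| >= 1; proximity windows growing from
#' 500 bp to a 10 kb limit; 200,000 overlap permutations; EM reassignment
#' with `max_iter = 200` and `theta_prior = 200,000`; association q < 0.05;
#' enrichment q < 0.1.
#'
#' @param seed Global seed; every stochastic stage derives its stream from
#'   it.
#' @param paths Named list of input paths: `gtf`, `herv_bed`, `counts1`,
#'   `samples1`, `counts2`, `samples2`, `gmt`, and optionally `fragments`
#'   (character vector of sparse alignment TSVs).
#' @param out_dir Output directory for result tables and the manifest.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(seed = 20210427, paths = list(), out_dir = "results") {
  structure(
    list(
      seed = seed,
      paths = paths,
      out_dir = out_dir,
      filter = list(s_min = 1, s_max = 200, s_len = 100,
                    normalization = "median_of_ratios"),
      de = list(alpha = 0.05, lfc_threshold = 1),
      proximity = list(initial_window_bp = 500, max_window_bp = 10000,
                       expansion_step_bp = 500),
      overlap = list(n_perm = 200000),
      em = list(max_iter = 200, theta_prior = 200000, tol = 1e-6,
                lambda = 0.1, reassign_mode = "best"),
      association = list(transform = "log2_norm_plus1", q_threshold = 0.05),
      enrichment = list(method = "rank_sum", q_threshold = 0.1, min_set_size = 5)
    ),
    class = "pipeline_config"
  )
}

#' Generate and write a complete synthetic demonstration study
#'
#' Writes a two-dataset synthetic study — annotation (GTF + BED), counts and
#' sample metadata per dataset (case/control sizes 25/23 and 99/18), sparse
#' fragment alignments for a couple of samples, gene sets (GMT) and truth
#' tables — and returns a ready-to-run pipeline configuration pointing at
#' it.
#'
#' @param seed RNG seed.
#' @param out_dir Directory to write the study into.
#' @param cfg Optional [sim_config()] overriding the demo's generator
#'   settings (its seed is replaced by `seed`).
#' @return A `pipeline_config` whose paths point at the written study and
#'   whose `out_dir` is `file.path(out_dir, "results")`.
#' @export
make_demo <- function(seed = 20210427, out_dir = tempfile("herv_demo"),
                      cfg = NULL) {
  cfg <- cfg %||% sim_config(n_genes = 1500, n_hervs = 400)
  cfg$seed <- seed
  study <- simulate_study(cfg, fragments = TRUE)
  paths <- write_study(study, out_dir)
  pc <- default_config(
    seed = seed,
    paths = list(
      gtf = unname(paths["gtf"]),
      herv_bed = unname(paths["bed"]),
      counts1 = unname(paths["dataset1_counts"]),
      samples1 = unname(paths["dataset1_samples"]),
      counts2 = unname(paths["dataset2_counts"]),
      samples2 = unname(paths["dataset2_samples"]),
      gmt = unname(paths["gmt"]),
      fragments = unname(paths[grep("^fragments_", names(paths))])
    ),
    out_dir = file.path(out_dir, "results")
  )
  pc
}

#' Run the integration pipeline end to end
#'
#' Executes, in order: optional EM reassignment of fragment alignments,
#' Jaccard filtering (per dataset and per feature class, genes and HERVs
#' each with their own threshold), the NB differential-expression test, the
#' expanding-window proximity search plus the DE-vs-non-DE distance test,
#' the cross-dataset overlap permutation tests and Fisher/correlation
#' statistics, pairwise HERV-gene association models on the shared DE
#' HERVs' neighbour genes, and importance-score enrichment. Every
#' intermediate table is written to `config$out_dir` together with a
#' manifest (parameters, seed, per-stage row counts, file checksums).
#' Re-running with the same configuration and seed reproduces byte-identical
#' tables.
#'
#' @param config A `pipeline_config` (see [default_config()], [make_demo()]).
#' @return Invisibly, a list with every in-memory stage result plus the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, parameters = config[setdiff(names(config), "paths")],
                   stages = list())
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  emit <- function(tbl, file) {
    readr::write_tsv(tbl, file.path(out_dir, file), progress = FALSE)
    file
  }

  # --- load inputs -----------------------------------------------------
  p <- config$paths
  ann <- stage("annotation", read_annotation(p$gtf, p$herv_bed))
  d1 <- stage("counts", read_counts(p$counts1, p$samples1))
  d2 <- stage("counts", read_counts(p$counts2, p$samples2))
  sets <- stage("gene_sets", read_gmt(p$gmt))
  manifest$stages$inputs <- list(
    n_genes = nrow(ann$genes), n_hervs = nrow(ann$hervs),
    n_samples = c(dataset1 = nrow(d1$samples), dataset2 = nrow(d2$samples)),
    n_gene_sets = nrow(sets)
  )

  # --- optional EM reassignment ---------------------------------------
  if (!is.null(p$fragments) && length(p$fragments) > 0) {
    results$reassigned <- stage("reassign", {
      lapply(p$fragments, function(fp) {
        aln <- readr::read_tsv(fp, col_types = "cci", progress = FALSE)
        fit <- em_fit(
          aln,
          max_iter = config$em$max_iter, theta_prior = config$em$theta_prior,
          tol = config$em$tol, lambda = config$em$lambda,
          reassign_mode = config$em$reassign_mode
        )
        cts <- reassign_to_counts(fit)
        emit(cts, paste0("reassigned_", basename(fp)))
        list(fit = glance.herv_em(fit), counts = cts)
      })
    })
    manifest$stages$reassign <- list(n_files = length(p$fragments))
  }

  # --- filter + DE per dataset, per feature class ---------------------
  datasets <- list(dataset1 = d1, dataset2 = d2)
  split_class <- function(cd, ids) filter(cd$counts, .data$feature_id %in% ids)
  de_res <- list()
  filt_res <- list()
  for (dn in names(datasets)) {
    cd <- datasets[[dn]]
    for (cls in c("gene", "herv")) {
      ids <- if (cls == "gene") ann$genes$gene_id else ann$hervs$locus_id
      cm <- split_class(cd, ids)
      flt <- stage(paste0("filter_", dn, "_", cls), jaccard_threshold(
        cm, cd$samples,
        s_min = config$filter$s_min, s_max = config$filter$s_max,
        s_len = config$filter$s_len,
        normalization = config$filter$normalization
      ))
      cmf <- filter_counts(cm, flt)
      de <- stage(paste0("de_", dn, "_", cls), nb_de_test(
        cmf, cd$samples,
        alpha = config$de$alpha, lfc_threshold = config$de$lfc_threshold
      ))
      key <- paste0(dn, "_", cls)
      filt_res[[key]] <- flt
      de_res[[key]] <- de
      emit(tidy.herv_filter(flt), paste0("filter_curve_", key, ".tsv"))
      emit(as_tibble(de), paste0("de_", key, ".tsv"))
      manifest$stages[[paste0("filter_", key)]] <-
        list(s_star = flt$s_star, n_retained = flt$n_retained, n_input = flt$n_input)
      manifest$stages[[paste0("de_", key)]] <- as.list(summarize_de(de))
    }
  }
  results$filters <- filt_res
  results$de <- de_res

  # --- proximity ------------------------------------------------------
  prox <- stage("proximity", find_nearest_genes(
    ann,
    initial_window_bp = config$proximity$initial_window_bp,
    max_window_bp = config$proximity$max_window_bp,
    expansion_step_bp = config$proximity$expansion_step_bp
  ))
  de_hervs1 <- de_ids(de_res$dataset1_herv)
  prox_pc <- stage("proximity", find_nearest_genes(
    ann, gene_universe = "protein_coding",
    initial_window_bp = config$proximity$initial_window_bp,
    max_window_bp = config$proximity$max_window_bp,
    expansion_step_bp = config$proximity$expansion_step_bp
  ))
  expressed_hervs1 <- filt_res$dataset1_herv$retained_ids
  dtest <- stage("distance_test", distance_null_test(
    filter(prox_pc, .data$herv_id %in% de_hervs1),
    filter(prox_pc, .data$herv_id %in% setdiff(expressed_hervs1, de_hervs1)),
    max_window_bp = config$proximity$max_window_bp
  ))
  results$proximity <- prox
  results$distance_test <- dtest
  emit(
    prox %>% select(-"intersected") %>% as_tibble(),
    "proximity_records.tsv"
  )
  emit(glance.herv_distance_test(dtest), "distance_test.tsv")
  tall <- classify_intersections(filter(prox, .data$herv_id %in% de_hervs1))
  manifest$stages$proximity <- list(
    n_records = nrow(prox),
    de_herv_relations = setNames(as.list(tall$relations$n), tall$relations$relation),
    distance_test_p = dtest$p_value
  )

  # --- overlap statistics --------------------------------------------
  results$overlap <- list()
  for (cls in c("gene", "herv")) {
    u1 <- filt_res[[paste0("dataset1_", cls)]]$retained_ids
    u2 <- filt_res[[paste0("dataset2_", cls)]]$retained_ids
    s1 <- de_ids(de_res[[paste0("dataset1_", cls)]])
    s2 <- de_ids(de_res[[paste0("dataset2_", cls)]])
    ot <- stage(paste0("overlap_", cls), overlap_permutation_test(
      u1, u2, s1, s2,
      n_perm = config$overlap$n_perm, seed = config$seed + 7L
    ))
    results$overlap[[cls]] <- ot
    emit(glance.herv_overlap_test(ot), paste0("overlap_", cls, ".tsv"))
    manifest$stages[[paste0("overlap_", cls)]] <-
      as.list(glance.herv_overlap_test(ot))
  }
  results$fisher <- stage("fisher", fisher_de_association(
    length(de_ids(de_res$dataset1_herv)), filt_res$dataset1_herv$n_retained,
    length(de_ids(de_res$dataset2_herv)), filt_res$dataset2_herv$n_retained
  ))
  emit(results$fisher, "fisher_herv.tsv")
  results$correlation <- stage("correlation", bind_rows(
    cross_dataset_correlation(de_res$dataset1_herv, de_res$dataset2_herv, "all"),
    cross_dataset_correlation(de_res$dataset1_herv, de_res$dataset2_herv, "de_union")
  ))
  emit(results$correlation, "correlation_herv.tsv")

  # --- pairwise association on shared DE HERVs' neighbour genes -------
  shared_hervs <- intersect(de_ids(de_res$dataset1_herv),
                            de_ids(de_res$dataset2_herv))
  pair_tbl <- prox %>%
    filter(.data$herv_id %in% shared_hervs, !is.na(.data$nearest_gene_id)) %>%
    (function(px) {
      near <- select(px, "herv_id", gene_id = "nearest_gene_id")
      inter <- px %>%
        select("herv_id", "intersected") %>%
        tidyr::unnest("intersected") %>%
        select("herv_id", "gene_id")
      distinct(bind_rows(near, inter))
    })
  results$association <- NULL
  if (nrow(pair_tbl) > 0) {
    for (dn in names(datasets)) {
      cd <- datasets[[dn]]
      cm_g <- split_class(cd, ann$genes$gene_id)
      cm_h <- split_class(cd, ann$hervs$locus_id)
      keep <- pair_tbl %>%
        filter(.data$gene_id %in% cm_g$feature_id,
               .data$herv_id %in% cm_h$feature_id)
      if (nrow(keep) == 0) next
      assoc <- stage(paste0("associate_", dn), fit_pair_association(
        cm_g, cm_h, cd$samples, keep,
        transform = config$association$transform,
        q_threshold = config$association$q_threshold
      ))
      results$association[[dn]] <- assoc
      emit(as_tibble(assoc), paste0("association_", dn, ".tsv"))
      manifest$stages[[paste0("associate_", dn)]] <- list(
        n_pairs = nrow(assoc), n_significant = sum(assoc$significant)
      )
    }
  }

  # --- enrichment on importance scores --------------------------------
  betas <- stage("condition_model", fit_condition_model(
    filter_counts(split_class(d1, ann$genes$gene_id), filt_res$dataset1_gene),
    d1$samples,
    transform = config$association$transform
  ))
  enr <- stage("enrich", score_enrichment(
    betas, sets,
    method = config$enrichment$method,
    q_threshold = config$enrichment$q_threshold,
    min_set_size = config$enrichment$min_set_size,
    de_ids = de_ids(de_res$dataset1_gene)
  ))
  orep <- stage("enrich", overrepresentation_test(
    de_ids(de_res$dataset1_gene), filt_res$dataset1_gene$retained_ids, sets,
    q_threshold = config$enrichment$q_threshold
  ))
  results$condition_betas <- betas
  results$enrichment <- enr
  results$overrepresentation <- orep
  emit(as_tibble(betas), "condition_betas_dataset1_gene.tsv")
  emit(as_tibble(enr), "enrichment_scores.tsv")
  emit(as_tibble(orep), "enrichment_overrepresentation.tsv")
  manifest$stages$enrich <- list(
    n_sets_tested = nrow(enr), n_significant = sum(enr$significant)
  )

  # --- manifest -------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$outputs) <- files
  manifest$package_version <- as.character(utils::packageVersion("hervomics"))
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  results$manifest <- manifest
  invisible(results)
}
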