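#' Expanding-window nearest-gene search around HERV loci
#'
#' For each HERV locus the search first classifies direct gene overlaps: if
#' the locus overlaps at least one gene, the distance is 0 and the relation
#' is `exonic` when any overlapped gene's exon intersects the locus, else
#' `intronic`; every overlapped element is reported. Otherwise a symmetric
#' window `[start - w, end + w)` grows from `initial_window_bp` in steps of
#' `expansion_step_bp` until it contains a gene or hits `max_window_bp`
#' (defaults 500 bp, 500 bp, 10 kb). The first non-empty window yields the
#' gene with the minimal gap (half-open interval gap, ties broken by smallest
#' gene start then lexicographic `gene_id`) with relation `proximal`; an
#' empty final window gives `none_within_limit`. Distances are unstranded.
#'
#' @param ann A [annotation()] object.
#' @param herv_ids Locus identifiers to search (default: all loci in `ann`).
#' @param initial_window_bp,max_window_bp,expansion_step_bp Window geometry.
#' @param gene_universe `"all"` biotypes (default, used for intersection
#'   reporting) or `"protein_coding"` only (the convention for the distance
#'   null test).
#' @return Tibble of class `herv_proximity`: `herv_id`, `chrom`,
#'   `nearest_gene_id` (NA when none found), `distance_bp`, `relation`
#'   (`exonic`/`intronic`/`proximal`/`none_within_limit`), `n_intersected`
#'   and list-column `intersected` of `(gene_id, biotype, region)` tibbles.
#' @export
find_nearest_genes <- function(ann, herv_ids = NULL, initial_window_bp = 500,
                               max_window_bp = 10000, expansion_step_bp = 500,
                               gene_universe = c("all", "protein_coding")) {
  stopifnot(inherits(ann, "herv_annotation"))
  gene_universe <- match.arg(gene_universe)
  if (!(initial_window_bp > 0 && initial_window_bp <= max_window_bp)) {
    abort("Need 0 < initial_window_bp <= max_window_bp.")
  }
  if (expansion_step_bp <= 0) abort("expansion_step_bp must be positive.")

  hervs <- ann$hervs
  if (!is.null(herv_ids)) {
    missing <- setdiff(herv_ids, hervs$locus_id)
    if (length(missing) > 0) {
      abort(paste0("Unknown herv id(s): ", paste(head(missing, 5), collapse = ", ")))
    }
    hervs <- hervs[match(herv_ids, hervs$locus_id), ]
  }
  genes <- ann$genes
  if (gene_universe == "protein_coding") {
    genes <- filter(genes, .data$biotype == "protein_coding")
  }
  genes_by_chrom <- split(genes, genes$chrom)
  exons_by_gene <- split(ann$exons, ann$exons$gene_id)

  windows <- unique(c(
    seq(initial_window_bp, max_window_bp, by = expansion_step_bp),
    max_window_bp
  ))

  rows <- vector("list", nrow(hervs))
  for (i in seq_len(nrow(hervs))) {
    h <- hervs[i, ]
    g <- genes_by_chrom[[h$chrom]]
    rows[[i]] <- nearest_one(h, g, exons_by_gene, windows)
  }
  structure(
    bind_rows(rows),
    class = c("herv_proximity", class(tibble()))
  )
}

nearest_one <- function(h, g, exons_by_gene, windows) {
  empty_rec <- function(relation, gene_id = NA_character_, dist = NA_integer_,
                        intersected = list(tibble(
                          gene_id = character(), biotype = character(),
                          region = character()
                        ))) {
    tibble(
      herv_id = h$locus_id, chrom = h$chrom,
      nearest_gene_id = gene_id, distance_bp = dist, relation = relation,
      n_intersected = nrow(intersected[[1]]), intersected = intersected
    )
  }
  if (is.null(g) || nrow(g) == 0) return(empty_rec("none_within_limit"))

  ov <- g$start < h$end & g$end > h$start
  if (any(ov)) {
    hit <- g[ov, ]
    region <- vapply(seq_len(nrow(hit)), function(k) {
      ex <- exons_by_gene[[hit$gene_id[k]]]
      if (!is.null(ex) && any(ex$start < h$end & ex$end > h$start)) "exon" else "intron"
    }, "")
    elems <- tibble(gene_id = hit$gene_id, biotype = hit$biotype, region = region)
    # nearest among overlapped: all at distance 0; smallest start then gene_id
    ord <- order(hit$start, hit$gene_id)
    return(empty_rec(
      relation = if (any(region == "exon")) "exonic" else "intronic",
      gene_id = hit$gene_id[ord[1]], dist = 0L,
      intersected = list(elems)
    ))
  }

  gaps <- interval_gap(h$start, h$end, g$start, g$end)
  for (w in windows) {
    inside <- gaps < w
    if (any(inside)) {
      cand <- g[inside, ]
      cg <- gaps[inside]
      ord <- order(cg, cand$start, cand$gene_id)
      return(empty_rec(
        relation = "proximal",
        gene_id = cand$gene_id[ord[1]], dist = as.integer(cg[ord[1]])
      ))
    }
  }
  empty_rec("none_within_limit")
}

#' Tally HERV-gene intersection classes
#'
#' @param records A [find_nearest_genes()] result.
#' @return List of class `herv_intersections`: `relations` (counts of
#'   exonic/intronic/proximal/none_within_limit), `by_biotype` (counts of
#'   intersected elements by biotype), and `n_multi` (HERVs intersecting
#'   more than one element).
#' @export
classify_intersections <- function(records) {
  lv <- c("exonic", "intronic", "proximal", "none_within_limit")
  relations <- tibble(
    relation = lv,
    n = vapply(lv, function(l) sum(records$relation == l), 0L)
  )
  elems <- if (nrow(records) > 0) bind_rows(records$intersected) else
    tibble(gene_id = character(), biotype = character(), region = character())
  by_biotype <- elems %>%
    group_by(.data$biotype) %>%
    summarise(n = n(), .groups = "drop")
  structure(
    list(
      relations = relations,
      by_biotype = by_biotype,
      n_multi = sum(records$n_intersected > 1)
    ),
    class = "herv_intersections"
  )
}

#' @export
print.herv_intersections <- function(x, ...) {
  cat("<herv_intersections>\n")
  for (i in seq_len(nrow(x$relations))) {
    cat("  ", x$relations$relation[i], ": ", x$relations$n[i], "\n", sep = "")
  }
  cat("  intersecting multiple elements: ", x$n_multi, "\n", sep = "")
  invisible(x)
}

#' Test whether DE HERVs sit closer to genes than non-DE HERVs
#'
#' Compares nearest-gene distances of differentially expressed HERVs against
#' the constructed null of non-DE HERV distances with a two-sample
#' Wilcoxon rank-sum (Mann-Whitney U) test, two-sided. Small tie-free
#' samples are tested exactly; larger or tied samples use the normal
#' approximation with tie correction (the [stats::wilcox.test()]
#' convention). HERVs with no gene within the window limit are excluded by
#' default or censored at `max_window_bp + 1`.
#'
#' @param records_de Proximity records ([find_nearest_genes()]) of DE HERVs.
#' @param records_non_de Proximity records of non-DE HERVs (the null).
#' @param unfound `"exclude"` (default) drops `none_within_limit` records;
#'   `"censor"` scores them as `max_window_bp + 1`.
#' @param max_window_bp Window limit used for censoring (default 10,000).
#' @param method `"rank_sum"` (default) or its alias
#'   `"signed_rank_as_printed"` — both run the unpaired rank-sum test; the
#'   alias records the label under which this comparison is sometimes
#'   reported.
#' @return Object of class `herv_distance_test` with the U statistic,
#'   p-value, group sizes and medians.
#' @export
distance_null_test <- function(records_de, records_non_de,
                               unfound = c("exclude", "censor"),
                               max_window_bp = 10000,
                               method = c("rank_sum", "signed_rank_as_printed")) {
  unfound <- match.arg(unfound)
  method <- match.arg(method)
  d_de <- extract_distances(records_de, unfound, max_window_bp)
  d_nd <- extract_distances(records_non_de, unfound, max_window_bp)
  if (length(d_de) == 0 || length(d_nd) == 0) {
    abort("Both groups must contribute at least one distance.")
  }
  wt <- suppressWarnings(wilcox.test(d_de, d_nd, alternative = "two.sided"))
  structure(
    list(
      statistic = unname(wt$statistic),
      p_value = wt$p.value,
      n_de = length(d_de),
      n_non_de = length(d_nd),
      median_distance_de = median(d_de),
      median_distance_non_de = median(d_nd),
      method = method,
      unfound = unfound,
      distances_de = d_de,
      distances_non_de = d_nd
    ),
    class = "herv_distance_test"
  )
}

extract_distances <- function(records, unfound, max_window_bp) {
  d <- records$distance_bp
  none <- records$relation == "none_within_limit"
  if (unfound == "exclude") {
    as.numeric(d[!none])
  } else {
    d[none] <- max_window_bp + 1L
    as.numeric(d)
  }
}

#' @export
print.herv_distance_test <- function(x, ...) {
  cat(
    "<herv_distance_test> W = ", signif(x$statistic, 6),
    ", p = ", signif(x$p_value, 4),
    " (n_de = ", x$n_de, ", n_non_de = ", x$n_non_de, ")\n",
    "  median distance: DE = ", x$median_distance_de,
    " bp, non-DE = ", x$median_distance_non_de, " bp\n",
    sep = ""
  )
  invisible(x)
}
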