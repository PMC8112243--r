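# Fixture builders shared across test files; everything is generated in code.

# A small but complete simulation configuration that runs fast.
tiny_cfg <- function(seed = 101, ...) {
  defaults <- list(
    seed = seed, n_genes = 300, n_hervs = 80,
    n_case = c(10, 12), n_control = c(10, 8),
    frac_de_genes = 0.1, frac_de_hervs = 0.1,
    n_gene_sets = 12, n_enriched_sets = 2, set_size_range = c(10, 20)
  )
  overrides <- list(...)
  do.call(sim_config, utils::modifyList(defaults, overrides))
}

# Counts tibble from a plain matrix (features F1..., samples S1...).
counts_tbl <- function(m, feature_ids = NULL, sample_ids = NULL) {
  feature_ids <- feature_ids %||% sprintf("F%03d", seq_len(nrow(m)))
  sample_ids <- sample_ids %||% sprintf("S%02d", seq_len(ncol(m)))
  colnames(m) <- sample_ids
  dplyr::bind_cols(
    tibble::tibble(feature_id = feature_ids),
    tibble::as_tibble(m)
  )
}

samples_tbl <- function(condition, sample_ids = NULL, dataset = "d1") {
  sample_ids <- sample_ids %||% sprintf("S%02d", seq_along(condition))
  tibble::tibble(sample_id = sample_ids, condition = condition, dataset = dataset)
}

unit_sf <- function(counts) {
  tibble::tibble(
    sample_id = setdiff(names(counts), "feature_id"),
    size_factor = 1
  )
}

# Hand-built annotation from compact gene / herv specs.
mini_annotation <- function(genes, hervs, exons = NULL) {
  annotation(genes = genes, hervs = hervs, exons = exons)
}

gene_row <- function(gene_id, chrom, start, end, biotype = "protein_coding",
                     strand = "+") {
  tibble::tibble(
    gene_id = gene_id, symbol = gene_id, biotype = biotype,
    chrom = chrom, start = start, end = end, strand = strand
  )
}

herv_row <- function(locus_id, chrom, start, end, strand = "+",
                     is_coding = FALSE, in_enhancer = FALSE) {
  tibble::tibble(
    locus_id = locus_id, family = herv_family(locus_id), chrom = chrom,
    start = start, end = end, strand = strand,
    is_coding = is_coding, in_enhancer = in_enhancer
  )
}

# Minimal proximity-record tibble with given distances.
mk_prox <- function(d, rel = "proximal") {
  tibble::tibble(
    herv_id = sprintf("H%03d", seq_along(d)), chrom = "chr1",
    nearest_gene_id = "G", distance_bp = d, relation = rel,
    n_intersected = 0L,
    intersected = replicate(
      length(d),
      tibble::tibble(gene_id = character(), biotype = character(),
                     region = character()),
      simplify = FALSE
    )
  )
}

# Random small fragment-alignment instance for EM property sweeps.
random_alignments <- function(n_loci, n_frag, p_candidate = 0.6) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  rows <- lapply(seq_len(n_frag), function(f) {
    k <- 1 + stats::rbinom(1, n_loci - 1, p_candidate)
    cand <- sample(loci, k)
    tibble::tibble(
      fragment_id = sprintf("FR%03d", f),
      locus_id = cand,
      score = sample(0:100, k)
    )
  })
  dplyr::bind_rows(rows)
}
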