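#' Build an annotation of genes and HERV loci
#'
#' An annotation bundles a gene table, an exon table and a HERV locus table
#' that share one coordinate convention: 0-based, half-open `[start, end)`
#' intervals. All downstream proximity and intersection operations consume
#' this object. Tables are stored sorted by chromosome then start so that
#' per-chromosome retrieval is already in genomic order.
#'
#' @param genes Tibble with columns `gene_id`, `symbol`, `biotype`, `chrom`,
#'   `start`, `end`, `strand`. Biotypes outside
#'   `protein_coding`/`lncRNA`/`pseudogene` are mapped to `other`.
#' @param hervs Tibble with columns `locus_id`, `family`, `chrom`, `start`,
#'   `end`, `strand` and logical `is_coding`, `in_enhancer`. The family is the
#'   HERV family label (e.g. `ERV316A3` for locus `ERV316A3_12q24.13`);
#'   coding/enhancer flags come from upstream annotation (e.g. CNIT calls and
#'   FANTOM5 enhancer overlap) and are consumed, never computed, here.
#' @param exons Optional tibble with columns `gene_id`, `chrom`, `start`,
#'   `end`; every exon must lie within its gene and exons of one gene must not
#'   overlap each other. When `NULL` each gene is treated as a single exon.
#' @return An object of class `herv_annotation`: a list with sorted `genes`,
#'   `exons` and `hervs` tibbles.
#' @export
annotation <- function(genes, hervs, exons = NULL) {
  genes <- as_tibble(genes)
  hervs <- as_tibble(hervs)
  check_intervals(genes, "genes")
  check_intervals(hervs, "hervs")

  known <- c("protein_coding", "lncRNA", "pseudogene")
  genes$biotype <- ifelse(genes$biotype %in% known, genes$biotype, "other")
  if (anyDuplicated(genes$gene_id)) {
    abort("Duplicate gene_id in annotation.")
  }
  if (anyDuplicated(hervs$locus_id)) {
    dup <- unique(hervs$locus_id[duplicated(hervs$locus_id)])
    abort(paste0("Duplicate locus_id in annotation: ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(hervs$family))) abort("Empty HERV family label.")

  if (is.null(exons)) {
    exons <- genes %>%
      select("gene_id", "chrom", "start", "end")
  }
  exons <- as_tibble(exons)
  check_intervals(exons, "exons")
  check_exons(genes, exons)

  out <- list(
    genes = arrange(genes, .data$chrom, .data$start, .data$gene_id),
    exons = arrange(exons, .data$chrom, .data$start, .data$gene_id),
    hervs = arrange(hervs, .data$chrom, .data$start, .data$locus_id)
  )
  structure(out, class = "herv_annotation")
}

check_intervals <- function(tbl, what) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tbl))) {
    abort(paste0("`", what, "` must have chrom/start/end columns."))
  }
  if (any(!nzchar(tbl$chrom))) abort(paste0("Empty chromosome name in ", what, "."))
  bad <- which(!(tbl$start >= 0 & tbl$start < tbl$end))
  if (length(bad) > 0) {
    abort(paste0(
      "Malformed interval(s) in ", what, " (need 0 <= start < end) at row(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(tbl)
}

check_exons <- function(genes, exons) {
  joined <- left_join(
    exons,
    select(genes, "gene_id", g_start = "start", g_end = "end"),
    by = "gene_id"
  )
  if (anyNA(joined$g_start)) abort("Exon refers to unknown gene_id.")
  if (any(joined$start < joined$g_start | joined$end > joined$g_end)) {
    abort("Exon extends outside its gene.")
  }
  overlap <- exons %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]), .groups = "drop")
  if (any(overlap$bad, na.rm = TRUE)) abort("Overlapping exons within a gene.")
  invisible(exons)
}

#' @export
print.herv_annotation <- function(x, ...) {
  cat(
    "<herv_annotation> ", nrow(x$genes), " genes (", nrow(x$exons), " exons), ",
    nrow(x$hervs), " HERV loci on ",
    length(unique(c(x$genes$chrom, x$hervs$chrom))), " chromosomes\n",
    sep = ""
  )
  invisible(x)
}

#' Retrieve annotation features on one chromosome, in start order
#'
#' @param ann A [annotation()] object.
#' @param chrom Chromosome name.
#' @return Tibble of genes (`genes_on`) or HERV loci (`hervs_on`) whose
#'   `chrom` matches, sorted by `start`.
#' @export
genes_on <- function(ann, chrom) {
  stopifnot(inherits(ann, "herv_annotation"))
  filter(ann$genes, .data$chrom == !!chrom)
}

#' @rdname genes_on
#' @export
hervs_on <- function(ann, chrom) {
  stopifnot(inherits(ann, "herv_annotation"))
  filter(ann$hervs, .data$chrom == !!chrom)
}

#' Read a gene GTF and a HERV BED into an annotation
#'
#' Gene models come from a GTF (1-based closed coordinates, converted at this
#' boundary to the internal 0-based half-open convention); HERV loci come from
#' a BED6+ file, which is already 0-based half-open and is read as-is. The BED
#' `name` field carries the locus identifier in `FAMILY_cytoband` form (e.g.
#' `ERV316A3_12q24.13`); the family is the prefix before the first underscore.
#' Optional BED columns 7 and 8 hold 0/1 coding-potential and enhancer flags;
#' both default to `FALSE` when absent.
#'
#' @param gtf_path Path to a GTF with `gene` and `exon` records carrying
#'   `gene_id` (and optionally `gene_name`, `gene_biotype`) attributes.
#' @param herv_bed_path Path to the HERV BED6(+2) file.
#' @return A [annotation()] object. Records with malformed coordinates are
#'   dropped with a warning that reports their line numbers; a duplicated
#'   locus identifier is an error.
#' @export
read_annotation <- function(gtf_path, herv_bed_path) {
  gr <- read_gtf_checked(gtf_path)
  meta <- as.data.frame(gr)
  # GTF is 1-based closed; GRanges keeps that convention, so start-1 / end.
  feats <- tibble(
    type = as.character(meta$type),
    chrom = as.character(meta$seqnames),
    start = meta$start - 1L,
    end = meta$end,
    strand = as.character(meta$strand),
    gene_id = meta$gene_id,
    symbol = if ("gene_name" %in% names(meta)) meta$gene_name else meta$gene_id,
    biotype = if ("gene_biotype" %in% names(meta)) meta$gene_biotype else "other"
  )
  feats$strand[!feats$strand %in% c("+", "-")] <- "*"
  genes <- feats %>%
    filter(.data$type == "gene") %>%
    select("gene_id", "symbol", "biotype", "chrom", "start", "end", "strand")
  exons <- feats %>%
    filter(.data$type == "exon") %>%
    select("gene_id", "chrom", "start", "end")
  if (nrow(genes) == 0) abort("No gene records found in GTF.")

  hervs <- read_herv_bed(herv_bed_path)
  annotation(genes, hervs, exons = if (nrow(exons) > 0) exons else NULL)
}

# Import a GTF via rtracklayer after screening out records whose coordinates
# cannot form an interval (start > end in 1-based closed convention); those
# are reported with their line numbers rather than failing the whole import.
read_gtf_checked <- function(gtf_path) {
  lines <- readLines(gtf_path)
  rec <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(rec) == 0) abort("GTF contains no records.")
  f <- strsplit(lines[rec], "\t", fixed = TRUE)
  starts <- suppressWarnings(as.integer(vapply(f, `[`, "", 4L)))
  ends <- suppressWarnings(as.integer(vapply(f, `[`, "", 5L)))
  bad <- which(is.na(starts) | is.na(ends) | starts > ends | starts < 1L)
  if (length(bad) > 0) {
    warn(paste0(
      "Rejected ", length(bad), " malformed GTF record(s) at line(s): ",
      paste(head(rec[bad], 10), collapse = ", ")
    ))
    tmp <- tempfile(fileext = ".gtf")
    writeLines(lines[-rec[bad]], tmp)
    gtf_path <- tmp
    on.exit(unlink(tmp))
  }
  rtracklayer::import(gtf_path, format = "gtf")
}

read_herv_bed <- function(herv_bed_path) {
  bed <- readr::read_tsv(
    herv_bed_path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#",
    progress = FALSE
  )
  if (ncol(bed) < 4) abort("HERV BED needs at least chrom, start, end, name.")
  start <- as.integer(bed[[2]])
  end <- as.integer(bed[[3]])
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0) {
    warn(paste0(
      "Rejected ", length(bad), " malformed BED record(s) at line(s): ",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  keep <- setdiff(seq_len(nrow(bed)), bad)
  locus_id <- bed[[4]][keep]
  if (anyDuplicated(locus_id)) {
    dup <- unique(locus_id[duplicated(locus_id)])
    abort(paste0("Duplicate locus_id in BED: ", paste(dup, collapse = ", ")))
  }
  strand <- if (ncol(bed) >= 6) bed[[6]][keep] else rep("*", length(keep))
  strand[!strand %in% c("+", "-")] <- "*"
  as_flag <- function(x) !is.na(x) & x %in% c("1", "TRUE", "true", "T")
  tibble(
    locus_id = locus_id,
    family = herv_family(locus_id),
    chrom = bed[[1]][keep],
    start = start[keep],
    end = end[keep],
    strand = strand,
    is_coding = if (ncol(bed) >= 7) as_flag(bed[[7]][keep]) else rep(FALSE, length(keep)),
    in_enhancer = if (ncol(bed) >= 8) as_flag(bed[[8]][keep]) else rep(FALSE, length(keep))
  )
}

#' Parse HERV family labels from locus identifiers
#'
#' Locus identifiers follow the `FAMILY_cytoband` convention
#' (`ERV316A3_12q24.13`); the family is everything before the first
#' underscore.
#'
#' @param locus_id Character vector of locus identifiers.
#' @return Character vector of family labels.
#' @export
herv_family <- function(locus_id) {
  fam <- sub("_.*$", "", locus_id)
  if (any(!nzchar(fam))) abort("locus_id yields an empty family label.")
  fam
}

#' Write an annotation back to GTF + BED
#'
#' Inverse of [read_annotation()]: gene/exon records go to a GTF (converted
#' back to 1-based closed coordinates), HERV loci to a BED6+2 with coding and
#' enhancer flag columns.
#'
#' @param ann A [annotation()] object.
#' @param gtf_path,bed_path Output paths.
#' @return Invisibly, `ann`.
#' @export
write_annotation <- function(ann, gtf_path, bed_path) {
  stopifnot(inherits(ann, "herv_annotation"))
  g <- ann$genes
  gene_lines <- sprintf(
    "%s\thervomics\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; gene_biotype \"%s\";",
    g$chrom, g$start + 1L, g$end, ifelse(g$strand == "*", ".", g$strand),
    g$gene_id, g$symbol, g$biotype
  )
  e <- left_join(ann$exons, select(g, "gene_id", "strand"), by = "gene_id")
  exon_lines <- sprintf(
    "%s\thervomics\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    e$chrom, e$start + 1L, e$end, ifelse(e$strand == "*", ".", e$strand), e$gene_id
  )
  writeLines(c(gene_lines, exon_lines), gtf_path)

  h <- ann$hervs
  readr::write_tsv(
    tibble(
      chrom = h$chrom, start = h$start, end = h$end, name = h$locus_id,
      score = 0L, strand = ifelse(h$strand == "*", ".", h$strand),
      is_coding = as.integer(h$is_coding), in_enhancer = as.integer(h$in_enhancer)
    ),
    bed_path,
    col_names = FALSE, progress = FALSE
  )
  invisible(ann)
}
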