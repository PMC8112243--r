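#' Read a feature-by-sample count table with sample metadata
#'
#' The counts TSV has feature identifiers in the first column and one column
#' per sample; the metadata TSV maps `sample_id` to `condition`
#' (`case`/`control`) and a `dataset` label. Cells equal to the NA token are
#' replaced by zero; any other non-numeric cell is an error, as is a sample
#' present in the counts but missing from the metadata.
#'
#' @param counts_path Path to the counts TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @param na_token Literal string treated as missing (default `"NA"`).
#' @return A list of class `count_data` with elements `counts` (tibble:
#'   `feature_id` plus one numeric column per sample) and `samples` (tibble:
#'   `sample_id`, `condition`, `dataset`).
#' @export
read_counts <- function(counts_path, meta_path, na_token = "NA") {
  raw <- readr::read_tsv(
    counts_path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), # keep the NA token literal; it is handled below
    progress = FALSE
  )
  names(raw)[1] <- "feature_id"
  if (anyDuplicated(raw$feature_id)) abort("Duplicate feature_id in counts.")
  if (anyDuplicated(names(raw))) abort("Duplicate sample_id in counts header.")
  sample_cols <- setdiff(names(raw), "feature_id")
  if (length(sample_cols) == 0) abort("Counts table has no sample columns.")

  num <- lapply(raw[sample_cols], function(x) {
    x[x == na_token] <- "0"
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      bad <- x[which(is.na(v))[1]]
      abort(paste0("Non-numeric count cell: \"", bad, "\""))
    }
    round(v)
  })
  counts <- tibble(feature_id = raw$feature_id, !!!num)
  if (any(as_count_matrix(counts) < 0)) abort("Negative counts are not allowed.")

  samples <- readr::read_tsv(
    meta_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"dataset" %in% names(samples)) samples$dataset <- "dataset1"
  samples <- check_samples(counts, samples[c("sample_id", "condition", "dataset")])
  samples <- filter(samples, .data$sample_id %in% sample_cols)

  structure(list(counts = counts, samples = samples), class = "count_data")
}

#' Write a count table and its sample metadata
#'
#' Inverse of [read_counts()]; columns are written in stored order with a
#' header row, so a write/read round trip is the identity on well-formed
#' matrices.
#'
#' @param x A `count_data` object (or a list with `counts` and `samples`).
#' @param counts_path,meta_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_counts <- function(x, counts_path, meta_path) {
  readr::write_tsv(x$counts, counts_path, progress = FALSE)
  readr::write_tsv(x$samples, meta_path, progress = FALSE)
  invisible(x)
}

#' @export
print.count_data <- function(x, ...) {
  cat(
    "<count_data> ", nrow(x$counts), " features x ",
    ncol(x$counts) - 1L, " samples (",
    sum(x$samples$condition == "case"), " case / ",
    sum(x$samples$condition == "control"), " control)\n",
    sep = ""
  )
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line — name, description, then member
#' identifiers, tab-separated. Duplicate members within a set are dropped;
#' sets left empty are removed (their number is reported in a warning);
#' unreadable lines (fewer than two fields) are skipped and reported; a
#' repeated set name is an error.
#'
#' @param gmt_path Path to the GMT file.
#' @return Tibble of class `gene_sets` with columns `set_name`,
#'   `description` and list-column `members`.
#' @export
read_gmt <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(structure(
      tibble(set_name = character(), description = character(), members = list()),
      class = c("gene_sets", class(tibble()))
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    warn(paste0("Skipped ", length(bad), " unreadable GMT line(s): ",
                paste(head(bad, 10), collapse = ", ")))
    parts <- parts[-bad]
  }
  name <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(name)) {
    dup <- unique(name[duplicated(name)])
    abort(paste0("Duplicate gene-set name(s): ", paste(dup, collapse = ", ")))
  }
  desc <- vapply(parts, `[`, "", 2L)
  members <- lapply(parts, function(p) unique(p[-c(1L, 2L)][nzchar(p[-c(1L, 2L)])]))
  empty <- lengths(members) == 0
  if (any(empty)) {
    warn(paste0("Dropped ", sum(empty), " empty gene set(s)."))
  }
  out <- tibble(
    set_name = name[!empty],
    description = desc[!empty],
    members = members[!empty]
  )
  structure(out, class = c("gene_sets", class(tibble())))
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `gene_sets` tibble (see [read_gmt()]).
#' @param gmt_path Output path.
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, gmt_path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_name[i], sets$description[i], sets$members[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, gmt_path)
  invisible(sets)
}
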