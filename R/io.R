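#' Read and write the pipeline's tabular formats
#'
#' Thin wrappers around tab-separated text: `read_counts_tsv` expects a
#' GEO-style raw count table (first column miRNA id, one column per
#' sample); `read_intake_tsv` expects one subject per row (first column
#' subject id, an `energy_kcal_day` column, one column per nutrient);
#' `write_tsv` writes any data frame without quoting or row names.
#'
#' @param path file path.
#' @return `read_counts_tsv`: a [count_matrix()]; `read_intake_tsv`:
#'   an [intake_table()] (raw only; run [kcal_normalize()]).
#' @name nutrimir-io
NULL

#' @rdname nutrimir-io
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m)
}

#' @rdname nutrimir-io
#' @export
read_intake_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!"energy_kcal_day" %in% names(df)) {
    stop("intake TSV must have an energy_kcal_day column")
  }
  nut <- setdiff(names(df), c(names(df)[1], "energy_kcal_day"))
  m <- as.matrix(df[, nut, drop = FALSE])
  rownames(m) <- df[[1]]
  intake_table(m, df$energy_kcal_day)
}

#' @rdname nutrimir-io
#' @param x data frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix (raw or normalized) as TSV
#'
#' @param cm a [count_matrix()].
#' @param path output file.
#' @param what `"raw"` or `"normalized"`.
#' @export
write_counts_tsv <- function(cm, path, what = c("raw", "normalized")) {
  what <- match.arg(what)
  m <- if (what == "raw") cm$counts else {
    if (is.null(cm$normalized)) stop("normalized counts absent")
    cm$normalized
  }
  df <- data.frame(mirna_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' Write an intake table (raw and energy columns, plus normalized
#' intakes when present) as TSV
#'
#' @param intake an [intake_table()].
#' @param path output file.
#' @param what `"normalized"` (default) or `"raw"`.
#' @export
write_intake_tsv <- function(intake, path,
                             what = c("normalized", "raw")) {
  what <- match.arg(what)
  m <- if (what == "raw") intake$raw else {
    if (is.null(intake$normalized)) stop("run kcal_normalize() first")
    intake$normalized
  }
  df <- data.frame(subject_id = rownames(m),
                   energy_kcal_day = intake$energy_kcal_day[rownames(m)],
                   m, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a GMT gene-set library
#'
#' Parses the tab-delimited GMT format (set name, description, member
#' genes) into a named list of gene-id vectors.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Read a miRNA-target annotation TSV
#'
#' Expects columns `mirna_id`, `gene_id` and optionally `source`;
#' duplicate (miRNA, gene) pairs across sources are merged.
#'
#' @param path TSV file.
#' @return data frame with unique `mirna_id` / `gene_id` rows (a
#'   `source` column, when present, is collapsed with `;`).
#' @export
read_targets_tsv <- function(path) {
  df <- read.delim(path)
  if (!all(c("mirna_id", "gene_id") %in% names(df))) {
    stop("targets TSV must have mirna_id and gene_id columns")
  }
  if ("source" %in% names(df)) {
    agg <- stats::aggregate(source ~ mirna_id + gene_id, df,
                            function(s) paste(unique(s), collapse = ";"))
    agg
  } else {
    unique(df[c("mirna_id", "gene_id")])
  }
}
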