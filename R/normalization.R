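#' Median-of-ratios size factors and count normalization
#'
#' Computes per-sample size factors by the median-of-ratios method: for
#' each miRNA with strictly positive counts in all samples, its
#' geometric mean across samples is taken as reference; a sample's size
#' factor is the median, over those reference miRNAs, of the ratio
#' count / geometric mean. Normalized counts (raw / size factor) are
#' stored alongside the raw matrix.
#'
#' miRNAs with any zero count are excluded from the reference set
#' because their log-scale geometric mean is undefined. If no miRNA is
#' positive in every sample the default is to fail; `fallback =
#' "poscounts"` instead computes each miRNA's geometric mean over its
#' positive counts only and uses every miRNA with at least one positive
#' count, taking per-sample medians over ratios at positive counts.
#'
#' @param cm a [count_matrix()] with at least two samples.
#' @param fallback behaviour when no miRNA has all-positive counts:
#'   `"error"` (default) or `"poscounts"` pseudo-reference.
#' @return the `count_matrix` with `size_factors` (named, positive) and
#'   `normalized` populated.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("miR-", 1:3), c("A", "B")))
#' size_factors(count_matrix(m))$size_factors
#' @export
size_factors <- function(cm, fallback = c("error", "poscounts")) {
  stopifnot(inherits(cm, "count_matrix"))
  fallback <- match.arg(fallback)
  counts <- cm$counts
  if (ncol(counts) < 2) stop("size factors need at least 2 samples")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    if (fallback == "error") {
      stop("no miRNA has strictly positive counts in all samples; ",
           "consider fallback = \"poscounts\" (pseudo-reference)")
    }
    use <- rowSums(counts > 0) > 0
    loggeo <- apply(counts[use, , drop = FALSE], 1, function(x) {
      mean(log(x[x > 0]))
    })
    logratios <- log(counts[use, , drop = FALSE]) - loggeo
    sf <- apply(logratios, 2, function(lr) exp(median(lr[is.finite(lr)])))
  } else {
    refc <- counts[ref, , drop = FALSE]
    geo <- exp(rowMeans(log(refc)))
    sf <- apply(refc / geo, 2, median)
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("degenerate size factors; check the count matrix")
  }
  cm$size_factors <- setNames(sf, colnames(counts))
  cm$normalized <- sweep(counts, 2, sf, "/")
  cm
}

#' Per-sample detectability filter
#'
#' Flags a miRNA as detectable in a sample when its normalized read
#' count strictly exceeds `threshold` (default 15 normalized reads).
#'
#' @param cm a normalized [count_matrix()] (run [size_factors()] first).
#' @param threshold positive detectability cutoff on normalized counts;
#'   the comparison is strict (`> threshold`).
#' @return A `filter_report` list: `n_input_mirnas`, `n_detectable`
#'   (miRNAs detectable in at least one sample), `detectable` (logical
#'   miRNA x sample matrix).
#' @export
detectability_filter <- function(cm, threshold = 15) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$normalized)) {
    stop("normalized counts absent: run size_factors() first")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive")
  }
  flags <- cm$normalized > threshold
  structure(
    list(n_input_mirnas = nrow(cm$counts),
         n_detectable = sum(rowSums(flags) > 0),
         threshold = threshold,
         detectable = flags),
    class = "filter_report"
  )
}

#' Analysis-set filter by within-group median expression
#'
#' Retains a miRNA for correlation screening when its median normalized
#' count strictly exceeds `threshold` within at least one dietary group.
#'
#' @inheritParams detectability_filter
#' @param groups factor or character vector of diet-group labels, one
#'   per sample (in column order of the matrix) or named by sample id.
#' @return A `filter_report` list with `n_input_mirnas`,
#'   `n_analysis_set`, `in_analysis_set` (named logical per miRNA), and
#'   `group_medians` (miRNA x group matrix of median normalized counts).
#' @export
analysis_set <- function(cm, groups, threshold = 15) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$normalized)) {
    stop("normalized counts absent: run size_factors() first")
  }
  groups <- resolve_groups(groups, colnames(cm$counts))
  if (any(table(groups) == 0)) stop("empty dietary group")
  glev <- levels(groups)
  med <- sapply(glev, function(g) {
    apply(cm$normalized[, groups == g, drop = FALSE], 1, median)
  })
  keep <- apply(med > threshold, 1, any)
  structure(
    list(n_input_mirnas = nrow(cm$counts),
         n_analysis_set = sum(keep),
         threshold = threshold,
         in_analysis_set = keep,
         group_medians = med),
    class = "filter_report"
  )
}

# align a per-sample group vector with the matrix column order; accepts
# a named vector/factor or one already in column order
resolve_groups <- function(groups, sample_ids) {
  if (!is.null(names(groups))) {
    missing <- setdiff(sample_ids, names(groups))
    if (length(missing) > 0) {
      stop("samples without a group assignment: ",
           paste(head(missing, 5), collapse = ", "))
    }
    groups <- groups[sample_ids]
  } else if (length(groups) != length(sample_ids)) {
    stop("groups must be named by sample or match the number of samples")
  }
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  droplevels(groups)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  cat("  input miRNAs:", x$n_input_mirnas, "\n")
  if (!is.null(x$n_detectable)) {
    cat("  detectable (>", x$threshold, "in >= 1 sample):",
        x$n_detectable, "\n")
  }
  if (!is.null(x$n_analysis_set)) {
    cat("  analysis set (group median >", x$threshold, "):",
        x$n_analysis_set, "\n")
  }
  invisible(x)
}
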