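#' Construct a miRNA count matrix container
#'
#' Wraps a raw mature-miRNA count matrix (rows = miRNAs, columns =
#' samples) together with, once computed, per-sample size factors and
#' normalized counts (raw / size factor).
#'
#' @param counts numeric matrix of non-negative integer counts with
#'   miRNA ids as rownames and sample ids as colnames.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `size_factors` (NULL until [size_factors()] is run) and
#'   `normalized` (NULL until computed).
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("miR-", 1:3), paste0("S", 1:4)))
#' cm <- count_matrix(m)
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry miRNA rownames and sample colnames")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and complete")
  }
  if (any(counts != round(counts))) {
    stop("counts must be integers (raw read counts)")
  }
  structure(
    list(counts = counts, size_factors = NULL, normalized = NULL),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(if (is.null(x$size_factors)) "size factors: not computed\n" else
    sprintf("size factors: computed (range %.3f-%.3f)\n",
            min(x$size_factors), max(x$size_factors)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
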