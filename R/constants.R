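#' Natural-compound vocabulary
#'
#' The 23 dietary natural compounds (NCs) tracked by the pipeline,
#' grouped into the three classes used throughout: lipid-related,
#' micro-element, and vitamin-related. `nc_compounds()` returns the
#' vocabulary as a data frame; `nc_classes()` returns the named class
#' vector keyed by `nc_id`.
#'
#' @return `nc_compounds()`: a data frame with columns `nc_id` (snake_case
#'   identifier), `nc_name` (display name), and `nc_class`.
#'   `nc_classes()`: a named character vector mapping `nc_id` to class.
#' @examples
#' head(nc_compounds())
#' table(nc_compounds()$nc_class)
#' @export
nc_compounds <- function() {
  df <- rbind(
    data.frame(
      nc_id = c("cholesterol", "linoleic_acid", "linolenic_acid",
                "monounsaturated_fatty_acids", "oleic_acid",
                "total_polyunsaturated_fatty_acids",
                "total_saturated_fatty_acids"),
      nc_name = c("cholesterol", "linoleic acid", "linolenic acid",
                  "monounsaturated fatty acids", "oleic acid",
                  "total polyunsaturated fatty acids",
                  "total saturated fatty acids"),
      nc_class = "lipid-related"
    ),
    data.frame(
      nc_id = c("calcium", "iron", "phosphorus", "potassium", "sodium",
                "zinc"),
      nc_name = c("calcium", "iron", "phosphorus", "potassium", "sodium",
                  "zinc"),
      nc_class = "micro-element"
    ),
    data.frame(
      nc_id = c("beta_carotene", "folic_acid", "niacin", "retinol",
                "riboflavin", "thiamine", "vitamin_b6", "vitamin_c",
                "vitamin_d", "vitamin_e"),
      nc_name = c("beta-carotene", "folic acid", "niacin", "retinol",
                  "riboflavin", "thiamine", "vitamin B6", "vitamin C",
                  "vitamin D", "vitamin E"),
      nc_class = "vitamin-related"
    )
  )
  rownames(df) <- NULL
  df
}

#' @rdname nc_compounds
#' @export
nc_classes <- function() {
  df <- nc_compounds()
  setNames(df$nc_class, df$nc_id)
}

# internal: assert that a character vector of NC ids is drawn from the
# packaged vocabulary; used by readers that claim full-vocabulary input
validate_nc_ids <- function(ids, require_all = FALSE) {
  known <- nc_compounds()$nc_id
  bad <- setdiff(ids, known)
  if (length(bad) > 0) {
    stop("unknown NC ids: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (require_all && length(setdiff(known, ids)) > 0) {
    stop("intake table does not cover the full 23-NC vocabulary; missing: ",
         paste(setdiff(known, ids), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
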