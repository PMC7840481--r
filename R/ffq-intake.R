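#' Construct an intake table
#'
#' Holds per-subject daily nutrient intakes: the raw intakes (nutrient
#' units/day), the total energy intake (kcal/day) and, once
#' [kcal_normalize()] has been run, energy-normalized intakes.
#'
#' @param raw numeric matrix, subjects x nutrients, raw daily intakes
#'   with subject rownames and nutrient-id colnames.
#' @param energy_kcal_day numeric vector of daily energy intake per
#'   subject (kcal), aligned with `raw` rows.
#' @param normalized optional matrix of energy-normalized intakes
#'   (nutrient units per 1,000 kcal), same shape as `raw`.
#' @return An object of class `intake_table`.
#' @export
intake_table <- function(raw, energy_kcal_day, normalized = NULL) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw)) || is.null(colnames(raw))) {
    stop("raw intakes must carry subject rownames and nutrient colnames")
  }
  if (any(raw < 0, na.rm = TRUE)) stop("raw intakes must be >= 0")
  if (length(energy_kcal_day) != nrow(raw)) {
    stop("energy_kcal_day must have one value per subject")
  }
  structure(
    list(raw = raw,
         energy_kcal_day = setNames(as.numeric(energy_kcal_day),
                                    rownames(raw)),
         normalized = normalized),
    class = "intake_table"
  )
}

#' @export
print.intake_table <- function(x, ...) {
  cat(sprintf("intake_table: %d subjects x %d nutrients (%s)\n",
              nrow(x$raw), ncol(x$raw),
              if (is.null(x$normalized)) "raw only" else
                "kcal-normalized"))
  invisible(x)
}

#' Compute daily nutrient intakes from FFQ responses
#'
#' Converts food-frequency questionnaire responses (consumption
#' frequency and portion size per food item) and a food-composition
#' table (nutrient amounts per 100 g edible portion, plus energy) into
#' per-subject daily intakes. For nutrient k and subject s,
#' `raw_k(s) = sum over items of frequency * portion_g * amount_k / 100`;
#' daily energy is computed the same way from the `energy_kcal` column.
#'
#' @param ffq data frame with columns `subject_id`, `item_id`,
#'   `frequency` (consumptions per day, >= 0) and `portion` (grams per
#'   consumption, > 0); one row per (subject, item).
#' @param comp data frame with column `item_id`, a numeric
#'   `energy_kcal` column (kcal per 100 g) and one numeric column per
#'   nutrient (amount per 100 g). Missing nutrient values are treated
#'   as 0 (a message reports how many) unless `strict = TRUE`.
#' @param strict fail on missing nutrient values instead of zeroing.
#' @return an [intake_table()] with raw intakes and daily energy
#'   (normalized slot empty; see [kcal_normalize()]).
#' @examples
#' ffq <- data.frame(subject_id = "s1", item_id = "bread",
#'                   frequency = 2, portion = 50)
#' comp <- data.frame(item_id = "bread", energy_kcal = 250, sodium = 10)
#' compute_intake(ffq, comp)$raw
#' @export
compute_intake <- function(ffq, comp, strict = FALSE) {
  need <- c("subject_id", "item_id", "frequency", "portion")
  if (!all(need %in% names(ffq))) {
    stop("ffq must have columns: ", paste(need, collapse = ", "))
  }
  if (!"item_id" %in% names(comp) || !"energy_kcal" %in% names(comp)) {
    stop("comp must have columns item_id and energy_kcal")
  }
  if (anyDuplicated(comp$item_id)) stop("duplicated item_id in comp")
  if (anyDuplicated(ffq[c("subject_id", "item_id")])) {
    stop("duplicated (subject_id, item_id) rows in ffq")
  }
  if (any(ffq$frequency < 0)) stop("negative frequency in ffq")
  if (any(ffq$portion <= 0)) stop("portion must be > 0")
  unknown <- setdiff(ffq$item_id, comp$item_id)
  if (length(unknown) > 0) {
    stop("FFQ items absent from the composition table: ",
         paste(unique(unknown), collapse = ", "))
  }
  nut_cols <- setdiff(names(comp), "item_id")
  amounts <- as.matrix(comp[, nut_cols, drop = FALSE])
  rownames(amounts) <- comp$item_id
  n_missing <- sum(is.na(amounts))
  if (n_missing > 0) {
    if (strict) stop(n_missing, " missing nutrient values in comp")
    message(n_missing, " missing nutrient values treated as 0")
    amounts[is.na(amounts)] <- 0
  }

  subjects <- unique(ffq$subject_id)
  # grams consumed per day: subjects x items
  grams <- matrix(0, length(subjects), nrow(comp),
                  dimnames = list(subjects, comp$item_id))
  grams[cbind(match(ffq$subject_id, subjects),
              match(ffq$item_id, comp$item_id))] <-
    ffq$frequency * ffq$portion
  daily <- grams %*% amounts / 100
  energy <- daily[, "energy_kcal"]
  raw <- daily[, setdiff(nut_cols, "energy_kcal"), drop = FALSE]
  intake_table(raw, energy)
}

#' Energy-normalize an intake table
#'
#' Expresses each nutrient intake as a density per 1,000 kcal
#' (`normalized = raw / energy * 1000`, the default), or by the
#' residual method (per-nutrient residual of the regression of raw
#' intake on energy, recentred at the mean intake). Raw values are
#' retained. Subjects with zero or missing energy cannot be normalized:
#' they are dropped from the normalized matrix with a warning.
#'
#' @param intake an [intake_table()].
#' @param method `"density"` (nutrient density per 1,000 kcal, default)
#'   or `"residual"` (energy-adjusted residual method).
#' @return the intake table with the `normalized` matrix filled in.
#' @examples
#' it <- intake_table(matrix(4, 1, 1, dimnames = list("s1", "sodium")),
#'                    energy_kcal_day = 2000)
#' kcal_normalize(it)$normalized  # 2 units per 1,000 kcal
#' @export
kcal_normalize <- function(intake, method = c("density", "residual")) {
  stopifnot(inherits(intake, "intake_table"))
  method <- match.arg(method)
  energy <- intake$energy_kcal_day
  ok <- is.finite(energy) & energy > 0
  if (!all(ok)) {
    warning(sum(!ok), " subject(s) with zero/undefined energy excluded ",
            "from the normalized table: ",
            paste(head(names(energy)[!ok], 5), collapse = ", "))
  }
  raw <- intake$raw[ok, , drop = FALSE]
  if (method == "density") {
    norm <- raw / energy[ok] * 1000
  } else {
    norm <- apply(raw, 2, function(y) {
      fit <- lm(y ~ energy[ok])
      mean(y) + stats::resid(fit)
    })
    rownames(norm) <- rownames(raw)
  }
  intake$normalized <- norm
  intake
}
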