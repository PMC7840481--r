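#' Confirmatory linear model of expression on covariates and intake
#'
#' Fits a Gaussian-identity linear model of (transformed) miRNA
#' expression on subject age, sex, BMI and the nutrient's daily intake,
#' pooled across diet groups. The overall model is tested against the
#' intercept-only null model by an F-test; the nutrient's contribution
#' is *dominant* when its two-sided t-test p-value is below 0.05 and
#' strictly below each of the age, sex and BMI p-values (ties are not
#' dominant).
#'
#' @param y numeric response: expression values, already transformed if
#'   desired (see [confirm_glm()] for the pipeline default,
#'   log2(normalized count + 1)).
#' @param age,bmi,nc numeric predictor vectors.
#' @param sex binary indicator or two-level factor/character.
#' @param mirna_id,nc_id optional identifiers carried into the result.
#' @return one-row data frame: identifiers, per-term coefficients
#'   (`coef_*`) and p-values (`p_*`), `model_p` (F-test vs null),
#'   `model_significant`, `nc_dominant`.
#' @examples
#' set.seed(1)
#' nc <- rnorm(60)
#' fit_glm(2 * nc + rnorm(60), age = rnorm(60),
#'         sex = rbinom(60, 1, 0.5), bmi = rnorm(60), nc = nc)
#' @export
fit_glm <- function(y, age, sex, bmi, nc, mirna_id = NA_character_,
                    nc_id = NA_character_) {
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.numeric(factor(sex)) - 1
  }
  df <- data.frame(y = y, age = age, sex = sex, bmi = bmi, nc = nc)
  if (nrow(df) <= 5) stop("need more than 5 observations")
  if (anyNA(df)) stop("missing values in model data")
  for (v in c("age", "sex", "bmi", "nc")) {
    if (sd(df[[v]]) == 0) {
      stop("degenerate (constant) predictor column: ", v)
    }
  }
  full <- glm(y ~ age + sex + bmi + nc, data = df, family = gaussian())
  null <- glm(y ~ 1, data = df, family = gaussian())
  model_p <- anova(null, full, test = "F")$`Pr(>F)`[2]
  sm <- summary(full)$coefficients
  pv <- sm[, "Pr(>|t|)"]
  co <- sm[, "Estimate"]
  # dominance presupposes a significant overall model: the confirmed
  # pairs are a subset of the model-significant ones
  nc_dominant <- model_p < 0.05 && pv["nc"] < 0.05 &&
    pv["nc"] < min(pv[c("age", "sex", "bmi")])
  data.frame(
    mirna_id = mirna_id, nc_id = nc_id,
    coef_intercept = unname(co["(Intercept)"]),
    coef_age = unname(co["age"]), coef_sex = unname(co["sex"]),
    coef_bmi = unname(co["bmi"]), coef_nc = unname(co["nc"]),
    p_age = unname(pv["age"]), p_sex = unname(pv["sex"]),
    p_bmi = unname(pv["bmi"]), p_nc = unname(pv["nc"]),
    model_p = model_p,
    model_significant = model_p < 0.05,
    nc_dominant = unname(nc_dominant)
  )
}

#' Confirm screened miRNA-nutrient pairs by covariate-adjusted models
#'
#' Runs [fit_glm()] for every screen-significant pair, on all subjects
#' pooled across diet groups, with expression entered as
#' log2(normalized count + 1) by default. Records referencing a miRNA
#' or nutrient absent from the data are skipped with a warning.
#'
#' @param records screen output ([screen_correlations()]), typically
#'   pre-filtered to `significant` rows; rows with
#'   `significant = FALSE` are ignored.
#' @param cm normalized [count_matrix()].
#' @param intake an [intake_table()] with normalized intakes.
#' @param meta metadata data frame (`subject_id`, `age`, `sex`, `bmi`).
#' @param log2_transform fit on log2(normalized + 1) (default TRUE) or
#'   on the normalized scale.
#' @return data frame of [fit_glm()] rows with a `summary` attribute
#'   (counts of fitted, model-significant and NC-dominant pairs).
#' @export
confirm_glm <- function(records, cm, intake, meta,
                        log2_transform = TRUE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(intake, "intake_table"))
  if (is.null(cm$normalized)) stop("run size_factors() first")
  if (is.null(intake$normalized)) stop("run kcal_normalize() first")
  if ("significant" %in% names(records)) {
    records <- records[records$significant, , drop = FALSE]
  }
  samples <- colnames(cm$normalized)
  m <- meta[match(samples, meta$subject_id), ]
  inorm <- intake$normalized[match(samples, rownames(intake$normalized)),
                             , drop = FALSE]
  out <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    mi <- records$mirna_id[r]; nc <- records$nc_id[r]
    if (!mi %in% rownames(cm$normalized) || !nc %in% colnames(inorm)) {
      warning("skipping pair with unknown id: ", mi, " / ", nc)
      next
    }
    y <- cm$normalized[mi, ]
    if (log2_transform) y <- log2(y + 1)
    out[[r]] <- fit_glm(y, age = m$age, sex = m$sex, bmi = m$bmi,
                        nc = inorm[, nc], mirna_id = mi, nc_id = nc)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(
      mirna_id = character(0), nc_id = character(0),
      coef_intercept = numeric(0), coef_age = numeric(0),
      coef_sex = numeric(0), coef_bmi = numeric(0),
      coef_nc = numeric(0), p_age = numeric(0), p_sex = numeric(0),
      p_bmi = numeric(0), p_nc = numeric(0), model_p = numeric(0),
      model_significant = logical(0), nc_dominant = logical(0)
    )
  }
  rownames(res) <- NULL
  attr(res, "summary") <- list(
    n_fitted = nrow(res),
    n_model_significant = sum(res$model_significant),
    n_nc_dominant = sum(res$nc_dominant)
  )
  res
}
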