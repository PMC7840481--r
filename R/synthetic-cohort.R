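#' Specify a synthetic study cohort
#'
#' Bundles all parameters of the synthetic-cohort generator: group
#' sizes, miRNA and nutrient panel sizes, sequencing depth range,
#' negative-binomial dispersion, optional covariate effects on
#' log-expression, planted miRNA-nutrient associations, and the RNG
#' seed. Defaults emulate the target study design: three equal dietary
#' groups of 40 subjects (120 total), a plasma miRNA panel with
#' strongly skewed abundances, the 23-nutrient panel, and typical
#' plasma small RNA-seq overdispersion (variance mu + 0.2 mu^2).
#'
#' @param n_per_group subjects per dietary group (>= 3).
#' @param groups ordered diet labels; the first is the linear-model
#'   reference level and the trend baseline.
#' @param n_mirna number of miRNAs simulated.
#' @param n_nc number of nutrients (<= 23 draws ids from
#'   [nc_compounds()]; more appends generic ids).
#' @param planted_pairs list of [planted_effect()] ground-truth
#'   associations.
#' @param depth_range length-2 numeric, min/max library size in reads.
#' @param dispersion NB dispersion alpha (variance mu + alpha mu^2);
#'   scalar or per-miRNA vector.
#' @param covariate_effects optional named list with any of `age`,
#'   `sex`, `bmi`: per-unit additive effects on log expression applied
#'   to all miRNAs (centred, so library totals are preserved).
#' @param signal_sd log-scale amplitude of the planted latent signal.
#' @param bmi_shift additive shift of mean BMI in the first (omnivore)
#'   group, reflecting the higher BMI typically seen in omnivores.
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return an object of class `cohort_spec`.
#' @examples
#' sp <- cohort_spec(n_per_group = 10, n_mirna = 50, n_nc = 5, seed = 1)
#' @export
cohort_spec <- function(n_per_group = 40,
                        groups = c("omnivore", "vegetarian", "vegan"),
                        n_mirna = 400,
                        n_nc = 23,
                        planted_pairs = list(),
                        depth_range = c(5e5, 1.5e6),
                        dispersion = 0.2,
                        covariate_effects = NULL,
                        signal_sd = 1.2,
                        bmi_shift = 1.5,
                        seed = 1) {
  fail <- function(field, why) {
    stop("invalid cohort_spec: field '", field, "' ", why, call. = FALSE)
  }
  if (!is.numeric(n_per_group) || n_per_group < 3) {
    fail("n_per_group", "must be >= 3")
  }
  if (length(groups) < 1 || anyDuplicated(groups)) {
    fail("groups", "must be distinct labels")
  }
  if (!is.numeric(n_mirna) || n_mirna < 1) fail("n_mirna", "must be >= 1")
  if (!is.numeric(n_nc) || n_nc < 1) fail("n_nc", "must be >= 1")
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2] ||
      depth_range[1] <= 0) {
    fail("depth_range", "must be positive with min <= max")
  }
  if (any(dispersion <= 0)) fail("dispersion", "must be > 0")
  if (!is.numeric(seed) || length(seed) != 1) fail("seed", "must be scalar")
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirna))
  nc_ids <- synthetic_nc_ids(n_nc)
  for (pp in planted_pairs) {
    if (!inherits(pp, "planted_effect")) {
      fail("planted_pairs", "entries must be planted_effect objects")
    }
    if (!pp$mirna_id %in% mirna_ids) {
      fail("planted_pairs", paste0("references unknown miRNA ", pp$mirna_id))
    }
    if (!pp$nc_id %in% nc_ids) {
      fail("planted_pairs", paste0("references unknown NC ", pp$nc_id))
    }
    if (!is.null(pp$applies_to_groups) &&
        !all(pp$applies_to_groups %in% groups)) {
      fail("planted_pairs", "applies_to_groups outside spec groups")
    }
  }
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         n_mirna = as.integer(n_mirna), n_nc = as.integer(n_nc),
         mirna_ids = mirna_ids, nc_ids = nc_ids,
         planted_pairs = planted_pairs,
         depth_range = depth_range, dispersion = dispersion,
         covariate_effects = covariate_effects,
         signal_sd = signal_sd, bmi_shift = bmi_shift,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Describe a planted miRNA-nutrient association
#'
#' Ground truth for recovery tests: the generator calibrates the latent
#' coupling so that the realized Spearman correlation between the
#' nutrient's energy-normalized intake and the miRNA's normalized
#' expression approximates `target_rho` in each group it applies to.
#'
#' @param mirna_id,nc_id identifiers present in the [cohort_spec()].
#' @param target_rho target Spearman correlation, |rho| < 1.
#' @param applies_to_groups subset of diet groups (default: all).
#' @return an object of class `planted_effect`.
#' @export
planted_effect <- function(mirna_id, nc_id, target_rho,
                           applies_to_groups = NULL) {
  if (!is.numeric(target_rho) || abs(target_rho) >= 1) {
    stop("target_rho must satisfy |rho| < 1")
  }
  structure(
    list(mirna_id = mirna_id, nc_id = nc_id,
         target_rho = target_rho, applies_to_groups = applies_to_groups),
    class = "planted_effect"
  )
}

synthetic_nc_ids <- function(n_nc) {
  known <- nc_compounds()$nc_id
  if (n_nc <= length(known)) head(known, n_nc) else
    c(known, sprintf("nc%02d", seq_len(n_nc - length(known))))
}

#' Assign the WHO BMI class
#'
#' Classes: underweight (BMI < 18.5), healthy (18.5 <= BMI <= 25),
#' overweight (25 < BMI <= 30), obese (BMI > 30). The WHO tables print
#' the overweight band as 26-30; values falling in the printed gap
#' (25, 26) are assigned to overweight for continuity.
#'
#' @param bmi numeric vector of body-mass indices (kg/m^2), > 0.
#' @return character vector of classes.
#' @examples
#' derive_bmi_class(c(18.4, 18.5, 25.5, 30.1))
#' @export
derive_bmi_class <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) stop("bmi must be > 0")
  cls <- as.character(cut(
    bmi, breaks = c(0, 18.5, 25, 30, Inf),
    labels = c("underweight", "healthy", "overweight", "obese"),
    right = FALSE, include.lowest = TRUE
  ))
  # cut() with right = FALSE puts 18.5 in healthy and 25 in overweight;
  # fix the two boundaries the thresholds pin down explicitly
  cls[bmi == 25] <- "healthy"
  cls[bmi == 30] <- "overweight"
  cls
}

# truncated-normal draws by rejection (seeded, deterministic)
rtnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# Calibrate the Gaussian-copula mixing weight w so that the Spearman
# correlation between intake rank score z and the depth-normalized NB
# count approximates target_rho. f(w) is estimated by a small Monte
# Carlo and is monotone in w; bisection on [-0.999, 0.999].
calibrate_copula_weight <- function(z, base_mu, depth, size, amp,
                                    target_rho, n_rep = 25L,
                                    n_iter = 12L) {
  f <- function(w) {
    r <- vapply(seq_len(n_rep), function(i) {
      e <- rnorm(length(z))
      lat <- w * z + sqrt(1 - w^2) * e
      mu <- base_mu * exp(amp * lat - amp^2 / 2)
      y <- rnbinom(length(z), mu = mu, size = size)
      suppressWarnings(cor(z, y / depth, method = "spearman"))
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }
  lo <- -0.999; hi <- 0.999
  if (f(hi) < target_rho) return(hi)
  if (f(lo) > target_rho) return(lo)
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target_rho) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a complete synthetic cohort
#'
#' Draws subject metadata (diet group, age, sex, BMI), energy and
#' per-nutrient daily intakes, and a raw miRNA count matrix with
#' sample-specific sequencing depth and NB noise. Planted associations
#' couple a miRNA's latent log-expression to a nutrient's
#' energy-normalized intake through a Gaussian copula whose mixing
#' weight is calibrated by bisection so the realized Spearman
#' correlation approximates the target. Planted miRNAs are promoted to
#' at least the 75th abundance percentile so they survive the
#' detectability filters the downstream screen applies.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements:
#'   \describe{
#'     \item{counts}{[count_matrix()] of raw counts (miRNA x sample).}
#'     \item{metadata}{data frame: subject_id, diet_group, age, sex,
#'       bmi, bmi_class.}
#'     \item{intake}{[intake_table()] with raw and kcal-normalized
#'       intakes.}
#'     \item{ground_truth}{data frame of planted pairs with the
#'       calibrated copula weight and the realized per-group Spearman
#'       rho of depth-normalized counts vs intake.}
#'   }
#' @examples
#' sim <- generate_cohort(cohort_spec(n_per_group = 5, n_mirna = 20,
#'                                    n_nc = 3, seed = 42))
#' dim(sim$counts)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_groups <- length(spec$groups)
  n <- spec$n_per_group * n_groups
  subject_id <- sprintf("S%03d", seq_len(n))
  diet_group <- factor(rep(spec$groups, each = spec$n_per_group),
                       levels = spec$groups)

  # demographics: ~60% women, age centred at 45, BMI slightly higher in
  # the first (omnivore) group
  sex <- ifelse(rbinom(n, 1, 0.6) == 1, "F", "M")
  age <- rtnorm(n, 45, 12, 18, 80)
  bmi_mean <- ifelse(diet_group == spec$groups[1], 23 + spec$bmi_shift, 23)
  bmi <- rtnorm(n, bmi_mean, 3, 16, 45)
  metadata <- data.frame(
    subject_id = subject_id, diet_group = diet_group,
    age = age, sex = sex, bmi = bmi,
    bmi_class = derive_bmi_class(bmi)
  )

  # intakes: log-normal raw intakes on nutrient-specific scales,
  # energy ~ 2,100 kcal/day, density normalization per 1,000 kcal
  energy <- rtnorm(n, 2100, 300, 1200, 3500)
  scale_log <- runif(spec$n_nc, 0, 6)
  raw_intake <- sapply(seq_len(spec$n_nc), function(k) {
    rlnorm(n, meanlog = scale_log[k], sdlog = 0.4)
  })
  dimnames(raw_intake) <- list(subject_id, spec$nc_ids)
  intake <- kcal_normalize(intake_table(raw_intake, energy))

  # miRNA relative abundances: heavily skewed, as in plasma miRNomes
  p <- exp(rnorm(spec$n_mirna, 0, 1.8))
  planted_mirnas <- unique(vapply(spec$planted_pairs,
                                  function(x) x$mirna_id, character(1)))
  if (length(planted_mirnas) > 0) {
    hi <- quantile(p, 0.75)
    idx <- match(planted_mirnas, spec$mirna_ids)
    p[idx] <- pmax(p[idx], hi)
  }
  p <- p / sum(p)
  depth <- runif(n, spec$depth_range[1], spec$depth_range[2])

  log_mu <- outer(log(p), log(depth), "+")
  dimnames(log_mu) <- list(spec$mirna_ids, subject_id)

  ce <- spec$covariate_effects
  if (!is.null(ce)) {
    eta <- rep(0, n)
    if (!is.null(ce$age)) eta <- eta + ce$age * (age - mean(age))
    if (!is.null(ce$sex)) {
      f <- as.numeric(sex == "F"); eta <- eta + ce$sex * (f - mean(f))
    }
    if (!is.null(ce$bmi)) eta <- eta + ce$bmi * (bmi - mean(bmi))
    log_mu <- sweep(log_mu, 2, eta, "+")
  }

  size <- 1 / spec$dispersion  # NB size parameter, recycled over miRNAs
  size_vec <- rep(size, length.out = spec$n_mirna)

  amp <- spec$signal_sd
  gt <- NULL
  for (pp in spec$planted_pairs) {
    gsel <- if (is.null(pp$applies_to_groups)) spec$groups else
      pp$applies_to_groups
    sel <- diet_group %in% gsel
    i <- match(pp$mirna_id, spec$mirna_ids)
    x <- intake$normalized[sel, pp$nc_id]
    z <- qnorm((rank(x) - 0.5) / length(x))
    w <- calibrate_copula_weight(
      z, base_mu = exp(log_mu[i, sel]), depth = depth[sel],
      size = size_vec[i], amp = amp, target_rho = pp$target_rho
    )
    e <- rnorm(sum(sel))
    lat <- w * z + sqrt(1 - w^2) * e
    log_mu[i, sel] <- log_mu[i, sel] + amp * lat - amp^2 / 2
    gt <- rbind(gt, data.frame(
      mirna_id = pp$mirna_id, nc_id = pp$nc_id,
      target_rho = pp$target_rho, copula_weight = w,
      groups = paste(gsel, collapse = ";")
    ))
  }

  counts <- matrix(
    rnbinom(spec$n_mirna * n, mu = exp(log_mu),
            size = rep(size_vec, times = n)),
    nrow = spec$n_mirna,
    dimnames = list(spec$mirna_ids, subject_id)
  )

  if (!is.null(gt)) {
    for (r in seq_len(nrow(gt))) {
      i <- gt$mirna_id[r]
      for (g in spec$groups) {
        sel <- diet_group == g
        rho <- suppressWarnings(cor(
          intake$normalized[sel, gt$nc_id[r]],
          counts[i, sel] / depth[sel], method = "spearman"
        ))
        gt[r, paste0("realized_rho_", g)] <- rho
      }
    }
  } else {
    gt <- data.frame(mirna_id = character(0), nc_id = character(0),
                     target_rho = numeric(0))
  }

  list(counts = count_matrix(counts), metadata = metadata,
       intake = intake, ground_truth = gt)
}

#' Generate synthetic FFQ responses and a food-composition table
#'
#' Produces item-level questionnaire responses (daily consumption
#' frequency and portion size per consumed item) for every subject of
#' the cohort, plus a matching composition table giving energy and each
#' nutrient amount per 100 g. Feeding the pair through
#' [compute_intake()] and [kcal_normalize()] yields an intake table of
#' the same shape the cohort generator emits directly.
#'
#' @param spec a [cohort_spec()].
#' @param n_items number of food items (default 188, a full
#'   EPIC-style questionnaire food list).
#' @return list with `ffq` (data frame: subject_id, item_id, frequency,
#'   portion) and `composition` (data frame: item_id, energy_kcal, one
#'   column per nutrient).
#' @export
generate_ffq <- function(spec, n_items = 188) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.numeric(n_items) || n_items < 1) stop("n_items must be >= 1")
  set.seed(spec$seed + 7919L)
  n <- spec$n_per_group * length(spec$groups)
  subject_id <- sprintf("S%03d", seq_len(n))
  item_id <- sprintf("item%03d", seq_len(n_items))

  energy_kcal <- runif(n_items, 40, 600)
  scale_log <- runif(spec$n_nc, -1, 4)
  amounts <- sapply(seq_len(spec$n_nc), function(k) {
    rlnorm(n_items, scale_log[k], 0.8) *
      rbinom(n_items, 1, 0.7)  # not every nutrient occurs in every food
  })
  composition <- data.frame(item_id = item_id, energy_kcal = energy_kcal)
  composition[spec$nc_ids] <- amounts

  rows <- lapply(subject_id, function(s) {
    eaten <- which(runif(n_items) < 0.35)
    if (length(eaten) == 0) return(NULL)
    data.frame(
      subject_id = s, item_id = item_id[eaten],
      frequency = rgamma(length(eaten), shape = 1.2, scale = 0.5),
      portion = rlnorm(length(eaten), log(80), 0.35)
    )
  })
  ffq <- do.call(rbind, rows)
  rownames(ffq) <- NULL
  list(ffq = ffq, composition = composition)
}
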