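#' Split subjects into high- and low-intake groups at the median
#'
#' Subjects with intake strictly above the median are labelled `high`;
#' subjects at or below the median (including ties at the median) are
#' labelled `low`.
#'
#' @param intake an [intake_table()] (normalized slot used when
#'   available) or a named numeric vector of intakes.
#' @param nc_id nutrient column to split on (ignored for a vector).
#' @return factor with levels `c("low", "high")`, named by subject.
#' @examples
#' median_split(c(a = 1, b = 2, c = 3, d = 4))
#' @export
median_split <- function(intake, nc_id = NULL) {
  if (inherits(intake, "intake_table")) {
    m <- if (!is.null(intake$normalized)) intake$normalized else intake$raw
    if (!nc_id %in% colnames(m)) stop("unknown nc_id: ", nc_id)
    x <- m[, nc_id]
    names(x) <- rownames(m)
  } else {
    x <- intake
  }
  if (length(x) < 4) stop("need at least 4 subjects")
  if (anyNA(x)) stop("missing intakes")
  med <- median(x)
  if (all(x == x[1])) stop("all intakes equal: median split undefined")
  lab <- factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
  names(lab) <- names(x)
  lab
}

# Negative-binomial regression with fixed dispersion used for both the
# full and reduced model; theta estimated by ML on the full model via
# MASS::glm.nb and shared (single dispersion per miRNA, no shrinkage).
fit_nb_pair <- function(counts, design_full, design_reduced, off) {
  ctl <- glm.control(epsilon = 1e-10, maxit = 200)
  make <- function(design) {
    d <- cbind(.counts = counts, design, .off = off)
    f <- stats::as.formula(paste(
      ".counts ~", paste(names(design), collapse = " + "),
      "+ offset(.off)"
    ), env = environment())
    list(d = d, f = f)
  }
  mf <- make(design_full); mr <- make(design_reduced)
  full0 <- tryCatch(
    suppressWarnings(MASS::glm.nb(mf$f, data = mf$d, control = ctl)),
    error = function(e) NULL
  )
  theta <- if (is.null(full0)) NULL else full0$theta
  if (is.null(theta) || !is.finite(theta)) theta <- 1e6
  theta <- min(max(theta, 1e-4), 1e8)
  fam <- MASS::negative.binomial(theta)
  full <- glm(mf$f, data = mf$d, family = fam, control = ctl)
  reduced <- glm(mr$f, data = mr$d, family = fam, control = ctl)
  list(full = full, reduced = reduced, theta = theta)
}

#' Negative-binomial likelihood-ratio test for one miRNA
#'
#' Tests an intake-group effect on raw counts by comparing nested NB
#' regressions with a log link and log-size-factor offset: the full
#' model contains age, sex, BMI, diet-group indicators and the
#' high/low-intake indicator; the reduced model drops the intake
#' indicator. The dispersion is estimated by maximum likelihood on the
#' full model and shared by both fits; the statistic
#' `2 (loglik_full - loglik_reduced)` is referred to chi-square with
#' 1 df, and the log2 fold-change is the intake coefficient / ln 2.
#'
#' @param counts non-negative integer counts, one per subject.
#' @param meta metadata data frame (`age`, `sex`, `bmi`, `diet_group`)
#'   in subject order matching `counts`.
#' @param split high/low factor from [median_split()], same order.
#' @param sf positive size factors, same order.
#' @return one-row data frame: `log2FC`, `p`, `theta` (NB size),
#'   `converged`; on non-convergence `p` and `log2FC` are `NA` and
#'   `reason` records why.
#' @export
nb_lrt <- function(counts, meta, split, sf) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(sf <= 0)) stop("size factors must be positive")
  sex <- if (is.numeric(meta$sex)) meta$sex else
    as.numeric(factor(meta$sex)) - 1
  diet <- droplevels(factor(meta$diet_group))
  base <- data.frame(age = meta$age, sex = sex, bmi = meta$bmi)
  if (nlevels(diet) > 1) base$diet_group <- diet
  dfull <- cbind(base, intake_group = split)
  off <- log(sf)
  fit <- tryCatch(
    fit_nb_pair(counts, dfull, base, off),
    error = function(e) e
  )
  if (inherits(fit, "error") || !fit$full$converged ||
      !fit$reduced$converged) {
    reason <- if (inherits(fit, "error")) conditionMessage(fit) else
      "IRLS did not converge"
    return(data.frame(log2FC = NA_real_, p = NA_real_,
                      theta = NA_real_, converged = FALSE,
                      reason = reason))
  }
  stat <- max(0, 2 * (as.numeric(logLik(fit$full)) -
                        as.numeric(logLik(fit$reduced))))
  co <- coef(fit$full)["intake_grouphigh"]
  data.frame(log2FC = unname(co) / log(2),
             p = pchisq(stat, df = 1, lower.tail = FALSE),
             theta = fit$theta, converged = TRUE,
             reason = NA_character_)
}

#' Differential expression between high- and low-intake subjects
#'
#' For one nutrient: splits the cohort at the median intake, runs the
#' NB likelihood-ratio test ([nb_lrt()]) on every miRNA, adjusts
#' p-values across tested miRNAs by Benjamini-Hochberg, and flags a
#' miRNA as expressed when its median normalized count exceeds 15 (the
#' detectability cutoff) in at least one intake group. A miRNA is
#' *significant* when its raw p < 0.05 and it passes the expression
#' flag.
#'
#' @param cm [count_matrix()] with size factors computed.
#' @param intake an [intake_table()].
#' @param meta metadata data frame.
#' @param nc_id nutrient to stratify on.
#' @param mirnas optional subset of miRNA ids to test (default: all).
#' @param threshold expressed-flag cutoff on median normalized counts.
#' @return data frame: `mirna_id`, `nc_id`, `base_mean` (average
#'   normalized count), `log2FC`, `p`, `p_adj`, `expressed_flag`,
#'   `significant`, `converged`.
#' @export
de_analysis <- function(cm, intake, meta, nc_id, mirnas = NULL,
                        threshold = 15) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$size_factors)) stop("run size_factors() first")
  samples <- colnames(cm$counts)
  m <- meta[match(samples, meta$subject_id), ]
  split_all <- median_split(intake, nc_id)
  split <- split_all[samples]
  if (anyNA(split)) stop("samples missing from the intake table")
  if (is.null(mirnas)) mirnas <- rownames(cm$counts)
  sf <- cm$size_factors
  res <- do.call(rbind, lapply(mirnas, function(mi) {
    r <- nb_lrt(cm$counts[mi, ], m, split, sf)
    r$mirna_id <- mi
    r
  }))
  norm <- cm$normalized[mirnas, , drop = FALSE]
  med_hi <- apply(norm[, split == "high", drop = FALSE], 1, median)
  med_lo <- apply(norm[, split == "low", drop = FALSE], 1, median)
  res$nc_id <- nc_id
  res$base_mean <- rowMeans(norm)
  res$expressed_flag <- med_hi > threshold | med_lo > threshold
  res$p_adj <- NA_real_
  tested <- res$converged & !is.na(res$p)
  res$p_adj[tested] <- bh_adjust(res$p[tested])
  res$significant <- !is.na(res$p) & res$p < 0.05 & res$expressed_flag
  res[c("mirna_id", "nc_id", "base_mean", "log2FC", "p", "p_adj",
        "expressed_flag", "significant", "converged", "reason")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving false-discovery-rate adjustment (step-up with
#' monotonicity enforcement), delegated to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
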