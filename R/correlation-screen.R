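#' Spearman rank correlation with t-approximation p-value
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranked
#' values (ties receive average ranks) and a two-sided p-value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom — the behaviour of the `rcorr`-style correlation
#' used for screening at all sample sizes.
#'
#' @param x,y paired numeric vectors, length >= 4, no missing values.
#' @return list with `rho` and `p`. A constant input vector makes rho
#'   undefined: both are returned as `NA` (callers drop such pairs).
#' @examples
#' spearman(1:10, (1:10)^2)   # rho = 1, p = 0
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = NA_real_, p = NA_real_))
  rho <- cor(rank(x), rank(y))
  p <- spearman_t_pvalue(rho, n)
  list(rho = rho, p = p)
}

spearman_t_pvalue <- function(rho, n) {
  ifelse(abs(rho) >= 1, 0,
         2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2))
}

#' Configure the correlation screen
#'
#' @param rho_threshold minimum absolute average rho (strict, default
#'   0.3).
#' @param p_threshold per-group significance level (default 0.05).
#' @param min_sig_groups number of diet groups that must reach
#'   `p < p_threshold` (default 2).
#' @param group_order diet labels in the order used for trend
#'   classification (omnivore to vegan by default).
#' @param rho_on apply the rho threshold to the absolute average rho
#'   across groups (`"average"`, default) or to every group's rho
#'   (`"per_group"`).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(rho_threshold = 0.3, p_threshold = 0.05,
                          min_sig_groups = 2,
                          group_order = c("omnivore", "vegetarian",
                                          "vegan"),
                          rho_on = c("average", "per_group")) {
  if (rho_threshold <= 0 || rho_threshold >= 1) {
    stop("rho_threshold must be in (0, 1)")
  }
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must be in (0, 1)")
  }
  if (min_sig_groups < 1 || min_sig_groups > length(group_order)) {
    stop("min_sig_groups must be between 1 and the number of groups")
  }
  structure(
    list(rho_threshold = rho_threshold, p_threshold = p_threshold,
         min_sig_groups = as.integer(min_sig_groups),
         group_order = group_order, rho_on = match.arg(rho_on)),
    class = "screen_config"
  )
}

#' Diet-stratified correlation screen of miRNA expression vs intake
#'
#' For every (analysis-set miRNA, nutrient) pair, computes the Spearman
#' correlation between normalized expression and energy-normalized
#' intake separately in each dietary group, then applies the screening
#' filters: a pair is *coherent* when all per-group rhos share one sign
#' (a zero rho breaks coherence), and *significant* when it is coherent,
#' reaches `p < p_threshold` in at least `min_sig_groups` groups, and
#' its absolute average rho exceeds `rho_threshold`. Each significant
#' pair is also classified for a progressive trend in |rho| along
#' `group_order`.
#'
#' @param cm normalized [count_matrix()]; rows restricted to the
#'   analysis set (see [analysis_set()]) before or via `keep`.
#' @param intake an [intake_table()] with the normalized slot filled.
#' @param meta metadata data frame with `subject_id` matching the count
#'   columns and `diet_group`.
#' @param cfg a [screen_config()].
#' @param keep optional logical/character selector of analysis-set
#'   miRNAs (e.g. `in_analysis_set` from [analysis_set()]).
#' @return data frame with one row per tested pair: `mirna_id`,
#'   `nc_id`, per-group `rho_<group>` / `p_<group>`, `average_rho`,
#'   `coherent`, `n_sig_groups`, `significant`, `trend`. Pairs dropped
#'   because one vector was constant are listed in the
#'   `dropped_pairs` attribute.
#' @export
screen_correlations <- function(cm, intake, meta, cfg = screen_config(),
                                keep = NULL) {
  stopifnot(inherits(cm, "count_matrix"), inherits(intake, "intake_table"))
  if (is.null(cm$normalized)) stop("run size_factors() first")
  if (is.null(intake$normalized)) stop("run kcal_normalize() first")
  expr <- cm$normalized
  if (!is.null(keep)) expr <- expr[keep, , drop = FALSE]
  samples <- colnames(expr)
  m <- meta[match(samples, meta$subject_id), ]
  if (anyNA(m$subject_id)) stop("samples missing from metadata")
  inorm <- intake$normalized[match(samples, rownames(intake$normalized)),
                             , drop = FALSE]
  if (anyNA(rownames(inorm))) stop("samples missing from intake table")
  groups <- cfg$group_order
  if (!all(groups %in% m$diet_group)) {
    stop("group_order contains groups absent from metadata: ",
         paste(setdiff(groups, m$diet_group), collapse = ", "))
  }
  small <- groups[table(factor(m$diet_group, groups))[groups] < 4]
  if (length(small) > 0) {
    stop("dietary group(s) with fewer than 4 subjects: ",
         paste(small, collapse = ", "))
  }

  mirnas <- rownames(expr)
  ncs <- colnames(inorm)
  res <- expand.grid(mirna_id = mirnas, nc_id = ncs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (g in groups) {
    sel <- m$diet_group == g
    n_g <- sum(sel)
    re <- apply(expr[, sel, drop = FALSE], 1, rank)   # n_g x mirna
    ri <- apply(inorm[sel, , drop = FALSE], 2, rank)  # n_g x nc
    rho <- suppressWarnings(cor(re, ri))              # mirna x nc
    res[[paste0("rho_", g)]] <- as.vector(rho)
    res[[paste0("p_", g)]] <- as.vector(spearman_t_pvalue(rho, n_g))
  }
  rho_cols <- paste0("rho_", groups)
  p_cols <- paste0("p_", groups)
  rho_mat <- as.matrix(res[rho_cols])
  p_mat <- as.matrix(res[p_cols])

  dropped <- res[apply(is.na(rho_mat), 1, any), c("mirna_id", "nc_id")]
  complete <- !apply(is.na(rho_mat), 1, any)
  res <- res[complete, , drop = FALSE]
  rho_mat <- rho_mat[complete, , drop = FALSE]
  p_mat <- p_mat[complete, , drop = FALSE]

  res$average_rho <- rowMeans(rho_mat)
  res$coherent <- apply(rho_mat, 1, function(r) {
    all(r > 0) || all(r < 0)
  })
  res$n_sig_groups <- rowSums(p_mat < cfg$p_threshold)
  rho_pass <- if (cfg$rho_on == "average") {
    abs(res$average_rho) > cfg$rho_threshold
  } else {
    apply(abs(rho_mat) > cfg$rho_threshold, 1, all)
  }
  res$significant <- res$coherent &
    res$n_sig_groups >= cfg$min_sig_groups & rho_pass
  res$trend <- classify_trend(rho_mat)
  rownames(res) <- NULL
  attr(res, "dropped_pairs") <- dropped
  attr(res, "config") <- cfg
  res
}

#' Classify a progressive |rho| trend across diet groups
#'
#' A pair's correlation trend is `increasing` when the absolute
#' per-group rho strictly increases along the group order (omnivore to
#' vegan by default), `decreasing` when it strictly decreases, and
#' `none` otherwise (any tie breaks strictness).
#'
#' @param rho_by_group numeric matrix (pairs x groups, in group order)
#'   or a single numeric vector of per-group rhos.
#' @return character vector in `{"increasing", "decreasing", "none"}`.
#' @examples
#' classify_trend(c(0.20, 0.30, 0.45))  # "increasing"
#' classify_trend(c(0.40, 0.40, 0.45))  # "none": the tie breaks it
#' @export
classify_trend <- function(rho_by_group) {
  if (is.null(dim(rho_by_group))) {
    rho_by_group <- matrix(rho_by_group, nrow = 1)
  }
  if (anyNA(rho_by_group)) stop("rho missing for some group")
  a <- abs(rho_by_group)
  d <- a[, -1, drop = FALSE] - a[, -ncol(a), drop = FALSE]
  ifelse(apply(d > 0, 1, all), "increasing",
         ifelse(apply(d < 0, 1, all), "decreasing", "none"))
}

#' Cohort balance checks across dietary groups
#'
#' Standard between-group comparability tests: chi-square tests of sex
#' and BMI-class composition against diet group, a Kruskal-Wallis test
#' of age, and pairwise Wilcoxon rank-sum tests of BMI between every
#' pair of groups.
#'
#' @param meta metadata data frame with `diet_group`, `sex`, `age`,
#'   `bmi`, `bmi_class`.
#' @return list with `sex_chisq`, `bmi_class_chisq`, `age_kruskal`
#'   (each: statistic, p) and `bmi_wilcoxon` (data frame of pairwise
#'   comparisons). Groups of size < 2 cause the affected test to be
#'   skipped with a warning.
#' @export
cohort_checks <- function(meta) {
  g <- droplevels(factor(meta$diet_group))
  if (nlevels(g) < 2) stop("need at least 2 dietary groups")
  small <- names(which(table(g) < 2))
  if (length(small) > 0) {
    warning("group(s) with < 2 subjects skipped: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    meta <- meta[keep, ]; g <- droplevels(g[keep])
  }
  chis <- function(x) {
    t <- suppressWarnings(chisq.test(table(x, g)))
    list(statistic = unname(t$statistic), p = t$p.value)
  }
  kw <- kruskal.test(meta$age, g)
  lev <- levels(g)
  pairs <- t(combn(lev, 2))
  wil <- data.frame(
    group1 = pairs[, 1], group2 = pairs[, 2],
    p = apply(pairs, 1, function(pr) {
      wilcox.test(meta$bmi[g == pr[1]], meta$bmi[g == pr[2]])$p.value
    })
  )
  list(
    sex_chisq = chis(meta$sex),
    bmi_class_chisq = chis(meta$bmi_class),
    age_kruskal = list(statistic = unname(kw$statistic), p = kw$p.value),
    bmi_wilcoxon = wil
  )
}
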