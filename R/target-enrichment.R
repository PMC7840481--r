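#' Aggregate differential-expression evidence onto target genes
#'
#' Maps miRNA-level DE evidence to genes through a miRNA-target
#' annotation. Each miRNA contributes a signed weight
#' `w = -sign(log2FC) * (-log10 p_adj)`: the sign is flipped because an
#' up-regulated miRNA represses its targets. A gene's score is the sum
#' of the weights of all miRNAs annotated to target it; genes with no
#' targeting miRNA in the input are absent from the output. Zero
#' p-values are capped at the smallest representable double with a
#' warning.
#'
#' @param de DE table with columns `mirna_id`, `log2FC` and `p_adj`
#'   (see [de_analysis()]); rows with missing values are dropped.
#' @param targets annotation data frame with columns `mirna_id`,
#'   `gene_id` (duplicated pairs across evidence sources are merged).
#' @return data frame: `gene_id`, `score`, `n_supporting_mirnas`.
#' @examples
#' de <- data.frame(mirna_id = "m1", log2FC = 1, p_adj = 0.01)
#' tg <- data.frame(mirna_id = "m1", gene_id = "G1")
#' gene_scores(de, tg)  # score -2
#' @export
gene_scores <- function(de, targets) {
  need <- c("mirna_id", "log2FC", "p_adj")
  if (!all(need %in% names(de))) {
    stop("de must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("mirna_id", "gene_id") %in% names(targets))) {
    stop("targets must have columns mirna_id and gene_id")
  }
  de <- de[is.finite(de$log2FC) & is.finite(de$p_adj), , drop = FALSE]
  p <- de$p_adj
  if (any(p == 0)) {
    warning(sum(p == 0), " zero p-value(s) capped at machine minimum")
    p[p == 0] <- .Machine$double.xmin
  }
  w <- -sign(de$log2FC) * (-log10(p))
  names(w) <- de$mirna_id
  targets <- unique(targets[c("mirna_id", "gene_id")])
  targets <- targets[targets$mirna_id %in% de$mirna_id, , drop = FALSE]
  if (nrow(targets) == 0) {
    return(data.frame(gene_id = character(0), score = numeric(0),
                      n_supporting_mirnas = integer(0)))
  }
  sc <- tapply(w[targets$mirna_id], targets$gene_id, sum)
  ns <- tapply(targets$mirna_id, targets$gene_id, length)
  data.frame(gene_id = names(sc), score = as.numeric(sc),
             n_supporting_mirnas = as.integer(ns[names(sc)]),
             row.names = NULL)
}

# plain logistic log-likelihood with optional L2 ridge penalty on the
# slope; used as a fallback under perfect separation
ridge_logistic <- function(member, score, lambda = 1e-3) {
  X <- cbind(1, score)
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    # log(1 + exp(eta)) without overflow for large |eta|
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    sum(lse) - sum(member * eta) + lambda * b[2]^2
  }
  fit <- optim(c(0, 0), nll, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(fit$hessian)))
  z <- fit$par[2] / se[2]
  list(coefficient = fit$par[2], p = 2 * pnorm(-abs(z)))
}

#' Logistic-regression gene-set enrichment
#'
#' For each gene set, fits a logistic model of set membership (over the
#' universe of scored genes) on the gene score, reports the slope and
#' its Wald p-value, adjusts p-values across tested sets by
#' Benjamini-Hochberg, and applies the retention filters: adjusted
#' p < 0.05, |coefficient| > 0.5, and at least 2 scored target genes in
#' the set. Sets with fewer than 2 scored members are left untested.
#' Under perfect separation the fit falls back to a lightly ridge-
#' penalized logistic model and is flagged.
#'
#' @param scores gene-score table from [gene_scores()] (>= 2 genes).
#' @param sets named list of character vectors of gene ids (e.g. from
#'   [read_gmt()]); each set is intersected with the scored universe.
#' @return data frame: `set_id`, `coefficient`, `p`, `p_adj`,
#'   `n_target_genes_in_set`, `penalized`, `retained`.
#' @export
logistic_gsa <- function(scores, sets) {
  if (nrow(scores) < 2) stop("need at least 2 scored genes")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a named list")
  }
  universe <- scores$gene_id
  res <- do.call(rbind, lapply(names(sets), function(s) {
    member <- as.numeric(universe %in% sets[[s]])
    n_in <- sum(member)
    if (n_in < 2 || n_in == length(member)) {
      return(data.frame(set_id = s, coefficient = NA_real_,
                        p = NA_real_, n_target_genes_in_set = n_in,
                        penalized = FALSE))
    }
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(member ~ scores$score, family = binomial(),
          control = glm.control(epsilon = 1e-12, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    if (sep || !fit$converged) {
      rf <- ridge_logistic(member, scores$score)
      data.frame(set_id = s, coefficient = rf$coefficient, p = rf$p,
                 n_target_genes_in_set = n_in, penalized = TRUE)
    } else {
      sm <- summary(fit)$coefficients
      data.frame(set_id = s, coefficient = sm[2, "Estimate"],
                 p = sm[2, "Pr(>|z|)"], n_target_genes_in_set = n_in,
                 penalized = FALSE)
    }
  }))
  res$p_adj <- NA_real_
  tested <- !is.na(res$p)
  res$p_adj[tested] <- bh_adjust(res$p[tested])
  res$retained <- tested & res$p_adj < 0.05 &
    abs(res$coefficient) > 0.5 & res$n_target_genes_in_set >= 2
  res[c("set_id", "coefficient", "p", "p_adj",
        "n_target_genes_in_set", "penalized", "retained")]
}

#' Direction-split target enrichment
#'
#' Runs the gene-score aggregation and logistic enrichment separately
#' on miRNAs positively and negatively associated with the nutrient, as
#' the screen's sign indicates (positively correlated miRNAs are
#' expected up-regulated in high-intake subjects and vice versa).
#'
#' @param de DE table ([de_analysis()]).
#' @param targets miRNA-target annotation data frame.
#' @param sets named list of gene sets.
#' @param direction which miRNAs to use: `"positive"` (log2FC > 0) or
#'   `"negative"` (log2FC < 0).
#' @return [logistic_gsa()] result for the selected direction.
#' @export
enrich_targets <- function(de, targets, sets,
                           direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  sel <- if (direction == "positive") de$log2FC > 0 else de$log2FC < 0
  sub <- de[sel & is.finite(de$log2FC), , drop = FALSE]
  if (nrow(sub) == 0) stop("no miRNAs in the requested direction")
  logistic_gsa(gene_scores(sub, targets), sets)
}
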