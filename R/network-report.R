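#' Assemble the miRNA-nutrient association network
#'
#' Builds a bipartite graph over the screen-significant miRNA-nutrient
#' pairs. Node attributes: `kind` (mirna / nc), `nc_class`
#' (lipid-related, micro-element, vitamin-related; `none` for miRNAs)
#' and `degree`. Edge attributes: `average_rho` (colour source),
#' `abs_rho` (width source), `glm_confirmed` (drawn solid when the
#' nutrient term dominated the confirmatory model, dashed otherwise)
#' and `trend`.
#'
#' @param records screen output; only `significant` rows become edges.
#' @param glm_results optional [confirm_glm()] output; pairs with
#'   `nc_dominant = TRUE` are marked `glm_confirmed`.
#' @param classes named character vector mapping every nutrient in the
#'   records to its class (default [nc_classes()]).
#' @return an [igraph::igraph] bipartite graph.
#' @export
build_network <- function(records, glm_results = NULL,
                          classes = nc_classes()) {
  if ("significant" %in% names(records)) {
    records <- records[records$significant, , drop = FALSE]
  }
  ncs <- unique(records$nc_id)
  missing <- setdiff(ncs, names(classes))
  if (length(missing) > 0) {
    stop("NC(s) without an assigned class: ",
         paste(missing, collapse = ", "))
  }
  mirnas <- unique(records$mirna_id)
  nodes <- data.frame(
    name = c(mirnas, ncs),
    kind = rep(c("mirna", "nc"), c(length(mirnas), length(ncs))),
    nc_class = c(rep("none", length(mirnas)),
                 unname(classes[ncs]))
  )
  confirmed <- character(0)
  if (!is.null(glm_results) && nrow(glm_results) > 0) {
    ok <- glm_results$nc_dominant
    confirmed <- paste(glm_results$mirna_id[ok], glm_results$nc_id[ok])
  }
  edges <- data.frame(
    from = records$mirna_id, to = records$nc_id,
    average_rho = records$average_rho,
    abs_rho = abs(records$average_rho),
    glm_confirmed = paste(records$mirna_id, records$nc_id) %in% confirmed,
    trend = if (nrow(records)) records$trend else character(0)
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::V(g)$type <- igraph::V(g)$kind == "nc"
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Write the network as GraphML plus node/edge tables
#'
#' Emits a Cytoscape-loadable GraphML file and paired node/edge TSVs
#' carrying the same attributes.
#'
#' @param g graph from [build_network()].
#' @param path output path prefix; writes `<path>.graphml`,
#'   `<path>_nodes.tsv`, `<path>_edges.tsv`.
#' @return invisibly, the three file paths.
#' @export
write_network <- function(g, path) {
  gml <- paste0(path, ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  nodes <- data.frame(
    id = igraph::V(g)$name, kind = igraph::V(g)$kind,
    nc_class = igraph::V(g)$nc_class, degree = igraph::V(g)$degree
  )
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    mirna_id = el[, 1], nc_id = el[, 2],
    average_rho = igraph::E(g)$average_rho,
    abs_rho = igraph::E(g)$abs_rho,
    glm_confirmed = igraph::E(g)$glm_confirmed,
    trend = igraph::E(g)$trend
  )
  nf <- paste0(path, "_nodes.tsv"); ef <- paste0(path, "_edges.tsv")
  write_tsv(nodes, nf)
  write_tsv(edges, ef)
  invisible(c(graphml = gml, nodes = nf, edges = ef))
}

round1 <- function(x) round(x, 1)

#' Summarize a full pipeline run
#'
#' Collects the funnel counts of every stage into one machine-readable
#' report: pairs tested / coherent / significant, trend tallies with
#' percentages, per-nutrient sign tallies of the significant pairs,
#' confirmatory-model counts, DE and enrichment counts, plus the
#' configuration echo and seed. Stages not supplied are reported as
#' explicit gaps.
#'
#' @param records screen output (required).
#' @param glm_results optional [confirm_glm()] output.
#' @param de optional [de_analysis()] output (or several, rbind-ed).
#' @param enrichment optional [logistic_gsa()] output.
#' @param config optional [screen_config()] echoed into the report.
#' @param seed optional integer seed echoed into the report.
#' @return a list of class `run_report`.
#' @export
summarize_run <- function(records, glm_results = NULL, de = NULL,
                          enrichment = NULL, config = NULL,
                          seed = NULL) {
  sig <- records[records$significant, , drop = FALSE]
  trending <- sum(sig$trend != "none")
  sign_by_nc <- if (nrow(sig) > 0) {
    tab <- table(sig$nc_id, factor(sign(sig$average_rho), c(-1, 1),
                                   c("negative", "positive")))
    df <- as.data.frame.matrix(tab)
    df$nc_id <- rownames(df)
    df$n_pairs <- df$negative + df$positive
    df$pct_positive <- round1(100 * df$positive / df$n_pairs)
    rownames(df) <- NULL
    df[c("nc_id", "n_pairs", "positive", "negative", "pct_positive")]
  } else NULL
  rep <- list(
    screen = list(
      n_tested = nrow(records),
      n_coherent = sum(records$coherent),
      n_significant = nrow(sig),
      n_mirnas_significant = length(unique(sig$mirna_id)),
      n_ncs_significant = length(unique(sig$nc_id)),
      n_trending = trending,
      pct_trending = if (nrow(sig) > 0)
        round1(100 * trending / nrow(sig)) else NA_real_,
      n_trend_increasing = sum(sig$trend == "increasing"),
      n_trend_decreasing = sum(sig$trend == "decreasing"),
      sign_by_nc = sign_by_nc
    ),
    glm = if (is.null(glm_results)) "not run" else {
      s <- attr(glm_results, "summary")
      if (is.null(s)) {
        s <- list(n_fitted = nrow(glm_results),
                  n_model_significant = sum(glm_results$model_significant),
                  n_nc_dominant = sum(glm_results$nc_dominant))
      }
      c(s, list(pct_model_significant = if (s$n_fitted > 0)
        round1(100 * s$n_model_significant / s$n_fitted) else NA_real_))
    },
    de = if (is.null(de)) "not run" else list(
      n_tested = nrow(de),
      n_significant = sum(de$significant, na.rm = TRUE),
      by_nc = as.list(tapply(de$significant, de$nc_id, sum,
                             na.rm = TRUE))
    ),
    enrichment = if (is.null(enrichment)) "not run" else list(
      n_sets_tested = sum(!is.na(enrichment$p)),
      n_retained = sum(enrichment$retained, na.rm = TRUE)
    ),
    config = if (is.null(config)) "not recorded" else unclass(config),
    seed = if (is.null(seed)) "not recorded" else seed,
    r_version = as.character(getRversion())
  )
  structure(rep, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("nutrimir run report\n")
  cat(sprintf("  screen: %d tested, %d coherent, %d significant\n",
              x$screen$n_tested, x$screen$n_coherent,
              x$screen$n_significant))
  if (!identical(x$glm, "not run")) {
    cat(sprintf("  glm: %d fitted, %d model-significant, %d NC-dominant\n",
                x$glm$n_fitted, x$glm$n_model_significant,
                x$glm$n_nc_dominant))
  }
  if (!identical(x$de, "not run")) {
    cat(sprintf("  de: %d tested, %d significant\n",
                x$de$n_tested, x$de$n_significant))
  }
  if (!identical(x$enrichment, "not run")) {
    cat(sprintf("  enrichment: %d sets tested, %d retained\n",
                x$enrichment$n_sets_tested, x$enrichment$n_retained))
  }
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report a `run_report` from [summarize_run()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
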