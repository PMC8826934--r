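#' Pipeline configuration
#'
#' Collects every threshold and setting of the end-to-end analysis in one
#' validated list. All defaults are the study values: a 1.5-fold cut
#' (|log2FC| > 0.585) with q < 0.1 for responder calling, |TPSM| > 0.6 for
#' network edges, normalized-amplitude cuts 1.5/2.5 with a 50% return
#' fraction for cluster labelling, a 5% missing-cell budget, 13 panel
#' clusters and 4 fasting-correlation clusters.
#'
#' @param fc_threshold absolute log2 fold-change cut.
#' @param q_threshold q-value cut.
#' @param tpsm_threshold network edge cut on |TPSM|.
#' @param amplitude_small,amplitude_large cluster amplitude cuts.
#' @param transient_fraction return fraction defining transience.
#' @param missing_top_fraction missing-cell budget fraction.
#' @param k_panel cluster count for the full panel.
#' @param k_fasting cluster count for the fasting-correlation matrix.
#' @param qvalue_lambda Storey tuning parameter.
#' @param qvalue_family `"pooled"` or `"per_molecule"`.
#' @param feature_references molecules whose per-subject features anchor the
#'   correlation screen.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_threshold = 0.585,
                            q_threshold = 0.1,
                            tpsm_threshold = 0.6,
                            amplitude_small = 1.5,
                            amplitude_large = 2.5,
                            transient_fraction = 0.5,
                            missing_top_fraction = 0.05,
                            k_panel = 13,
                            k_fasting = 4,
                            qvalue_lambda = 0.5,
                            qvalue_family = c("pooled", "per_molecule"),
                            feature_references = NULL) {
  qvalue_family <- match.arg(qvalue_family)
  stopifnot(
    fc_threshold >= 0,
    q_threshold > 0, q_threshold <= 1,
    tpsm_threshold >= 0, tpsm_threshold <= 1,
    amplitude_small >= 0, amplitude_large > amplitude_small,
    transient_fraction > 0, transient_fraction <= 1,
    missing_top_fraction >= 0, missing_top_fraction <= 1,
    k_panel >= 1, k_fasting >= 1,
    qvalue_lambda > 0, qvalue_lambda < 1
  )
  structure(
    list(
      fc_threshold = fc_threshold, q_threshold = q_threshold,
      tpsm_threshold = tpsm_threshold,
      amplitude_small = amplitude_small, amplitude_large = amplitude_large,
      transient_fraction = transient_fraction,
      missing_top_fraction = missing_top_fraction,
      k_panel = k_panel, k_fasting = k_fasting,
      qvalue_lambda = qvalue_lambda, qvalue_family = qvalue_family,
      feature_references = feature_references
    ),
    class = "pipeline_config"
  )
}

#' Run the full temporal-pattern analysis
#'
#' Executes the complete chain on a raw dataset: collapse of the duplicated
#' fasting draw, missing-data exclusion, differencing from fasting,
#' dispersion normalization, responder calling, hierarchical clustering and
#' labelling of the normalized mean trajectories, PCA into amplitude and
#' rate components, TPSI/TVRI/TPSM, clustering of the fasting-correlation
#' profile of the responders, the |TPSM| network with components,
#' betweenness and group-normalized degree, and the per-subject AUC /
#' half-AUC-time feature screen.
#'
#' @param ds a raw `timecourse_dataset` (grid may include the -10 min
#'   duplicate fasting draw).
#' @param config a [pipeline_config()].
#' @param skip character vector of stages to skip: any of `"network"`,
#'   `"features"`, `"fasting_correlation"`.
#' @return An object of class `ogtt_pipeline`: list of stage results
#'   (`dataset`, `normalized`, `response`, `clusters`, `pca`, `similarity`,
#'   `tpsm`, `fasting_clusters`, `network`, `features`, `screen`,
#'   `config`) plus `summary`, a plain list suitable for JSON export.
#' @export
run_pipeline <- function(ds, config = pipeline_config(), skip = character()) {
  stopifnot(inherits(ds, "timecourse_dataset"),
            inherits(config, "pipeline_config"))

  filtered <- filter_missing_molecules(ds, config$missing_top_fraction)
  collapsed <- collapse_fasting_duplicates(filtered)
  dd <- suppressWarnings(difference_from_fasting(collapsed))
  nd <- normalize_timecourses(collapsed)

  response <- call_responders(
    collapsed,
    fc_threshold = config$fc_threshold, q_threshold = config$q_threshold,
    family = config$qvalue_family, lambda = config$qvalue_lambda
  )
  responders <- response$responders$molecule[response$responders$responder]

  clusters <- hierarchical_cluster(nd$Ybar,
                                   k = min(config$k_panel, nrow(nd$Ybar)))
  pca <- pca_decompose(nd$Ybar)

  sim <- similarity_indices(collapsed)
  tp <- tpsm(dd)

  fasting_clusters <- NULL
  if (!("fasting_correlation" %in% skip) && length(responders) >= 2) {
    fc_prof <- fasting_correlation_profile(collapsed, molecules = responders)
    complete <- rowSums(is.na(fc_prof)) == 0
    if (sum(complete) >= 2) {
      fasting_clusters <- hierarchical_cluster(
        fc_prof[complete, , drop = FALSE],
        k = min(config$k_fasting, sum(complete))
      )
    }
  }

  network <- NULL
  if (!("network" %in% skip)) {
    network <- network_summary(
      tp$tpsm, annotation = collapsed$annotation,
      threshold = config$tpsm_threshold
    )
  }

  features <- NULL
  screen <- NULL
  if (!("features" %in% skip)) {
    features <- temporal_features(dd)
    refs <- config$feature_references %||% character(0)
    refs <- intersect(refs, collapsed$molecules)
    if (length(refs) > 0) {
      cluster_of <- setNames(clusters$assignment$cluster,
                             clusters$assignment$molecule)
      targets <- intersect(responders, names(cluster_of))
      screen <- feature_correlation_screen(
        features, references = refs, targets = setdiff(targets, refs),
        q_threshold = config$q_threshold, lambda = config$qvalue_lambda
      )
    }
  }

  summary <- pipeline_summary(
    config, filtered, response, clusters, pca, sim, fasting_clusters,
    network, screen
  )

  structure(
    list(
      dataset = collapsed, differenced = dd, normalized = nd,
      response = response, clusters = clusters, pca = pca,
      similarity = sim, tpsm = tp, fasting_clusters = fasting_clusters,
      network = network, features = features, screen = screen,
      config = config, summary = summary
    ),
    class = "ogtt_pipeline"
  )
}

pipeline_summary <- function(config, filtered, response, clusters, pca, sim,
                             fasting_clusters, network, screen) {
  report <- attr(filtered, "exclusion_report")
  resp <- response$responders
  out <- list(
    thresholds = config[!vapply(config, is.null, logical(1))],
    molecules_retained = length(filtered$molecules),
    molecules_excluded_missing = if (is.null(report)) 0L
                                 else sum(report$excluded),
    responders = list(
      n = sum(resp$responder, na.rm = TRUE),
      n_increase = sum(resp$direction == "increase", na.rm = TRUE),
      n_decrease = sum(resp$direction == "decrease", na.rm = TRUE),
      molecules = resp$molecule[which(resp$responder)]
    ),
    clusters = list(
      k = nrow(clusters$labels),
      labels = as.data.frame(clusters$labels)
    ),
    pca = list(
      explained_variance_ratio = unname(pca$explained_variance_ratio),
      pc1_pc2_cumulative = sum(pca$explained_variance_ratio[1:2])
    ),
    similarity = list(
      median_tpsi = stats::median(sim$tpsi, na.rm = TRUE),
      median_tvri = stats::median(sim$tvri, na.rm = TRUE)
    )
  )
  if (!is.null(fasting_clusters)) {
    out$fasting_clusters <- list(k = nrow(fasting_clusters$labels))
  }
  if (!is.null(network)) {
    nodes <- network$nodes
    comp_sizes <- sort(unique(stats::na.omit(
      nodes[c("component", "component_size")]
    ))$component_size, decreasing = TRUE)
    top_b <- nodes$molecule[which.max(nodes$betweenness)]
    out$network <- list(
      n_edges = nrow(network$graph$edges),
      n_components = length(unique(stats::na.omit(nodes$component))),
      component_sizes = comp_sizes,
      largest_component = if (length(comp_sizes)) comp_sizes[1L] else 0L,
      top_betweenness_molecule = if (nrow(network$graph$edges)) top_b
                                 else NA_character_,
      max_betweenness = max(nodes$betweenness)
    )
  }
  if (!is.null(screen) && nrow(screen) > 0) {
    out$feature_screen <- list(
      n_tested = nrow(screen),
      n_significant = sum(screen$significant)
    )
  }
  out
}

#' @export
print.ogtt_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<ogtt_pipeline>\n")
  cat("  molecules retained: ", s$molecules_retained, "\n", sep = "")
  cat("  responders: ", s$responders$n, " (", s$responders$n_increase,
      " increase, ", s$responders$n_decrease, " decrease)\n", sep = "")
  cat("  PC1+PC2 explained variance: ",
      round(100 * s$pca$pc1_pc2_cumulative, 1), "%\n", sep = "")
  if (!is.null(s$network)) {
    cat("  network: ", s$network$n_edges, " edges, ",
        s$network$n_components, " component(s), largest ",
        s$network$largest_component, "\n", sep = "")
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the stage tables as CSV and the run summary as JSON. Re-running on
#' the same inputs overwrites the files with identical content.
#'
#' @param result an `ogtt_pipeline` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "ogtt_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  readr::write_csv(result$response$tests, p("response_tests.csv"), na = "")
  readr::write_csv(result$response$responders, p("responders.csv"), na = "")
  readr::write_csv(as_normalized_tibble(result$normalized),
                   p("normalized.csv"), na = "")
  readr::write_csv(
    dplyr::left_join(result$clusters$assignment,
                     result$clusters$labels, by = "cluster"),
    p("clusters.csv"), na = ""
  )
  scores <- tibble::as_tibble(result$pca$scores, rownames = "molecule")
  readr::write_csv(scores, p("pca_scores.csv"), na = "")
  loadings <- tibble::as_tibble(result$pca$loadings, rownames = "time_min")
  readr::write_csv(loadings, p("pca_loadings.csv"), na = "")
  readr::write_csv(result$similarity, p("similarity_indices.csv"), na = "")
  readr::write_csv(
    tibble::as_tibble(result$tpsm$tpsm, rownames = "molecule"),
    p("tpsm_matrix.csv"), na = ""
  )
  if (!is.null(result$network)) {
    readr::write_csv(result$network$graph$edges, p("network_edges.csv"),
                     na = "")
    readr::write_csv(result$network$nodes, p("network_nodes.csv"), na = "")
  }
  if (!is.null(result$features)) {
    readr::write_csv(result$features, p("temporal_features.csv"), na = "")
  }
  if (!is.null(result$screen)) {
    readr::write_csv(result$screen, p("feature_screen.csv"), na = "")
  }
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
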