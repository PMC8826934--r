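#' Build the thresholded molecule similarity graph
#'
#' Molecules become nodes; an undirected edge joins two molecules when the
#' absolute value of their temporal pattern similarity strictly exceeds the
#' threshold (default 0.6, the conventional cut for a moderately high
#' Pearson correlation). Edges carry the signed similarity and its
#' magnitude; shortest-path computations ignore the magnitudes (unweighted
#' geodesics).
#'
#' @param tpsm_matrix square symmetric molecule x molecule matrix of signed
#'   similarities (`NA` entries never form edges).
#' @param annotation tibble (molecule, metabolic_group) covering every node.
#' @param threshold strict lower bound on the absolute similarity.
#' @return An object of class `molecule_graph`: list with `graph` (igraph
#'   over connected nodes), `edges` (tibble source, target, tpsm, abs_tpsm,
#'   sign), `nodes` (all molecule ids), `isolated` (ids without edges),
#'   `annotation`, `threshold`.
#' @export
build_graph <- function(tpsm_matrix, annotation = NULL, threshold = 0.6) {
  stopifnot(is.matrix(tpsm_matrix), nrow(tpsm_matrix) == ncol(tpsm_matrix))
  if (is.null(rownames(tpsm_matrix))) {
    dimnames(tpsm_matrix) <- list(
      paste0("M", seq_len(nrow(tpsm_matrix))),
      paste0("M", seq_len(nrow(tpsm_matrix)))
    )
  }
  asym <- max(abs(tpsm_matrix - t(tpsm_matrix)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-9) {
    stop("similarity matrix is not symmetric (max asymmetry ", asym, ")")
  }
  nodes <- rownames(tpsm_matrix)
  n <- length(nodes)
  idx <- which(
    upper.tri(tpsm_matrix) & !is.na(tpsm_matrix) &
      abs(tpsm_matrix) > threshold,
    arr.ind = TRUE
  )
  edges <- tibble::tibble(
    source = nodes[idx[, 1L]],
    target = nodes[idx[, 2L]],
    tpsm = tpsm_matrix[idx],
    abs_tpsm = abs(tpsm_matrix[idx]),
    sign = ifelse(tpsm_matrix[idx] >= 0, "positive", "negative")
  )
  connected <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(
    edges[c("source", "target", "tpsm", "abs_tpsm")],
    directed = FALSE,
    vertices = data.frame(name = connected)
  )
  structure(
    list(
      graph = g,
      edges = edges,
      nodes = nodes,
      isolated = setdiff(nodes, connected),
      annotation = annotation,
      threshold = threshold
    ),
    class = "molecule_graph"
  )
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(
    "<molecule_graph> ", length(x$nodes), " molecules, ", nrow(x$edges),
    " edge(s) at |TPSM| > ", x$threshold, "; ",
    length(x$isolated), " isolated\n",
    sep = ""
  )
  invisible(x)
}

#' Connected components of the molecule graph
#'
#' Components are computed over the nodes that have at least one edge;
#' isolated molecules are reported with component `NA`. Component ids are
#' numbered by decreasing size (ties broken by first molecule id).
#'
#' @param mg a `molecule_graph`.
#' @return Tibble (molecule, component, component_size), one row per node
#'   of the full molecule panel.
#' @export
connected_components <- function(mg) {
  stopifnot(inherits(mg, "molecule_graph"))
  if (nrow(mg$edges) == 0) {
    return(tibble::tibble(
      molecule = mg$nodes, component = NA_integer_,
      component_size = NA_integer_
    ))
  }
  comp <- igraph::components(mg$graph)
  members <- split(names(comp$membership), comp$membership)
  ord <- order(-lengths(members),
               vapply(members, function(m) sort(m)[1L], character(1)))
  remap <- match(seq_along(members), ord)
  out <- tibble::tibble(
    molecule = mg$nodes,
    component = NA_integer_,
    component_size = NA_integer_
  )
  i <- match(names(comp$membership), out$molecule)
  out$component[i] <- remap[comp$membership]
  out$component_size[i] <- comp$csize[comp$membership]
  out
}

#' Betweenness centrality of the molecule graph
#'
#' Brandes' algorithm over unweighted geodesics, normalized by
#' 2 / ((n - 1)(n - 2)) where n is by default the number of connected nodes
#' of the whole graph (per-component normalization available). Isolated
#' molecules have centrality 0.
#'
#' @param mg a `molecule_graph`.
#' @param per_component normalize within each component instead of over the
#'   whole graph.
#' @return Tibble (molecule, betweenness), one row per molecule of the
#'   panel.
#' @export
betweenness_centrality <- function(mg, per_component = FALSE) {
  stopifnot(inherits(mg, "molecule_graph"))
  out <- tibble::tibble(molecule = mg$nodes, betweenness = 0)
  if (nrow(mg$edges) == 0) {
    return(out)
  }
  raw <- igraph::betweenness(mg$graph, directed = FALSE, weights = NA,
                             normalized = FALSE)
  if (per_component) {
    comp <- igraph::components(mg$graph)
    n_c <- comp$csize[comp$membership]
    denom <- (n_c - 1) * (n_c - 2) / 2
    bc <- ifelse(denom > 0, raw / denom, 0)
  } else {
    n <- igraph::vcount(mg$graph)
    bc <- if (n < 3) raw * 0 else raw / ((n - 1) * (n - 2) / 2)
  }
  i <- match(names(raw), out$molecule)
  out$betweenness[i] <- unname(bc)
  out
}

#' Group-normalized degree
#'
#' A molecule's degree in the thresholded graph divided by the number of
#' molecules of its own metabolic group in the analysed panel. This puts
#' the connectivity of molecules from groups of very different sizes on a
#' common scale; isolated molecules score 0.
#'
#' @param mg a `molecule_graph`; its `annotation` (or the `annotation`
#'   argument) must cover every node.
#' @param annotation optional tibble (molecule, metabolic_group) overriding
#'   the one stored in the graph.
#' @return Tibble (molecule, metabolic_group, degree, group_size,
#'   deg_normalized).
#' @export
degree_normalized <- function(mg, annotation = NULL) {
  stopifnot(inherits(mg, "molecule_graph"))
  annotation <- annotation %||% mg$annotation
  if (is.null(annotation)) stop("molecule annotation required")
  annotation <- tibble::as_tibble(annotation)
  unknown <- setdiff(mg$nodes, annotation$molecule)
  if (length(unknown) > 0) {
    stop("node(s) without group annotation: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  deg <- setNames(rep(0L, length(mg$nodes)), mg$nodes)
  if (nrow(mg$edges) > 0) {
    d <- igraph::degree(mg$graph)
    deg[names(d)] <- d
  }
  group <- annotation$metabolic_group[match(mg$nodes, annotation$molecule)]
  group_size <- table(group)[group]
  tibble::tibble(
    molecule = mg$nodes,
    metabolic_group = group,
    degree = as.integer(deg),
    group_size = as.integer(group_size),
    deg_normalized = as.numeric(deg) / as.integer(group_size)
  )
}

#' Full network summary of a similarity matrix
#'
#' Runs [build_graph()], [connected_components()],
#' [betweenness_centrality()] and [degree_normalized()] and returns one
#' node table.
#'
#' @param tpsm_matrix signed similarity matrix.
#' @param annotation tibble (molecule, metabolic_group).
#' @param threshold edge threshold on the absolute similarity.
#' @return List with `graph` (the `molecule_graph`) and `nodes` (tibble
#'   molecule, metabolic_group, component, component_size, degree,
#'   deg_normalized, betweenness).
#' @export
network_summary <- function(tpsm_matrix, annotation, threshold = 0.6) {
  mg <- build_graph(tpsm_matrix, annotation = annotation,
                    threshold = threshold)
  nodes <- connected_components(mg)
  nodes <- dplyr::left_join(nodes, betweenness_centrality(mg),
                            by = "molecule")
  nodes <- dplyr::left_join(
    nodes,
    degree_normalized(mg)[c("molecule", "metabolic_group", "degree",
                            "group_size", "deg_normalized")],
    by = "molecule"
  )
  list(graph = mg, nodes = nodes)
}
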