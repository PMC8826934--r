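#' Hierarchical clustering of mean normalized trajectories
#'
#' Agglomerative clustering of the molecule x time matrix of normalized mean
#' trajectories, using Euclidean distance and Ward's criterion in the
#' `ward.D2` convention (input distances are not pre-squared). The tree is
#' cut to `k` clusters and cluster ids are renumbered in dendrogram
#' traversal order, so cluster 1 is the leftmost group of the tree. Each
#' cluster's mean trajectory is labelled by amplitude, kinetics and
#' direction via [label_trajectory()].
#'
#' @param M numeric matrix, molecules in rows (named), time points in
#'   columns; no missing entries. Rows with any `NA` are dropped with a
#'   warning.
#' @param k number of clusters (<= number of molecules).
#' @return An object of class `cluster_result`: list with `hclust` (the
#'   merge tree), `assignment` (tibble molecule, cluster), `labels` (tibble
#'   cluster, amplitude, kinetics, direction, n), and `means` (cluster x
#'   time matrix).
#' @export
hierarchical_cluster <- function(M, k) {
  stopifnot(is.matrix(M), !is.null(rownames(M)))
  drop <- rowSums(is.na(M)) > 0
  if (any(drop)) {
    warning(
      sum(drop), " molecule(s) with incomplete trajectories dropped: ",
      paste(head(rownames(M)[drop], 5), collapse = ", ")
    )
    M <- M[!drop, , drop = FALSE]
  }
  if (k > nrow(M)) stop("k exceeds the number of molecules")
  hc <- hclust(dist(M), method = "ward.D2")
  raw <- cutree(hc, k = k)
  # renumber clusters by order of first appearance along the dendrogram
  first_seen <- unique(raw[hc$order])
  cluster <- match(raw, first_seen)
  names(cluster) <- names(raw)

  means <- do.call(rbind, lapply(seq_len(k), function(cl) {
    colMeans(M[cluster == cl, , drop = FALSE])
  }))
  rownames(means) <- as.character(seq_len(k))

  labels <- dplyr::bind_rows(lapply(seq_len(k), function(cl) {
    lab <- label_trajectory(means[cl, ])
    tibble::tibble(
      cluster = cl, amplitude = lab["amplitude"], kinetics = lab["kinetics"],
      direction = lab["direction"], n = sum(cluster == cl)
    )
  }))

  structure(
    list(
      hclust = hc,
      assignment = tibble::tibble(
        molecule = rownames(M), cluster = unname(cluster)
      ),
      labels = labels,
      means = means
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$assignment), " molecules in ",
      nrow(x$labels), " clusters\n", sep = "")
  print(x$labels)
  invisible(x)
}

#' Label a normalized trajectory by amplitude, kinetics and direction
#'
#' Amplitude is judged from the maximum absolute normalized value: `large`
#' above 2.5, `small` between 1.5 and 2.5, `not_clear` below 1.5. Kinetics
#' is `transient` when, after the global extremum, the absolute value falls
#' to at most 50% of the extremum at some later grid point, and `sustained`
#' otherwise; when the amplitude is `not_clear` the kinetics is also
#' reported `not_clear`. Direction is the sign of the global extremum
#' (`mixed` for an identically-zero trajectory).
#'
#' @param y numeric trajectory on the full grid (normalized units).
#' @param large,small amplitude thresholds.
#' @param transient_fraction return fraction defining transience.
#' @return Named character vector (amplitude, kinetics, direction).
#' @export
label_trajectory <- function(y, large = 2.5, small = 1.5,
                             transient_fraction = 0.5) {
  stopifnot(!anyNA(y))
  peak <- max(abs(y))
  i_peak <- which.max(abs(y))
  amplitude <- if (peak > large) {
    "large"
  } else if (peak >= small) {
    "small"
  } else {
    "not_clear"
  }
  direction <- if (peak == 0) {
    "mixed"
  } else if (y[i_peak] > 0) {
    "increase"
  } else {
    "decrease"
  }
  kinetics <- if (amplitude == "not_clear") {
    "not_clear"
  } else {
    after <- y[seq_along(y) > i_peak]
    if (length(after) > 0 && any(abs(after) <= transient_fraction * peak)) {
      "transient"
    } else {
      "sustained"
    }
  }
  c(amplitude = amplitude, kinetics = kinetics, direction = direction)
}

#' Principal-component decomposition of mean trajectories
#'
#' Columns (time points) are mean-centred across molecules -- no variance
#' scaling -- and decomposed by SVD. Scores are the projections of the
#' molecules; the factor loading of a component at a time point is the
#' Pearson correlation between that component's scores and the column of
#' values at that time point, so loadings live on the \[-1, 1\] correlation
#' scale. With column centring, a molecule with no excursion sits at the
#' origin of the score space.
#'
#' Sign convention: the first component is oriented so its loading at the
#' time point nearest 90 min is positive (it then reads as the overall
#' amplitude-and-direction axis), and the second so its loading at the
#' earliest post-ingestion time point is positive (it then reads as the
#' rate axis, positive loadings early and negative late).
#'
#' @param M numeric matrix of normalized mean trajectories, molecules in
#'   rows, time points in columns (column names in minutes); no `NA`s.
#' @return An object of class `pca_result`: list with `scores` (molecule x
#'   PC matrix), `loadings` (time x PC matrix of correlations),
#'   `explained_variance_ratio`, `center` and `times`.
#' @export
pca_decompose <- function(M) {
  stopifnot(is.matrix(M), nrow(M) >= 2, ncol(M) >= 2, !anyNA(M))
  times <- as.numeric(colnames(M))
  if (anyNA(times)) stop("column names of M must be numeric minutes")
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  scores <- pc$x
  evr <- pc$sdev^2 / sum(pc$sdev^2)

  # orient components: PC1 positive near 90 min, PC2 positive at first
  # post-ingestion point
  flip_to_positive <- function(a, t_ref) {
    ti <- which.min(abs(times - t_ref))
    col_t <- M[, ti]
    if (sd(col_t) == 0) return(invisible(NULL))
    r <- suppressWarnings(cor(scores[, a], col_t))
    if (!is.na(r) && r < 0) scores[, a] <<- -scores[, a]
    invisible(NULL)
  }
  if (ncol(scores) >= 1) flip_to_positive(1L, 90)
  if (ncol(scores) >= 2) flip_to_positive(2L, min(times[times > 0]))

  loadings <- vapply(seq_len(ncol(scores)), function(a) {
    vapply(seq_len(ncol(M)), function(ti) {
      if (sd(M[, ti]) == 0 || sd(scores[, a]) == 0) NA_real_
      else cor(scores[, a], M[, ti])
    }, numeric(1))
  }, numeric(ncol(M)))
  dimnames(loadings) <- list(colnames(M), colnames(scores))

  structure(
    list(
      scores = scores,
      loadings = loadings,
      explained_variance_ratio = evr,
      center = pc$center,
      times = times
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  evr <- round(100 * x$explained_variance_ratio[1:min(3, length(
    x$explained_variance_ratio))], 1)
  cat("<pca_result> ", nrow(x$scores), " molecules x ", length(x$times),
      " time points; explained variance ",
      paste0(paste0("PC", seq_along(evr), " ", evr, "%"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
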