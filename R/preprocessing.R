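#' Exclude molecules with too many missing cells
#'
#' A molecule is removed when its missing-cell count strictly exceeds
#' `floor(n_subjects * n_times * top_fraction)`, i.e. the worst `top_fraction`
#' of the per-molecule cell budget. With the study layout of 20 subjects and
#' 14 raw time points (double fasting draw included) and the default 5%
#' fraction, the threshold is 14 cells. The comparison is strict, so a
#' molecule sitting exactly at the threshold is retained.
#'
#' @param ds a `timecourse_dataset`, normally on the raw (pre-collapse) grid
#'   so the cell budget matches the sampling protocol.
#' @param top_fraction allowed missing fraction, in \[0, 1\].
#' @return The filtered `timecourse_dataset`, with attribute
#'   `"exclusion_report"`: a tibble (molecule, n_missing, excluded) also
#'   carrying the integer threshold as attribute `"threshold"`.
#' @export
filter_missing_molecules <- function(ds, top_fraction = 0.05) {
  if (top_fraction < 0 || top_fraction > 1) {
    stop("top_fraction must lie in [0, 1]")
  }
  n_cells <- n_subjects(ds) * n_times(ds)
  threshold <- floor(n_cells * top_fraction)
  n_missing <- apply(ds$x, 2L, function(m) sum(is.na(m)))
  excluded <- n_missing > threshold
  report <- tibble::tibble(
    molecule = ds$molecules,
    n_missing = as.integer(n_missing),
    excluded = unname(excluded)
  )
  attr(report, "threshold") <- threshold

  keep <- ds$molecules[!excluded]
  out <- timecourse_dataset(
    ds$x[, keep, , drop = FALSE],
    annotation = ds$annotation[ds$annotation$molecule %in% keep, ],
    demographics = ds$demographics
  )
  attr(out, "exclusion_report") <- report
  attr(out, "ground_truth") <- attr(ds, "ground_truth")
  out
}

#' Normalize time courses by the time-averaged inter-individual dispersion
#'
#' For each molecule the cross-subject mean and standard deviation are
#' computed at every time point; the s.d. uses the population denominator
#' (the number of individuals, not n - 1). The per-molecule scale is the
#' time-mean of those standard deviations, and each subject's trajectory is
#' expressed as its difference from fasting divided by that scale:
#' \deqn{Y_{j,k,t} = (x_{j,k,t} - x_{j,k,0}) / \bar S_k}
#' The cross-subject mean of Y is the normalized mean trajectory used for
#' clustering and PCA. By construction the mean trajectory is exactly 0 at
#' t = 0, and Y is invariant to rescaling a molecule's measurement unit.
#'
#' Missing cells are handled complete-case per time point; a time point with
#' fewer than 2 available subjects contributes no dispersion estimate and is
#' skipped in the time average.
#'
#' @param ds a `timecourse_dataset` whose grid contains t = 0.
#' @return An object of class `normalized_dataset`: list with `Y` (array
#'   subject x molecule x time), `Ybar` (matrix molecule x time), `Sbar`
#'   (named vector, original units), `times`, `subjects`, `molecules`,
#'   `annotation` and `excluded` (tibble molecule, reason).
#' @export
normalize_timecourses <- function(ds) {
  if (!(0 %in% ds$times)) stop("dataset grid must contain t = 0")
  n_s <- n_subjects(ds)
  n_t <- n_times(ds)
  i0 <- which(ds$times == 0)

  Sbar <- setNames(numeric(n_molecules(ds)), ds$molecules)
  Y <- array(NA_real_, dim = dim(ds$x), dimnames = dimnames(ds$x))
  excluded <- character(0)
  reason <- character(0)

  for (k in seq_len(n_molecules(ds))) {
    m <- matrix(ds$x[, k, ], nrow = n_s)  # subjects x times
    # population-denominator s.d. across available subjects per time point
    S_t <- apply(m, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NA_real_)
      sqrt(sum((v - mean(v))^2) / length(v))
    })
    if (all(is.na(S_t))) {
      excluded <- c(excluded, ds$molecules[k])
      reason <- c(reason, "insufficient data")
      next
    }
    sbar_k <- mean(S_t, na.rm = TRUE)
    if (sbar_k == 0) {
      excluded <- c(excluded, ds$molecules[k])
      reason <- c(reason, "zero dispersion")
      next
    }
    Sbar[k] <- sbar_k
    Y[, k, ] <- (m - m[, i0]) / sbar_k
  }

  keep <- setdiff(ds$molecules, excluded)
  Y <- Y[, keep, , drop = FALSE]
  Ybar <- apply(Y, c(2L, 3L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  dimnames(Ybar) <- list(keep, as.character(ds$times))

  structure(
    list(
      Y = Y,
      Ybar = Ybar,
      Sbar = Sbar[keep],
      times = ds$times,
      subjects = ds$subjects,
      molecules = keep,
      annotation = ds$annotation[match(keep, ds$annotation$molecule), ],
      excluded = tibble::tibble(molecule = excluded, reason = reason)
    ),
    class = "normalized_dataset"
  )
}

#' @export
print.normalized_dataset <- function(x, ...) {
  cat(
    "<normalized_dataset> ", length(x$molecules), " molecules x ",
    length(x$times), " time points (", length(x$subjects), " subjects); ",
    nrow(x$excluded), " excluded\n",
    sep = ""
  )
  invisible(x)
}

#' Long-format view of normalized trajectories
#'
#' @param nd a `normalized_dataset`.
#' @return Tibble (subject_id, molecule, time_min, Y).
#' @export
as_normalized_tibble <- function(nd) {
  grid <- expand.grid(
    subject_id = nd$subjects,
    molecule = nd$molecules,
    time_min = nd$times,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  grid$Y <- as.vector(nd$Y)
  tibble::as_tibble(grid)
}
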