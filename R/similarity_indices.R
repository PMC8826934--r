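#' Temporal variation of the relationships among individuals (TVRI)
#'
#' At each time point the subjects' concentrations are z-scored across
#' subjects (sample s.d., denominator n - 1). A subject whose z-score is
#' constant over time keeps the same position relative to the cohort
#' throughout; the s.d. of each subject's z-profile over time (denominator
#' n_time - 1) measures how much that position moves. TVRI is 1 minus the
#' mean of those per-subject standard deviations: 1 means the rank/position
#' structure among individuals is perfectly stable over time, and lower
#' values mean it reshuffles.
#'
#' Molecules with any missing cell are skipped (the index needs the full
#' subject x time block), as is any molecule with zero cross-subject
#' variance at some time point (the z-score is undefined there).
#'
#' @param ds a `timecourse_dataset`.
#' @return Tibble (molecule, tvri, skipped_reason); `tvri` is `NA` where
#'   skipped.
#' @export
tvri <- function(ds) {
  stopifnot(n_subjects(ds) >= 2)
  res <- lapply(ds$molecules, function(mol) {
    m <- molecule_matrix(ds, mol)
    if (anyNA(m)) {
      return(tibble::tibble(molecule = mol, tvri = NA_real_,
                            skipped_reason = "missing data"))
    }
    S_t <- apply(m, 2L, sd)
    if (any(S_t == 0)) {
      return(tibble::tibble(molecule = mol, tvri = NA_real_,
                            skipped_reason = "zero cross-subject variance"))
    }
    z <- scale(m)  # column-wise (mean 0, sd with n - 1 denominator)
    S_z <- apply(z, 1L, sd)  # per subject, over time, denominator n_t - 1
    tibble::tibble(molecule = mol, tvri = 1 - mean(S_z),
                   skipped_reason = NA_character_)
  })
  dplyr::bind_rows(res)
}

# concatenated subject-pair vectors for one molecule's x' matrix
# (subjects x times); returns list(X, Y, n_pairs)
pair_concatenation <- function(m) {
  n_s <- nrow(m)
  pairs <- utils::combn(n_s, 2)
  X <- vector("list", ncol(pairs))
  Y <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    X[[p]] <- m[i, ok]
    Y[[p]] <- m[j, ok]
  }
  list(X = unlist(X), Y = unlist(Y), n_pairs = ncol(pairs))
}

#' Temporal pattern similarity among individuals (TPSI)
#'
#' For each molecule, all unordered subject pairs (i < j in input order) are
#' enumerated; for every pair the two difference-from-fasting trajectories
#' are appended to a pair of long vectors, and TPSI is the single Pearson
#' correlation over the whole concatenation. With 20 subjects the
#' concatenation spans choose(20, 2) = 190 pairs. The t = 0 entries
#' (identically 0) are part of the trajectories and are included. A pair
#' contributes only the time points at which both subjects are non-missing.
#'
#' @param dd a `differenced_dataset` (see [difference_from_fasting()]).
#' @return Tibble (molecule, tpsi, n_pairs); `tpsi` is `NA` when the
#'   concatenated vectors have zero variance or the molecule was flagged
#'   for an unusable fasting draw.
#' @export
tpsi <- function(dd) {
  stopifnot(inherits(dd, "differenced_dataset"), length(dd$subjects) >= 2)
  res <- lapply(dd$molecules, function(mol) {
    if (mol %in% dd$flagged) {
      return(tibble::tibble(molecule = mol, tpsi = NA_real_,
                            n_pairs = NA_integer_))
    }
    m <- molecule_matrix(dd, mol)
    pc <- pair_concatenation(m)
    val <- if (length(pc$X) < 2 || sd(pc$X) == 0 || sd(pc$Y) == 0) {
      NA_real_
    } else {
      cor(pc$X, pc$Y)
    }
    tibble::tibble(molecule = mol, tpsi = val,
                   n_pairs = as.integer(pc$n_pairs))
  })
  dplyr::bind_rows(res)
}

#' Temporal pattern similarity among molecules (TPSM)
#'
#' Each molecule's difference-from-fasting trajectories are concatenated
#' over subjects in fixed input order into one long vector; TPSM of a
#' molecule pair is the Pearson correlation of the two concatenations
#' (positions where either molecule is missing are dropped pairwise), and
#' TPSM_Abs is its absolute value. Positive TPSM means in-phase temporal
#' patterns, negative means anti-phase.
#'
#' @param dd a `differenced_dataset`.
#' @return List with `tpsm` (symmetric molecule x molecule matrix, unit
#'   diagonal) and `tpsm_abs`. Rows/columns of zero-variance or flagged
#'   molecules are `NA` (diagonal included).
#' @export
tpsm <- function(dd) {
  stopifnot(inherits(dd, "differenced_dataset"), length(dd$molecules) >= 2)
  n_m <- length(dd$molecules)
  # subject-concatenated x' vectors as columns
  V <- vapply(dd$molecules, function(mol) {
    as.vector(t(molecule_matrix(dd, mol)))  # subject-major concatenation
  }, numeric(length(dd$subjects) * length(dd$times)))
  usable <- vapply(seq_len(n_m), function(k) {
    v <- V[, k]
    !(dd$molecules[k] %in% dd$flagged) &&
      sum(!is.na(v)) >= 2 && sd(v, na.rm = TRUE) > 0
  }, logical(1))
  M <- suppressWarnings(cor(V, use = "pairwise.complete.obs"))
  M[!usable, ] <- NA_real_
  M[, !usable] <- NA_real_
  diag(M)[usable] <- 1
  dimnames(M) <- list(dd$molecules, dd$molecules)
  list(tpsm = M, tpsm_abs = abs(M))
}

#' Fasting-versus-time correlation profile
#'
#' For each molecule and each time point, the Pearson correlation across
#' subjects between the fasting values and the values at that time point.
#' A molecule whose high-fasting subjects remain high throughout keeps
#' r near 1 at all times; r decaying with time means the fasting order is
#' lost. The resulting molecule x time matrix is typically clustered
#' (Euclidean/Ward, 4 clusters) to group molecules by how long they
#' remember their fasting state.
#'
#' @param ds a `timecourse_dataset` whose grid contains t = 0.
#' @param molecules optional subset of molecule ids (e.g. the responders).
#' @param min_pairs minimum complete subject pairs per correlation.
#' @return Matrix molecule x time of correlations; the t = 0 column is 1
#'   wherever the fasting variance is non-zero; rows with zero fasting
#'   variance are `NA`.
#' @export
fasting_correlation_profile <- function(ds, molecules = NULL, min_pairs = 3) {
  if (!(0 %in% ds$times)) stop("dataset grid must contain t = 0")
  molecules <- molecules %||% ds$molecules
  stopifnot(all(molecules %in% ds$molecules))
  i0 <- which(ds$times == 0)
  out <- matrix(
    NA_real_, nrow = length(molecules), ncol = n_times(ds),
    dimnames = list(molecules, as.character(ds$times))
  )
  for (mol in molecules) {
    m <- molecule_matrix(ds, mol)
    x0 <- m[, i0]
    if (sd(x0, na.rm = TRUE) == 0 || all(is.na(x0))) next
    for (ti in seq_len(n_times(ds))) {
      xt <- m[, ti]
      ok <- !is.na(x0) & !is.na(xt)
      if (sum(ok) < min_pairs || sd(xt[ok]) == 0) next
      out[mol, ti] <- cor(x0[ok], xt[ok])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-molecule similarity summary
#'
#' Convenience wrapper computing TPSI and TVRI on the same dataset and
#' joining them with the molecule annotation.
#'
#' @param ds a `timecourse_dataset` with t = 0 on the grid.
#' @return Tibble (molecule, metabolic_group, tpsi, tvri).
#' @export
similarity_indices <- function(ds) {
  dd <- difference_from_fasting(ds)
  out <- dplyr::left_join(
    tpsi(dd)[c("molecule", "tpsi")],
    tvri(ds)[c("molecule", "tvri")],
    by = "molecule"
  )
  dplyr::left_join(
    out, ds$annotation[c("molecule", "metabolic_group")], by = "molecule"
  )
}
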