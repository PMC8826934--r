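#' Multi-subject molecule time-course dataset
#'
#' The central container of the package: concentrations of one or more blood
#' molecules measured in several subjects on a shared time grid (minutes
#' relative to ingestion). Internally the values are held as a 3-dimensional
#' array `x[subject, molecule, time]` with `NA` marking missing cells, plus a
#' molecule annotation table assigning each molecule to a metabolic group.
#'
#' @param x numeric 3-d array with dimensions subject x molecule x time and
#'   complete dimnames; the third dimension's names must parse as numeric
#'   minutes.
#' @param annotation tibble with columns `molecule` and `metabolic_group`
#'   (optionally `display_name`). Molecules not listed are assigned group
#'   `"other"` with a warning.
#' @param demographics optional tibble with a `subject_id` column.
#'
#' @return An object of class `timecourse_dataset`: a list with elements
#'   `x` (the array), `annotation`, `demographics`, `subjects`, `molecules`
#'   and `times` (integer minutes, strictly increasing).
#' @export
timecourse_dataset <- function(x, annotation = NULL, demographics = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  dn <- dimnames(x)
  if (is.null(dn)) dn <- vector("list", 3L)
  for (i in 1:3) {
    if (is.null(dn[[i]])) {
      if (dim(x)[i] == 0L) {
        dn[[i]] <- character(0)   # empty subsets lose their dimnames
      } else {
        stop("`x` must carry complete dimnames (subject, molecule, time)")
      }
    }
  }
  dimnames(x) <- dn
  times <- suppressWarnings(as.numeric(dn[[3L]]))
  if (anyNA(times)) stop("time dimnames must be numeric minutes")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("time grid must be strictly increasing")
  }
  if (any(times < -10)) stop("time grid values must be >= -10 minutes")
  subjects <- dn[[1L]]
  molecules <- dn[[2L]]
  if (anyDuplicated(subjects)) stop("duplicate subject ids")
  if (anyDuplicated(molecules)) stop("duplicate molecule ids")

  annotation <- complete_annotation(annotation, molecules)
  if (!is.null(demographics)) {
    demographics <- tibble::as_tibble(demographics)
    stopifnot("subject_id" %in% names(demographics))
  }

  structure(
    list(
      x = x,
      annotation = annotation,
      demographics = demographics,
      subjects = subjects,
      molecules = molecules,
      times = times
    ),
    class = "timecourse_dataset"
  )
}

complete_annotation <- function(annotation, molecules) {
  supplied <- !is.null(annotation)
  if (!supplied) {
    annotation <- tibble::tibble(
      molecule = character(), metabolic_group = character()
    )
  }
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("molecule", "metabolic_group") %in% names(annotation)))
  if (anyDuplicated(annotation$molecule)) {
    stop("duplicate molecule ids in annotation table")
  }
  bad <- setdiff(unique(annotation$metabolic_group), METABOLIC_GROUPS)
  if (length(bad) > 0) {
    stop("unknown metabolic group label(s): ", paste(bad, collapse = ", "))
  }
  if (!"display_name" %in% names(annotation)) {
    annotation$display_name <- annotation$molecule
  }
  missing_ann <- setdiff(molecules, annotation$molecule)
  if (length(missing_ann) > 0) {
    if (supplied) {
      warning(
        length(missing_ann), " molecule(s) missing from annotation table; ",
        "assigned group \"other\": ",
        paste(head(missing_ann, 5), collapse = ", ")
      )
    }
    annotation <- dplyr::bind_rows(
      annotation,
      tibble::tibble(
        molecule = missing_ann,
        metabolic_group = "other",
        display_name = missing_ann
      )
    )
  }
  annotation[match(molecules, annotation$molecule), , drop = FALSE]
}

#' @export
print.timecourse_dataset <- function(x, ...) {
  cat(
    "<timecourse_dataset> ", length(x$subjects), " subjects x ",
    length(x$molecules), " molecules x ", length(x$times),
    " time points (", min(x$times), "..", max(x$times), " min); ",
    sum(is.na(x$x)), " missing cell(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Number of subjects / molecules / time points of a dataset
#'
#' @param ds a `timecourse_dataset`.
#' @return An integer count.
#' @export
n_subjects <- function(ds) length(ds$subjects)

#' @rdname n_subjects
#' @export
n_molecules <- function(ds) length(ds$molecules)

#' @rdname n_subjects
#' @export
n_times <- function(ds) length(ds$times)

#' Read a tidy time-course CSV into a dataset
#'
#' The canonical interchange format is long/tidy: one measurement per row
#' with columns `subject_id`, `molecule`, `time_min`, `concentration`.
#' Empty concentration cells denote missing values; no numeric sentinel is
#' recognised. The time grid is inferred from the distinct `time_min`
#' values; cells absent from the file are marked missing.
#'
#' @param path path to the time-course CSV.
#' @param annotation_path optional path to an annotation CSV with columns
#'   `molecule`, `metabolic_group`.
#' @param demographics_path optional path to a demographics CSV with a
#'   `subject_id` column.
#' @return A [timecourse_dataset()].
#' @export
read_timecourse_csv <- function(path, annotation_path = NULL,
                                demographics_path = NULL) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      molecule = readr::col_character(),
      time_min = readr::col_double(),
      concentration = readr::col_character()
    ),
    progress = FALSE
  )
  stopifnot(all(
    c("subject_id", "molecule", "time_min", "concentration") %in% names(raw)
  ))
  dup <- duplicated(raw[c("subject_id", "molecule", "time_min")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(
      "duplicate (subject, molecule, time) row: (",
      raw$subject_id[i], ", ", raw$molecule[i], ", ", raw$time_min[i], ")"
    )
  }
  conc <- trimws(raw$concentration)
  conc[conc == ""] <- NA_character_
  val <- suppressWarnings(as.numeric(conc))
  bad <- which(!is.na(conc) & is.na(val))
  if (length(bad) > 0) {
    stop(
      "non-numeric concentration \"", conc[bad[1L]], "\" at data row ",
      bad[1L]
    )
  }

  subjects <- unique(raw$subject_id)
  molecules <- unique(raw$molecule)
  times <- sort(unique(raw$time_min))
  x <- array(
    NA_real_,
    dim = c(length(subjects), length(molecules), length(times)),
    dimnames = list(subjects, molecules, as.character(times))
  )
  x[cbind(
    match(raw$subject_id, subjects),
    match(raw$molecule, molecules),
    match(raw$time_min, times)
  )] <- val

  annotation <- if (!is.null(annotation_path)) {
    readr::read_csv(
      annotation_path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  demographics <- if (!is.null(demographics_path)) {
    readr::read_csv(demographics_path, show_col_types = FALSE, progress = FALSE)
  }
  timecourse_dataset(x, annotation = annotation, demographics = demographics)
}

#' Write a dataset back to the tidy CSV dialect
#'
#' Missing cells are written as empty fields so that a read/write round trip
#' preserves values and missingness exactly.
#'
#' @param ds a `timecourse_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(ds, path) {
  long <- as_timecourse_tibble(ds)
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' Long-format view of a dataset
#'
#' @param ds a `timecourse_dataset`.
#' @return Tibble with columns `subject_id`, `molecule`, `time_min`,
#'   `concentration`; one row per cell, missing cells carried as `NA`.
#' @export
as_timecourse_tibble <- function(ds) {
  grid <- expand.grid(
    subject_id = ds$subjects,
    molecule = ds$molecules,
    time_min = ds$times,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  grid$concentration <- as.vector(ds$x)
  dplyr::arrange(tibble::as_tibble(grid), .data$subject_id, .data$molecule,
                 .data$time_min)
}

#' Collapse the duplicated pre-ingestion draws
#'
#' Study protocols often draw the fasting sample twice before ingestion; the
#' two draws are coded as t = -10 and t = 0 min. This operation replaces the
#' t = 0 value by the mean of the two draws wherever both are present, keeps
#' the single available draw otherwise, and drops the -10 column so the grid
#' starts at 0.
#'
#' @param ds a `timecourse_dataset` whose grid may contain t = -10.
#' @return A `timecourse_dataset` with grid starting at 0.
#' @export
collapse_fasting_duplicates <- function(ds) {
  if (!(-10 %in% ds$times)) {
    return(ds)
  }
  if (!(0 %in% ds$times)) {
    stop("dataset has a t = -10 draw but no t = 0 column to collapse into")
  }
  i_pre <- which(ds$times == -10)
  i_0 <- which(ds$times == 0)
  pre <- ds$x[, , i_pre, drop = FALSE]
  at0 <- ds$x[, , i_0, drop = FALSE]
  both <- !is.na(pre) & !is.na(at0)
  only_pre <- !is.na(pre) & is.na(at0)
  merged <- at0
  merged[both] <- (pre[both] + at0[both]) / 2
  merged[only_pre] <- pre[only_pre]
  x <- ds$x[, , -i_pre, drop = FALSE]
  x[, , which(ds$times[-i_pre] == 0)] <- merged[, , 1L]
  timecourse_dataset(x, annotation = ds$annotation,
                     demographics = ds$demographics)
}

#' Difference-from-fasting trajectories
#'
#' Computes x'(j, k, t) = x(j, k, t) - x(j, k, 0), the concentration change
#' relative to the fasting draw, for every subject and molecule. Missingness
#' propagates: x' is missing whenever either operand is. Molecules whose
#' fasting value is missing for every subject are flagged; their x' is all
#' missing and downstream difference-based indices skip them.
#'
#' @param ds a `timecourse_dataset` whose grid contains t = 0.
#' @return An object of class `differenced_dataset`: list with `xprime`
#'   (array, same shape as `ds$x`), `annotation`, `subjects`, `molecules`,
#'   `times`, and `flagged` (molecules with no usable fasting value).
#' @export
difference_from_fasting <- function(ds) {
  if (!(0 %in% ds$times)) stop("dataset grid must contain t = 0")
  i0 <- which(ds$times == 0)
  x0 <- ds$x[, , i0]
  if (length(ds$subjects) == 1L || length(ds$molecules) == 1L) {
    x0 <- matrix(ds$x[, , i0], nrow = length(ds$subjects),
                 dimnames = list(ds$subjects, ds$molecules))
  }
  xprime <- sweep(ds$x, c(1L, 2L), x0, `-`)
  dimnames(xprime) <- dimnames(ds$x)
  flagged <- ds$molecules[colSums(!is.na(x0)) == 0L]
  if (length(flagged) > 0) {
    warning(
      "molecule(s) with all fasting values missing: ",
      paste(flagged, collapse = ", ")
    )
  }
  structure(
    list(
      xprime = xprime,
      annotation = ds$annotation,
      subjects = ds$subjects,
      molecules = ds$molecules,
      times = ds$times,
      flagged = flagged
    ),
    class = "differenced_dataset"
  )
}

#' @export
print.differenced_dataset <- function(x, ...) {
  cat(
    "<differenced_dataset> ", length(x$subjects), " subjects x ",
    length(x$molecules), " molecules x ", length(x$times), " time points\n",
    sep = ""
  )
  invisible(x)
}

# extract the subject x time matrix of one molecule
molecule_matrix <- function(obj, molecule) {
  arr <- if (inherits(obj, "differenced_dataset")) obj$xprime else obj$x
  k <- match(molecule, obj$molecules)
  if (is.na(k)) stop("unknown molecule: ", molecule)
  m <- arr[, k, , drop = TRUE]
  matrix(m, nrow = length(obj$subjects),
         dimnames = list(obj$subjects, as.character(obj$times)))
}
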