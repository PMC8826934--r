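# trapezoidal area of y over t
trapz_area <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# cumulative trapezoidal area at each grid point (0 at the first)
cumtrapz_area <- function(t, y) {
  n <- length(t)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

# bridge interior NAs by linear interpolation; trim leading/trailing NAs
bridge_missing <- function(t, y) {
  ok <- !is.na(y)
  if (sum(ok) < 2L) return(NULL)
  keep <- seq(min(which(ok)), max(which(ok)))
  t <- t[keep]
  y <- y[keep]
  if (anyNA(y)) {
    y <- approx(t[!is.na(y)], y[!is.na(y)], xout = t)$y
  }
  list(t = t, y = y)
}

#' Signed area under a difference-from-fasting trajectory
#'
#' Trapezoidal integration of x' over the observation window, in
#' concentration x minutes. Because x' is the deviation from the fasting
#' value, the area is signed: negative for molecules that fall below their
#' fasting level. Interior missing points are bridged by linear
#' interpolation between their neighbours; leading/trailing missing points
#' shrink the integration range.
#'
#' @param times grid in minutes (including 0).
#' @param xprime difference-from-fasting values on the grid (`NA` allowed).
#' @return Signed area, or `NA` if fewer than 2 points are available.
#' @export
auc_trapezoid <- function(times, xprime) {
  b <- bridge_missing(times, xprime)
  if (is.null(b)) return(NA_real_)
  trapz_area(b$t, b$y)
}

#' Time to reach half of the total signed area
#'
#' The cumulative trapezoidal area is followed along the trajectory and the
#' earliest time at which it first reaches half of the total signed area is
#' returned, locating the crossing by linear interpolation inside the
#' bracketing grid interval. For a trajectory that changes sign the
#' cumulative area can cross the half level more than once; the earliest
#' crossing is returned and the result flagged non-monotone.
#'
#' @param times grid in minutes (including 0).
#' @param xprime difference-from-fasting values on the grid.
#' @return List with `t_half` (minutes, `NA` if the total area is 0 or
#'   undefined) and `flag` (`"ok"`, `"zero_auc"`, `"non_monotone"` or
#'   `"undefined"`).
#' @export
t_auc_half <- function(times, xprime) {
  b <- bridge_missing(times, xprime)
  if (is.null(b)) return(list(t_half = NA_real_, flag = "undefined"))
  total <- trapz_area(b$t, b$y)
  if (total == 0) return(list(t_half = NA_real_, flag = "zero_auc"))
  cum <- cumtrapz_area(b$t, b$y)
  half <- total / 2
  # crossing when the cumulative area passes `half` in the sign of total
  s <- sign(total)
  reached <- s * cum >= s * half
  if (!any(reached)) return(list(t_half = NA_real_, flag = "undefined"))
  i <- which(reached)[1L]
  t_half <- if (i == 1L) {
    b$t[1L]
  } else {
    # linear interpolation of the cumulative area inside [t[i-1], t[i]]
    b$t[i - 1L] + (half - cum[i - 1L]) / (cum[i] - cum[i - 1L]) *
      (b$t[i] - b$t[i - 1L])
  }
  # more than one sign change of (cum - half) marks a non-monotone area
  cross <- diff(s * cum >= s * half)
  flag <- if (sum(cross != 0) > 1L) "non_monotone" else "ok"
  list(t_half = t_half, flag = flag)
}

#' Per-subject AUC and half-AUC-time feature table
#'
#' Computes, for every subject and molecule, the signed trapezoidal area of
#' the difference-from-fasting trajectory and the time at which half of
#' that area is reached.
#'
#' @param dd a `differenced_dataset`.
#' @return Tibble (subject_id, molecule, auc, t_auc_half, flag).
#' @export
temporal_features <- function(dd) {
  stopifnot(inherits(dd, "differenced_dataset"))
  res <- vector("list", length(dd$subjects) * length(dd$molecules))
  idx <- 0L
  for (mol in dd$molecules) {
    m <- molecule_matrix(dd, mol)
    for (s in seq_along(dd$subjects)) {
      idx <- idx + 1L
      y <- m[s, ]
      a <- auc_trapezoid(dd$times, y)
      th <- t_auc_half(dd$times, y)
      res[[idx]] <- list(
        subject_id = dd$subjects[s], molecule = mol,
        auc = a, t_auc_half = th$t_half, flag = th$flag
      )
    }
  }
  dplyr::bind_rows(res)
}

#' Correlation screen of per-subject features against reference molecules
#'
#' For each reference molecule (typically glucose and insulin), each target
#' molecule and each feature (AUC, half-AUC time), the Pearson correlation
#' across subjects between the reference's and the target's per-subject
#' feature values is computed, with p-values from the correlation test and
#' q-values from one Storey family over the whole screen.
#'
#' @param ft feature tibble from [temporal_features()].
#' @param references molecule ids to correlate against.
#' @param targets molecule ids to screen (defaults to all non-reference
#'   molecules present).
#' @param q_threshold significance cut on the q-value.
#' @param lambda Storey tuning parameter.
#' @return Tibble (reference, target, feature, n, r, p, q, significant).
#' @export
feature_correlation_screen <- function(ft, references,
                                       targets = NULL,
                                       q_threshold = 0.1,
                                       lambda = 0.5) {
  stopifnot(all(references %in% ft$molecule))
  targets <- targets %||% setdiff(unique(ft$molecule), references)
  feats <- c("auc", "t_auc_half")
  rows <- list()
  for (ref in references) {
    fr <- ft[ft$molecule == ref, ]
    for (tg in targets) {
      if (tg == ref) next
      tt <- ft[ft$molecule == tg, ]
      merged <- dplyr::inner_join(
        fr[c("subject_id", feats)], tt[c("subject_id", feats)],
        by = "subject_id", suffix = c("_ref", "_tg")
      )
      for (f in feats) {
        a <- merged[[paste0(f, "_ref")]]
        b <- merged[[paste0(f, "_tg")]]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) next
        ct <- cor.test(a[ok], b[ok], method = "pearson")
        rows[[length(rows) + 1L]] <- list(
          reference = ref, target = tg, feature = f,
          n = sum(ok), r = unname(ct$estimate), p = ct$p.value
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      reference = character(), target = character(), feature = character(),
      n = integer(), r = numeric(), p = numeric(), q = numeric(),
      significant = logical()
    ))
  }
  out <- dplyr::bind_rows(rows)
  out$q <- as.numeric(storey_qvalues(out$p, lambda = lambda))
  out$significant <- out$q < q_threshold
  out
}
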