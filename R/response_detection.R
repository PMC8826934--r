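#' Paired tests of each post-ingestion time point against fasting
#'
#' For every molecule and every time point after 0 min, a two-tailed paired
#' t-test compares the subjects' concentrations at that time with their
#' fasting values. Subjects missing either member of the pair are dropped
#' pairwise; fewer than 3 complete pairs leaves the p-value unavailable.
#' Two degenerate cases are resolved explicitly: all differences exactly
#' zero gives t = 0, p = 1; all differences equal but non-zero (zero
#' variance, certain change) is reported as p = 0 with `degenerate = TRUE`.
#'
#' @param ds a `timecourse_dataset` whose grid contains t = 0.
#' @return Tibble (molecule, time_min, n_pairs, t, p, degenerate).
#' @export
paired_tests <- function(ds) {
  if (!(0 %in% ds$times)) stop("dataset grid must contain t = 0")
  i0 <- which(ds$times == 0)
  post <- which(ds$times > 0)
  res <- vector("list", n_molecules(ds) * length(post))
  idx <- 0L
  for (k in seq_len(n_molecules(ds))) {
    m <- matrix(ds$x[, k, ], nrow = n_subjects(ds))
    x0 <- m[, i0]
    for (ti in post) {
      idx <- idx + 1L
      xt <- m[, ti]
      ok <- !is.na(x0) & !is.na(xt)
      n <- sum(ok)
      row <- list(
        molecule = ds$molecules[k], time_min = ds$times[ti],
        n_pairs = n, t = NA_real_, p = NA_real_, degenerate = FALSE
      )
      if (n >= 3L) {
        d <- xt[ok] - x0[ok]
        if (sd(d) == 0) {
          if (all(d == 0)) {
            row$t <- 0
            row$p <- 1
          } else {
            row$p <- 0
            row$degenerate <- TRUE
          }
        } else {
          tt <- t.test(xt[ok], x0[ok], paired = TRUE)
          row$t <- unname(tt$statistic)
          row$p <- tt$p.value
        }
      }
      res[[idx]] <- row
    }
  }
  dplyr::bind_rows(res)
}

#' Per-time fold changes relative to fasting
#'
#' The default is the paired form: the mean over subjects of the per-subject
#' log2 ratio x_t / x_0, matching the paired test design. The alternative
#' `"ratio_of_means"` takes log2 of the ratio of the subject means. Subjects
#' with non-positive values in either member of a pair are dropped with a
#' warning (the log ratio is undefined).
#'
#' @param ds a `timecourse_dataset`.
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return Tibble (molecule, time_min, log2fc, n_used).
#' @export
fold_changes <- function(ds, method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  if (!(0 %in% ds$times)) stop("dataset grid must contain t = 0")
  i0 <- which(ds$times == 0)
  post <- which(ds$times > 0)
  dropped <- 0L
  res <- vector("list", n_molecules(ds) * length(post))
  idx <- 0L
  for (k in seq_len(n_molecules(ds))) {
    m <- matrix(ds$x[, k, ], nrow = n_subjects(ds))
    x0 <- m[, i0]
    for (ti in post) {
      idx <- idx + 1L
      xt <- m[, ti]
      ok <- !is.na(x0) & !is.na(xt)
      pos <- ok & x0 > 0 & xt > 0
      dropped <- dropped + sum(ok & !pos)
      fc <- if (sum(pos) == 0L) {
        NA_real_
      } else if (method == "mean_of_ratios") {
        mean(log2(xt[pos] / x0[pos]))
      } else {
        log2(mean(xt[pos]) / mean(x0[pos]))
      }
      res[[idx]] <- list(
        molecule = ds$molecules[k], time_min = ds$times[ti],
        log2fc = fc, n_used = sum(pos)
      )
    }
  }
  if (dropped > 0) {
    warning(dropped, " pair(s) with non-positive concentrations dropped ",
            "from fold-change computation")
  }
  dplyr::bind_rows(res)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the upper tail of the p-value
#' distribution and scales the Benjamini-Hochberg step-up quantities by it:
#' q_i = pi0 * min over p_j >= p_i of (m * p_j / rank_j), clipped to \[0, 1\].
#' The default uses a single tuning point lambda = 0.5; `smoother = TRUE`
#' instead fits a cubic smoothing spline to pi0(lambda) over a lambda grid
#' and evaluates it at the grid maximum.
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA`s are carried
#'   through untouched.
#' @param lambda tuning parameter in (0, 1) for the point estimate.
#' @param smoother logical; use the spline estimate of pi0.
#' @param lambda_grid grid used when `smoother = TRUE`.
#' @return Numeric vector of q-values, same length and order as `p`, with
#'   attribute `"pi0"`.
#' @export
storey_qvalues <- function(p, lambda = 0.5, smoother = FALSE,
                           lambda_grid = seq(0.05, 0.90, by = 0.05)) {
  if (length(p) == 0) stop("empty p-value vector")
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) == 0) stop("all p-values missing")
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)

  pi0 <- if (smoother) {
    est <- vapply(lambda_grid, function(l) mean(pv > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda_grid, est, df = 3)
    unname(predict(fit, x = max(lambda_grid))$y)
  } else {
    mean(pv > lambda) / (1 - lambda)
  }
  pi0 <- min(max(pi0, 0), 1)
  if (pi0 == 0) pi0 <- 1 / m  # degenerate: no p above lambda

  # step-up: ordered by p, running minimum of m * p / rank from the top
  o <- order(pv)
  ranked <- pv[o] * m / seq_len(m)
  qv <- rev(cummin(rev(ranked))) * pi0
  qv <- pmin(qv, 1)
  out <- rep(NA_real_, length(p))
  out[ok][o] <- qv
  attr(out, "pi0") <- pi0
  out
}

#' Call glucose-responsive molecules
#'
#' A molecule is a responder when at some post-ingestion time point its
#' absolute log2 fold change strictly exceeds `fc_threshold` (0.585, i.e. a
#' 1.5-fold change) and its q-value is strictly below `q_threshold`. The
#' direction of response is the sign of the fold change at the earliest such
#' time point, so molecules that move both ways are labelled by their first
#' significant excursion.
#'
#' @param ds a `timecourse_dataset`.
#' @param fc_threshold absolute log2 fold-change cut (strict >).
#' @param q_threshold q-value cut (strict <).
#' @param family `"pooled"` (one Storey family across all molecule x time
#'   tests, default) or `"per_molecule"`.
#' @param fc_method passed to [fold_changes()].
#' @param lambda,smoother passed to [storey_qvalues()].
#' @return An object of class `response_table`: list with `tests` (tibble
#'   molecule, time_min, log2fc, t, p, q, significant) and `responders`
#'   (tibble molecule, responder, direction, earliest_sig_time), plus the
#'   thresholds used.
#' @export
call_responders <- function(ds, fc_threshold = 0.585, q_threshold = 0.1,
                            family = c("pooled", "per_molecule"),
                            fc_method = "mean_of_ratios",
                            lambda = 0.5, smoother = FALSE) {
  family <- match.arg(family)
  tests <- dplyr::left_join(
    paired_tests(ds),
    fold_changes(ds, method = fc_method),
    by = c("molecule", "time_min")
  )
  if (family == "pooled") {
    tests$q <- as.numeric(storey_qvalues(tests$p, lambda = lambda,
                                         smoother = smoother))
  } else {
    tests <- dplyr::group_by(tests, .data$molecule)
    tests <- dplyr::mutate(
      tests,
      q = as.numeric(storey_qvalues(.data$p, lambda = lambda,
                                    smoother = smoother))
    )
    tests <- dplyr::ungroup(tests)
  }
  tests$significant <- !is.na(tests$log2fc) & !is.na(tests$q) &
    abs(tests$log2fc) > fc_threshold & tests$q < q_threshold

  responders <- dplyr::summarise(
    dplyr::group_by(tests, .data$molecule),
    responder = any(.data$significant),
    earliest_sig_time = if (any(.data$significant)) {
      min(.data$time_min[.data$significant])
    } else {
      NA_real_
    },
    direction = if (any(.data$significant)) {
      first_t <- min(.data$time_min[.data$significant])
      if (.data$log2fc[.data$significant &
                         .data$time_min == first_t][1L] > 0) {
        "increase"
      } else {
        "decrease"
      }
    } else {
      "none"
    },
    .groups = "drop"
  )
  responders <- responders[match(ds$molecules, responders$molecule), ]

  structure(
    list(
      tests = tests,
      responders = responders,
      fc_threshold = fc_threshold,
      q_threshold = q_threshold,
      family = family
    ),
    class = "response_table"
  )
}

#' @export
print.response_table <- function(x, ...) {
  n <- sum(x$responders$responder, na.rm = TRUE)
  cat(
    "<response_table> ", nrow(x$responders), " molecules; ", n,
    " responder(s) at |log2FC| > ", x$fc_threshold, ", q < ",
    x$q_threshold, "\n",
    sep = ""
  )
  invisible(x)
}
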