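#' Default OGTT sampling grid
#'
#' Thirteen draws from fasting to 240 min, the standard dense OGTT schedule.
#'
#' @return Integer vector of minutes.
#' @export
ogtt_grid <- function() {
  c(0, 10, 20, 30, 45, 60, 75, 90, 120, 150, 180, 210, 240)
}

#' Temporal archetype specification
#'
#' A parametric template for the post-ingestion excursion of one molecule
#' class, expressed as a relative deviation from baseline (0 at t = 0).
#'
#' @param shape one of `"transient_increase"`, `"sustained_decrease"`,
#'   `"transient_decrease"`, `"flat"`, `"late_rebound"`.
#' @param peak_time minutes at which the extremum is reached (ignored for
#'   `"flat"`).
#' @param peak_amplitude magnitude of the extremum as a multiple of baseline
#'   (> 0 for non-flat shapes).
#' @param return_fraction fraction of the peak deviation remaining at the end
#'   of the window, in \[0, 1\]. Sustained shapes require >= 0.5 (they do not
#'   recover past half of their excursion); transient shapes < 0.5.
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(shape, peak_time = 60, peak_amplitude = 1,
                           return_fraction = 0.2) {
  shape <- match.arg(shape, c(
    "transient_increase", "sustained_decrease", "transient_decrease",
    "flat", "late_rebound"
  ))
  stopifnot(return_fraction >= 0, return_fraction <= 1)
  if (shape != "flat" && peak_amplitude <= 0) {
    stop("peak_amplitude must be > 0 for non-flat shapes")
  }
  if (shape == "sustained_decrease" && return_fraction < 0.5) {
    stop("sustained shapes require return_fraction >= 0.5")
  }
  structure(
    list(
      shape = shape, peak_time = peak_time,
      peak_amplitude = peak_amplitude, return_fraction = return_fraction
    ),
    class = "archetype_spec"
  )
}

#' Evaluate an archetype template on a time grid
#'
#' The template is 0 at t = 0, reaches its signed extremum (magnitude
#' `peak_amplitude`) exactly at `peak_time`, and relaxes smoothly (cosine
#' half-waves) so that the deviation remaining at the final time point is
#' `return_fraction * peak_amplitude`. The `late_rebound` shape falls to its
#' minimum and then overshoots back above baseline, emulating
#' counter-regulatory hormones such as growth hormone.
#'
#' @param spec an [archetype_spec()].
#' @param times numeric grid of minutes (must contain 0 and, for non-flat
#'   shapes, bracket `peak_time`).
#' @return Numeric vector of relative deviations, one per grid point.
#' @export
archetype_curve <- function(spec, times) {
  stopifnot(inherits(spec, "archetype_spec"))
  if (spec$shape == "flat") {
    return(rep(0, length(times)))
  }
  t_end <- max(times)
  if (spec$peak_time <= 0 || spec$peak_time > t_end) {
    stop("peak_time must lie inside (0, max(times)]")
  }
  a <- spec$peak_amplitude
  rf <- spec$return_fraction
  rise <- function(t) a * (1 - cos(pi * t / spec$peak_time)) / 2
  fall <- function(t) {
    if (spec$peak_time == t_end) {
      return(rep(a, length(t)))
    }
    a * (rf + (1 - rf) *
           (1 + cos(pi * (t - spec$peak_time) / (t_end - spec$peak_time))) / 2)
  }
  up <- ifelse(times <= spec$peak_time, rise(times), fall(times))
  switch(spec$shape,
    transient_increase = up,
    transient_decrease = -up,
    sustained_decrease = -up,
    late_rebound = {
      # descend to -a at peak_time, then rebound through baseline to +rf * a
      reb <- ifelse(
        times <= spec$peak_time,
        -rise(times),
        -a + (a + rf * a) * (times - spec$peak_time) /
          (t_end - spec$peak_time)
      )
      reb
    }
  )
}

#' Cohort generator specification
#'
#' Defines the synthetic study: subjects, grid, molecule groups with their
#' temporal archetypes, and the noise structure. Each entry of `groups` is a
#' list with elements `group` (metabolic group label), `n` (molecule count)
#' and `archetype` (an [archetype_spec()]); several entries may share one
#' group label.
#'
#' The noise model is multiplicative around a subject-by-molecule baseline:
#' \deqn{x_{j,k,t} = b_{j,k} (1 + a_{j,k} f_k(t) + o_{j,k,t} + \epsilon_{j,k,t})}
#' where `f_k` is the archetype template, `a_{j,k} ~ N(1, shape_noise_sd)`
#' is a subject-specific amplitude, `o_{j,k,t}` is a subject offset of s.d.
#' `offset_sd` that persists across time points with probability
#' `rank_stability` (and is redrawn per time point otherwise), and the
#' residual noise is split between a component shared within each metabolic
#' group (weight `within_group_corr`) and an independent component.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param times sampling grid in minutes.
#' @param groups list of group entries, see Details.
#' @param baseline_cv coefficient of variation of the lognormal subject
#'   baselines.
#' @param shape_noise_sd s.d. of the subject amplitude and residual noise;
#'   the dial for inter-individual pattern similarity (TPSI).
#' @param rank_stability probability in \[0, 1\] that a subject's offset
#'   persists from one time point to the next; the dial for the temporal
#'   stability of subject rank order (TVRI).
#' @param offset_sd s.d. of the persistent/redrawn subject offsets.
#' @param within_group_corr fraction in \[0, 1\] of residual noise variance
#'   shared within a metabolic group; the dial for within-group TPSM.
#' @param missing_rate fraction of cells deleted uniformly at random.
#' @param baseline_scale named or unnamed numeric giving the median baseline
#'   concentration per molecule (recycled).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_subjects = 20,
                           times = ogtt_grid(),
                           groups = list(),
                           baseline_cv = 0.2,
                           shape_noise_sd = 0.08,
                           rank_stability = 0.85,
                           offset_sd = 0.15,
                           within_group_corr = 0.5,
                           missing_rate = 0.002,
                           baseline_scale = 100) {
  stopifnot(
    n_subjects >= 2,
    baseline_cv >= 0,
    shape_noise_sd >= 0,
    offset_sd >= 0,
    rank_stability >= 0, rank_stability <= 1,
    within_group_corr >= 0, within_group_corr <= 1,
    missing_rate >= 0, missing_rate <= 1
  )
  for (g in groups) {
    stopifnot(
      is.list(g),
      all(c("group", "n", "archetype") %in% names(g)),
      g$group %in% METABOLIC_GROUPS,
      g$n >= 1,
      inherits(g$archetype, "archetype_spec")
    )
  }
  structure(
    list(
      n_subjects = n_subjects, times = times, groups = groups,
      baseline_cv = baseline_cv, shape_noise_sd = shape_noise_sd,
      rank_stability = rank_stability, offset_sd = offset_sd,
      within_group_corr = within_group_corr, missing_rate = missing_rate,
      baseline_scale = baseline_scale
    ),
    class = "generator_spec"
  )
}

#' Study-like cohort preset
#'
#' Emulates the structure of a dense 20-subject OGTT panel of 83 blood
#' molecules: a glucose-related group with a large transient increase
#' peaking 20--60 min, lipids with a large transient decrease, amino acids
#' with a sustained decrease (plus one citrulline-like amino acid whose
#' kinetics are lipid-like), counter-regulatory hormones, and a majority of
#' unresponsive (flat) molecules. Eighteen molecules carry archetypes strong
#' enough to exceed the 1.5-fold responder cut (6 increasing, 12
#' decreasing).
#'
#' @param n_subjects number of subjects.
#' @param ... overrides passed to [generator_spec()].
#' @return A `generator_spec`.
#' @export
study_like_spec <- function(n_subjects = 20, ...) {
  groups <- list(
    list(group = "glucose-related", n = 4,
         archetype = archetype_spec("transient_increase", 45, 1.2, 0.15)),
    list(group = "glucose-related", n = 2,
         archetype = archetype_spec("flat")),
    list(group = "lipid", n = 2,
         archetype = archetype_spec("transient_decrease", 150, 0.55, 0.3)),
    list(group = "lipid", n = 10,
         archetype = archetype_spec("flat")),
    list(group = "amino acid", n = 7,
         archetype = archetype_spec("sustained_decrease", 180, 0.45, 0.85)),
    list(group = "amino acid", n = 1,   # citrulline-like: lipid kinetics
         archetype = archetype_spec("transient_decrease", 150, 0.5, 0.3)),
    list(group = "amino acid", n = 12,
         archetype = archetype_spec("flat")),
    list(group = "hormone", n = 1,
         archetype = archetype_spec("late_rebound", 180, 0.6, 0.3)),
    list(group = "hormone", n = 1,
         archetype = archetype_spec("sustained_decrease", 120, 0.5, 0.8)),
    list(group = "hormone", n = 5,
         archetype = archetype_spec("flat")),
    list(group = "ion", n = 5,
         archetype = archetype_spec("flat")),
    list(group = "other", n = 2,
         archetype = archetype_spec("transient_increase", 60, 0.7, 0.4)),
    list(group = "other", n = 31,
         archetype = archetype_spec("flat"))
  )
  generator_spec(n_subjects = n_subjects, groups = groups, ...)
}

#' Water-control cohort preset
#'
#' Same panel structure as [study_like_spec()] but every archetype flat: the
#' null arm in which no molecule truly responds, used to check the
#' false-responder rate.
#'
#' @param n_subjects number of subjects.
#' @param ... overrides passed to [generator_spec()].
#' @return A `generator_spec`.
#' @export
water_like_spec <- function(n_subjects = 20, ...) {
  spec <- study_like_spec(n_subjects = n_subjects, ...)
  spec$groups <- lapply(spec$groups, function(g) {
    g$archetype <- archetype_spec("flat")
    g
  })
  spec
}

#' Generate a synthetic cohort
#'
#' Draws a full subject x molecule x time dataset from a [generator_spec()],
#' together with the ground truth used to generate it. The same seed always
#' yields a bit-identical dataset.
#'
#' @param spec a `generator_spec`.
#' @param seed integer seed for all randomness.
#' @param duplicate_fasting if `TRUE`, emit an additional t = -10 draw equal
#'   to an independent noisy replicate of the fasting state, mimicking the
#'   double pre-ingestion draw.
#' @return A `timecourse_dataset` with attribute `"ground_truth"`: a list
#'   with `molecules` (tibble: molecule, group, shape, peak_time,
#'   peak_amplitude, return_fraction) and `baselines` (subject x molecule
#'   matrix).
#' @export
generate_dataset <- function(spec, seed = 1, duplicate_fasting = FALSE) {
  stopifnot(inherits(spec, "generator_spec"), length(spec$groups) > 0)
  set.seed(as.integer(seed))

  times <- spec$times
  if (duplicate_fasting) times <- c(-10, times)
  n_t <- length(times)
  n_s <- spec$n_subjects
  subjects <- sprintf("S%02d", seq_len(n_s))

  truth <- do.call(rbind, lapply(seq_along(spec$groups), function(i) {
    g <- spec$groups[[i]]
    data.frame(
      group = g$group, shape = g$archetype$shape,
      peak_time = g$archetype$peak_time,
      peak_amplitude = g$archetype$peak_amplitude,
      return_fraction = g$archetype$return_fraction,
      entry = i, idx = seq_len(g$n),
      stringsAsFactors = FALSE
    )
  }))
  n_m <- nrow(truth)
  truth$molecule <- sprintf("M%02d_%s", seq_len(n_m),
                            gsub("[^a-z]+", "_", truth$group))
  molecules <- truth$molecule

  # templates on the post-ingestion grid; 0 for the extra -10 draw
  grid0 <- spec$times
  templates <- vapply(seq_len(n_m), function(k) {
    g <- spec$groups[[truth$entry[k]]]
    tpl <- archetype_curve(g$archetype, grid0)
    if (duplicate_fasting) tpl <- c(0, tpl)
    tpl
  }, numeric(n_t))                      # n_t x n_m

  # lognormal baselines with the requested CV
  scale <- rep_len(spec$baseline_scale, n_m)
  sdlog <- sqrt(log(1 + spec$baseline_cv^2))
  baselines <- matrix(
    rlnorm(n_s * n_m, meanlog = log(scale)[rep(seq_len(n_m), each = n_s)] -
             sdlog^2 / 2, sdlog = sdlog),
    nrow = n_s, dimnames = list(subjects, molecules)
  )

  amp <- matrix(rnorm(n_s * n_m, 1, spec$shape_noise_sd), nrow = n_s)

  x <- array(NA_real_, dim = c(n_s, n_m, n_t),
             dimnames = list(subjects, molecules, as.character(times)))

  group_of <- truth$group
  group_levels <- unique(group_of)
  w_shared <- sqrt(spec$within_group_corr)
  w_indep <- sqrt(1 - spec$within_group_corr)

  # shared within-group noise: one draw per (subject, group, time)
  shared <- array(
    rnorm(n_s * length(group_levels) * n_t, 0, spec$shape_noise_sd),
    dim = c(n_s, length(group_levels), n_t)
  )

  for (k in seq_len(n_m)) {
    # subject offsets: persist across time with probability rank_stability
    offset <- matrix(NA_real_, n_s, n_t)
    o_cur <- rnorm(n_s, 0, spec$offset_sd)
    for (ti in seq_len(n_t)) {
      redraw <- runif(n_s) > spec$rank_stability
      o_cur[redraw] <- rnorm(sum(redraw), 0, spec$offset_sd)
      offset[, ti] <- o_cur
    }
    gi <- match(group_of[k], group_levels)
    sh <- matrix(shared[, gi, ], n_s, n_t)
    eps <- w_shared * sh +
      w_indep * matrix(rnorm(n_s * n_t, 0, spec$shape_noise_sd), n_s)
    rel <- 1 + amp[, k] %o% templates[, k] + offset + eps
    x[, k, ] <- baselines[, k] * rel
  }

  if (spec$missing_rate > 0) {
    drop <- runif(length(x)) < spec$missing_rate
    x[drop] <- NA_real_
  }

  ds <- timecourse_dataset(
    x,
    annotation = tibble::tibble(
      molecule = molecules, metabolic_group = group_of
    )
  )
  attr(ds, "ground_truth") <- list(
    molecules = tibble::as_tibble(
      truth[c("molecule", "group", "shape", "peak_time", "peak_amplitude",
              "return_fraction")]
    ),
    baselines = baselines
  )
  ds
}
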