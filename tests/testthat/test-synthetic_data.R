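test_that("archetype templates honour their anchor points", {
  g <- ogtt_grid()
  expect_equal(archetype_curve(archetype_spec("flat"), g), rep(0, 13))

  tr <- archetype_curve(archetype_spec("transient_increase", 45, 2, 0.1), g)
  expect_equal(tr[g == 0], 0)
  expect_equal(tr[g == 45], 2)
  expect_equal(abs(tr[g == 240]), 0.2)
  expect_equal(which.max(abs(tr)), which(g == 45))

  su <- archetype_curve(archetype_spec("sustained_decrease", 180, 1, 0.9), g)
  expect_equal(su[g == 240], -0.9)
  expect_equal(min(su), -1)
  expect_true(all(diff(su[g <= 180]) <= 0))  # monotone approach

  expect_error(
    archetype_curve(archetype_spec("transient_increase", 300, 1, 0.1), g),
    "peak_time"
  )
  expect_error(archetype_spec("sustained_decrease", 180, 1, 0.2),
               "return_fraction >= 0.5")
})

test_that("generation is deterministic for a fixed seed", {
  spec <- study_like_spec(n_subjects = 5)
  a <- generate_dataset(spec, seed = 99)
  b <- generate_dataset(spec, seed = 99)
  expect_identical(a$x, b$x)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(a, f1)
  write_timecourse_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  c <- generate_dataset(spec, seed = 100)
  expect_false(identical(a$x, c$x))
})

test_that("missing cells follow the requested rate", {
  spec <- study_like_spec(n_subjects = 20, missing_rate = 0.05)
  spec$groups <- list(list(
    group = "other", n = 10, archetype = archetype_spec("flat")
  ))
  n_cells <- 20 * 10 * 13
  counts <- vapply(1:5, function(s) {
    sum(is.na(generate_dataset(spec, seed = s)$x))
  }, numeric(1))
  # binomial 99% band around 0.05 * 2600 = 130 per replicate
  band <- qbinom(c(0.005, 0.995), n_cells, 0.05)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("noise-free generation gives one exact shape per molecule", {
  spec <- study_like_spec(
    n_subjects = 6, baseline_cv = 0, shape_noise_sd = 0, offset_sd = 0,
    rank_stability = 1, missing_rate = 0
  )
  ds <- generate_dataset(spec, seed = 3)
  dd <- difference_from_fasting(ds)
  ti <- tpsi(dd)
  gt <- attr(ds, "ground_truth")$molecules
  nonflat <- gt$molecule[gt$shape != "flat"]
  expect_true(all(abs(ti$tpsi[ti$molecule %in% nonflat] - 1) < 1e-12))

  # with baseline spread the trajectories are proportional, not identical:
  # the pooled pair correlation drops below 1 and must equal the value
  # computed directly from the ground-truth baselines and template
  spec$baseline_cv <- 0.3
  ds2 <- generate_dataset(spec, seed = 3)
  ti2 <- tpsi(difference_from_fasting(ds2))
  gt2 <- attr(ds2, "ground_truth")
  for (mol in nonflat[c(1, 8, 14)]) {
    row <- gt2$molecules[gt2$molecules$molecule == mol, ]
    tpl <- archetype_curve(
      archetype_spec(row$shape, row$peak_time, row$peak_amplitude,
                     row$return_fraction),
      ogtt_grid()
    )
    oracle <- enumerate_tpsi(outer(gt2$baselines[, mol], tpl))
    got <- ti2$tpsi[ti2$molecule == mol]
    expect_equal(got, oracle, tolerance = 1e-10)
    expect_true(got > 0.5 && got < 1)
  }
})

test_that("independent shapes per subject give TPSI centred near zero", {
  spec <- study_like_spec(
    n_subjects = 12, shape_noise_sd = 0.5, rank_stability = 0,
    offset_sd = 0.5, missing_rate = 0
  )
  spec$groups <- list(list(
    group = "other", n = 30, archetype = archetype_spec("flat")
  ))
  ds <- generate_dataset(spec, seed = 21)
  ti <- tpsi(difference_from_fasting(ds))
  expect_lt(abs(mean(ti$tpsi)), 0.1)
})

test_that("rank stability raises TVRI; within-group noise raises TPSM", {
  # paired seeds: stable vs reshuffled subject offsets
  delta <- vapply(1:20, function(s) {
    base <- list(
      n_subjects = 10, baseline_cv = 0, shape_noise_sd = 0.05,
      offset_sd = 0.3, missing_rate = 0
    )
    stable <- do.call(study_like_spec, c(base, rank_stability = 1))
    loose <- do.call(study_like_spec, c(base, rank_stability = 0))
    gt <- attr(generate_dataset(stable, seed = s), "ground_truth")$molecules
    nonflat <- gt$molecule[gt$shape != "flat"]
    t1 <- tvri(generate_dataset(stable, seed = s))
    t0 <- tvri(generate_dataset(loose, seed = s))
    mean(t1$tvri[t1$molecule %in% nonflat]) -
      mean(t0$tvri[t0$molecule %in% nonflat])
  }, numeric(1))
  expect_gt(mean(delta > 0), 0.95)

  # within-group shared noise makes same-group flat molecules more similar
  diffs <- vapply(1:10, function(s) {
    spec <- generator_spec(
      n_subjects = 10,
      groups = list(
        list(group = "lipid", n = 6, archetype = archetype_spec("flat")),
        list(group = "ion", n = 6, archetype = archetype_spec("flat"))
      ),
      within_group_corr = 0.8, missing_rate = 0, offset_sd = 0.05
    )
    tp <- tpsm(difference_from_fasting(generate_dataset(spec, seed = s)))
    A <- abs(tp$tpsm)
    within <- c(A[1:6, 1:6][upper.tri(A[1:6, 1:6])],
                A[7:12, 7:12][upper.tri(A[7:12, 7:12])])
    between <- A[1:6, 7:12]
    mean(within) - mean(between)
  }, numeric(1))
  expect_true(all(diffs > 0))
})
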