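test_that("TVRI is 1 for rank-preserving data and 0 for a full swap", {
  # x_{j,t} = a_j + f(t): each subject's z-score is constant over time
  f <- c(0, 5, 2, 8)
  m <- rbind(1 + f, 3 + f, 7 + f)
  colnames(m) <- c(0, 30, 60, 90)
  tv <- tvri(toy_dataset(m))
  expect_equal(tv$tvri, 1)

  # two subjects swapping positions between two times
  m2 <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c(0, 60)))
  expect_equal(tvri(toy_dataset(m2))$tvri, 0)
})

test_that("TVRI skips molecules with missing cells or degenerate variance", {
  m <- matrix(c(1, 2, NA, 3, 4, 5), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c(0, 30, 60)))
  tv <- tvri(toy_dataset(m))
  expect_true(is.na(tv$tvri))
  expect_equal(tv$skipped_reason, "missing data")

  m2 <- matrix(c(5, 1, 5, 2), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c(0, 60)))
  tv2 <- tvri(toy_dataset(m2))
  expect_equal(tv2$skipped_reason, "zero cross-subject variance")
})

test_that("TVRI matches the naive loop oracle on random data", {
  set.seed(19)
  for (rep in 1:5) {
    m <- matrix(rnorm(6 * 8, 50, 10), 6, 8,
                dimnames = list(NULL, seq(0, 210, by = 30)))
    tv <- tvri(toy_dataset(m))
    expect_equal(tv$tvri, naive_tvri(m), tolerance = 1e-12)
  }
})

test_that("TPSI spans all subject pairs and is exact on shared shapes", {
  set.seed(3)
  m <- matrix(rnorm(20 * 13, 100, 10), 20, 13,
              dimnames = list(NULL, ogtt_grid()))
  dd <- difference_from_fasting(toy_dataset(m))
  ti <- tpsi(dd)
  expect_equal(ti$n_pairs, 190L)

  # identical non-constant trajectories across subjects give exactly 1
  tpl <- c(0, 4, 2, 1)
  m2 <- matrix(rep(tpl, each = 5), 5, 4,
               dimnames = list(NULL, c(0, 30, 60, 240)))
  m2 <- m2 + 10
  ti2 <- tpsi(difference_from_fasting(toy_dataset(m2)))
  expect_equal(ti2$tpsi, 1)
})

test_that("TPSI equals the direct pair-enumeration oracle", {
  m <- matrix(c(
    0, 2, 1,
    0, 3, 2,
    0, 1, -1
  ), 3, 3, byrow = TRUE, dimnames = list(NULL, c(0, 60, 120)))
  ds <- toy_dataset(m + 50)
  dd <- difference_from_fasting(ds)
  expect_equal(tpsi(dd)$tpsi, enumerate_tpsi(m), tolerance = 1e-12)

  set.seed(29)
  m2 <- matrix(rnorm(6 * 5), 6, 5,
               dimnames = list(NULL, c(0, 30, 60, 120, 240)))
  m2[, 1] <- 0
  dd2 <- difference_from_fasting(toy_dataset(m2 + 100))
  expect_equal(tpsi(dd2)$tpsi, enumerate_tpsi(sweep(m2, 1, m2[, 1])),
               tolerance = 1e-10)
})

test_that("TPSI is invariant to subject offsets and common rescaling", {
  set.seed(37)
  m <- matrix(rnorm(5 * 6, 100, 10), 5, 6,
              dimnames = list(NULL, c(0, 30, 60, 120, 180, 240)))
  base <- tpsi(difference_from_fasting(toy_dataset(m)))$tpsi
  shifted <- m + c(5, -3, 10, 0, 2)     # per-subject constant
  expect_equal(tpsi(difference_from_fasting(toy_dataset(shifted)))$tpsi,
               base, tolerance = 1e-12)
  expect_equal(tpsi(difference_from_fasting(toy_dataset(m * 7)))$tpsi,
               base, tolerance = 1e-12)
})

test_that("TPSM matches hand-computed correlations on a small panel", {
  times <- c(0, 60, 120)
  a <- rbind(c(0, 2, 1), c(0, 4, 3))
  b <- -a                        # anti-phase partner
  c_ <- rbind(c(0, 1, 5), c(0, 2, 0))
  mats <- list(a = a + 100, b = b + 50, c = c_ + 80)
  for (i in seq_along(mats)) colnames(mats[[i]]) <- times
  ds <- toy_dataset_multi(mats, times)
  tp <- tpsm(difference_from_fasting(ds))
  expect_equal(unname(diag(tp$tpsm)), rep(1, 3))
  expect_equal(tp$tpsm["a", "b"], -1)
  expect_equal(tp$tpsm_abs["a", "b"], 1)
  hand_ac <- cor(as.vector(t(a)), as.vector(t(c_)))
  expect_equal(tp$tpsm["a", "c"], hand_ac, tolerance = 1e-12)
  expect_equal(tp$tpsm, t(tp$tpsm))
})

test_that("TPSM is invariant to a consistent subject reordering", {
  set.seed(41)
  times <- c(0, 30, 60, 120)
  mats <- list(
    a = cbind(0, matrix(rnorm(12), 4, 3)),
    b = cbind(0, matrix(rnorm(12), 4, 3))
  )
  for (i in 1:2) colnames(mats[[i]]) <- times
  ds <- toy_dataset_multi(lapply(mats, function(m) m + 10), times)
  tp1 <- tpsm(difference_from_fasting(ds))
  perm <- c(3, 1, 4, 2)
  ds2 <- toy_dataset_multi(lapply(mats, function(m) m[perm, ] + 10), times)
  tp2 <- tpsm(difference_from_fasting(ds2))
  expect_equal(tp1$tpsm["a", "b"], tp2$tpsm["a", "b"], tolerance = 1e-12)
})

test_that("fasting correlation profile has unit fasting column", {
  set.seed(43)
  m <- matrix(rnorm(8 * 4, 100, 10), 8, 4,
              dimnames = list(NULL, c(0, 60, 120, 240)))
  ds <- toy_dataset(m)
  prof <- fasting_correlation_profile(ds)
  expect_equal(unname(prof[, "0"]), 1)

  # subject-independent shift keeps r = 1 at every time
  m2 <- outer(rnorm(8, 100, 10), rep(1, 4)) +
    matrix(rep(c(0, 5, -3, 2), each = 8), 8, 4)
  dimnames(m2) <- dimnames(m)
  prof2 <- fasting_correlation_profile(toy_dataset(m2))
  expect_equal(unname(prof2[1, ]), rep(1, 4))

  # exact decreasing permutation gives the hand-computed negative r
  x0 <- c(1, 2, 3, 4, 5)
  m3 <- cbind(x0, rev(x0))
  colnames(m3) <- c(0, 60)
  prof3 <- fasting_correlation_profile(toy_dataset(m3))
  expect_equal(unname(prof3[1, "60"]), cor(x0, rev(x0)))
  expect_equal(unname(prof3[1, "60"]), -1)
})

test_that("index regimes reproduce the similarity quadrants", {
  # amino-acid-like: faithful shapes, stable ranks -> high TPSI, high TVRI
  # glucose-like: faithful shapes, shuffling ranks -> high TPSI, low TVRI
  res <- vapply(1:20, function(s) {
    base <- list(
      n_subjects = 10, times = ogtt_grid(), missing_rate = 0,
      shape_noise_sd = 0.05, baseline_cv = 0.15, offset_sd = 0.25
    )
    amino_groups <- list(list(
      group = "amino acid", n = 4,
      archetype = archetype_spec("sustained_decrease", 180, 0.5, 0.85)
    ))
    gluco_groups <- list(list(
      group = "glucose-related", n = 4,
      archetype = archetype_spec("transient_increase", 45, 1.2, 0.15)
    ))
    amino <- do.call(generator_spec,
                     c(base, list(groups = amino_groups), rank_stability = 1))
    gluco <- do.call(generator_spec,
                     c(base, list(groups = gluco_groups), rank_stability = 0))
    ds_a <- generate_dataset(amino, seed = s)
    ds_g <- generate_dataset(gluco, seed = s)
    sim_a <- similarity_indices(ds_a)
    sim_g <- similarity_indices(ds_g)
    c(tpsi_a = mean(sim_a$tpsi), tvri_a = mean(sim_a$tvri),
      tpsi_g = mean(sim_g$tpsi), tvri_g = mean(sim_g$tvri))
  }, numeric(4))
  means <- rowMeans(res)
  expect_gt(means["tpsi_a"], 0.5)
  expect_gt(means["tvri_a"], 0.6)
  expect_gt(means["tpsi_g"], 0.4)
  expect_lt(means["tvri_g"], means["tvri_a"] - 0.2)
})
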