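ann_for <- function(nodes, group = "other") {
  tibble::tibble(molecule = nodes, metabolic_group = group)
}

sym <- function(m) {
  dimnames(m) <- list(paste0("M", seq_len(nrow(m))),
                      paste0("M", seq_len(nrow(m))))
  diag(m) <- 1
  m
}

test_that("edges require strictly exceeding the threshold", {
  m <- sym(matrix(0.5, 4, 4))
  expect_equal(nrow(build_graph(m)$edges), 0L)

  m2 <- sym(matrix(0, 3, 3))
  m2[1, 2] <- m2[2, 1] <- 0.6       # boundary: no edge
  m2[1, 3] <- m2[3, 1] <- 0.601
  mg <- build_graph(m2)
  expect_equal(nrow(mg$edges), 1L)
  expect_equal(sort(c(mg$edges$source, mg$edges$target)), c("M1", "M3"))

  # signed edges from a hand-enumerated toy matrix
  m3 <- sym(matrix(c(
    1, 0.9, -0.7, 0.2,
    0.9, 1, 0.3, -0.1,
    -0.7, 0.3, 1, 0.65,
    0.2, -0.1, 0.65, 1
  ), 4, 4, byrow = TRUE))
  mg3 <- build_graph(m3)
  key <- paste(mg3$edges$source, mg3$edges$target)
  expect_setequal(key, c("M1 M2", "M1 M3", "M3 M4"))
  expect_equal(mg3$edges$sign[key == "M1 M3"], "negative")

  bad <- sym(matrix(0.1, 3, 3))
  bad[1, 2] <- 0.9
  expect_error(build_graph(bad), "not symmetric")
})

test_that("components partition connected nodes; isolated reported apart", {
  m <- sym(matrix(0, 4, 4))
  cc0 <- connected_components(build_graph(m))
  expect_true(all(is.na(cc0$component)))

  # two disjoint triangles plus an isolated node
  m2 <- sym(matrix(0, 7, 7))
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    m2[p[1], p[2]] <- m2[p[2], p[1]] <- 0.9
  }
  cc <- connected_components(build_graph(m2))
  expect_equal(sum(is.na(cc$component)), 1L)
  sizes <- table(cc$component)
  expect_equal(unname(sort(as.integer(sizes))), c(3L, 3L))
  expect_equal(cc$component_size[!is.na(cc$component)], rep(3L, 6))
})

test_that("random graphs agree with a union-find component oracle", {
  set.seed(51)
  for (rep in 1:5) {
    n <- 12
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.15) m[i, j] <- m[j, i] <- 0.9
    }
    m <- sym(m)
    cc <- connected_components(build_graph(m))
    # union-find oracle
    parent <- seq_len(n)
    find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (abs(m[i, j]) > 0.6) parent[find(i)] <- find(j)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    deg <- rowSums(abs(m) > 0.6) - 1  # diagonal is 1
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (deg[i] == 0 || deg[j] == 0) next
      same_oracle <- roots[i] == roots[j]
      same_pkg <- cc$component[i] == cc$component[j]
      expect_equal(same_pkg, same_oracle)
    }
  }
})

test_that("betweenness matches textbook cases and normalization", {
  # path A-B-C: the middle node carries the single geodesic
  m <- sym(matrix(0, 3, 3))
  m[1, 2] <- m[2, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- 0.9
  bc <- betweenness_centrality(build_graph(m))
  expect_equal(bc$betweenness, c(0, 1, 0))

  # complete K4: no node lies on another pair's geodesic
  m2 <- sym(matrix(0.9, 4, 4))
  expect_equal(betweenness_centrality(build_graph(m2))$betweenness,
               rep(0, 4))
})

test_that("betweenness equals brute-force geodesic enumeration", {
  set.seed(57)
  for (rep in 1:6) {
    n <- 8
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.3) m[i, j] <- m[j, i] <- 0.7
    }
    m <- sym(m)
    mg <- build_graph(m)
    bc <- betweenness_centrality(mg)
    adj <- (abs(m) > 0.6) * 1
    diag(adj) <- 0
    raw_oracle <- brute_betweenness(adj)
    n_conn <- sum(rowSums(adj) > 0)
    denom <- if (n_conn >= 3) (n_conn - 1) * (n_conn - 2) / 2 else 1
    expect_equal(bc$betweenness, raw_oracle / denom, tolerance = 1e-12)
  }
})

test_that("group-normalized degree divides by own-group panel size", {
  m <- sym(matrix(0, 9, 9))
  for (j in 2:5) m[1, j] <- m[j, 1] <- 0.9   # hub of degree 4
  nodes <- rownames(m)
  ann <- ann_for(nodes, group = c(rep("amino acid", 8), "lipid"))
  dn <- degree_normalized(build_graph(m, annotation = ann))
  expect_equal(dn$deg_normalized[dn$molecule == "M1"], 4 / 8)
  expect_equal(dn$deg_normalized[dn$molecule == "M9"], 0)
  expect_equal(dn$deg_normalized, dn$degree / dn$group_size)

  expect_error(
    degree_normalized(build_graph(m, annotation = ann_for(nodes[1:3]))),
    "without group annotation"
  )
})

test_that("raising the threshold never adds edges, degree or components", {
  set.seed(61)
  n <- 15
  m <- matrix(0, n, n)
  vals <- runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  m <- sym(m)
  prev_edges <- Inf
  prev_deg <- rep(Inf, n)
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    mg <- build_graph(m, annotation = ann_for(rownames(m)), threshold = thr)
    dn <- degree_normalized(mg)
    expect_lte(nrow(mg$edges), prev_edges)
    expect_true(all(dn$degree <= prev_deg))
    prev_edges <- nrow(mg$edges)
    prev_deg <- dn$degree
  }
})

test_that("a molecule mixing two group templates bridges the network", {
  g <- ogtt_grid()
  t1 <- archetype_curve(archetype_spec("transient_increase", 45, 1, 0.1), g)
  t2 <- archetype_curve(archetype_spec("sustained_decrease", 200, 1, 0.9), g)
  set.seed(71)
  n_s <- 10
  mk <- function(tpl) {
    m <- 100 * (1 + outer(rnorm(n_s, 1, 0.05), tpl) +
                  matrix(rnorm(n_s * 13, 0, 0.03), n_s))
    colnames(m) <- g
    m
  }
  mats <- c(
    setNames(lapply(1:4, function(i) mk(t1)), paste0("g", 1:4)),
    setNames(lapply(1:4, function(i) mk(t2)), paste0("a", 1:4)),
    list(bridge = mk((t1 + t2) / 2))
  )
  ds <- toy_dataset_multi(mats, g,
                          groups = c(rep("glucose-related", 4),
                                     rep("amino acid", 4), "other"))
  tp <- tpsm(difference_from_fasting(ds))
  ns <- network_summary(tp$tpsm, ds$annotation, threshold = 0.6)
  bb <- ns$nodes
  expect_equal(bb$molecule[which.max(bb$betweenness)], "bridge")
})
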