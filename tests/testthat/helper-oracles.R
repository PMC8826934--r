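# Builders and independent oracles used across the suite.

# dataset from a subjects x times matrix for a single molecule
toy_dataset <- function(m, molecule = "glc", times = NULL,
                        group = "glucose-related") {
  times <- times %||% as.numeric(colnames(m))
  subjects <- rownames(m) %||% sprintf("S%d", seq_len(nrow(m)))
  x <- array(
    m,
    dim = c(nrow(m), 1L, ncol(m)),
    dimnames = list(subjects, molecule, as.character(times))
  )
  timecourse_dataset(
    x,
    annotation = tibble::tibble(molecule = molecule, metabolic_group = group)
  )
}

# dataset from a named list of subjects x times matrices (shared grid)
toy_dataset_multi <- function(mats, times, groups = NULL) {
  subjects <- sprintf("S%d", seq_len(nrow(mats[[1]])))
  x <- array(
    NA_real_,
    dim = c(nrow(mats[[1]]), length(mats), length(times)),
    dimnames = list(subjects, names(mats), as.character(times))
  )
  for (k in seq_along(mats)) x[, k, ] <- mats[[k]]
  groups <- groups %||% rep("other", length(mats))
  timecourse_dataset(
    x,
    annotation = tibble::tibble(
      molecule = names(mats), metabolic_group = groups
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive triple-loop implementation of the dispersion normalization
naive_normalize <- function(x) {
  n_s <- dim(x)[1]; n_m <- dim(x)[2]; n_t <- dim(x)[3]
  i0 <- which(as.numeric(dimnames(x)[[3]]) == 0)
  Y <- array(NA_real_, dim = dim(x), dimnames = dimnames(x))
  for (k in seq_len(n_m)) {
    S <- rep(NA_real_, n_t)
    for (ti in seq_len(n_t)) {
      v <- x[, k, ti]
      v <- v[!is.na(v)]
      if (length(v) >= 2) S[ti] <- sqrt(mean((v - mean(v))^2))
    }
    sbar <- mean(S, na.rm = TRUE)
    if (is.nan(sbar) || sbar == 0) next
    for (j in seq_len(n_s)) {
      for (ti in seq_len(n_t)) {
        Y[j, k, ti] <- (x[j, k, ti] - x[j, k, i0]) / sbar
      }
    }
  }
  Y
}

# naive loop implementation of TVRI for one subjects x times matrix
naive_tvri <- function(m) {
  n_s <- nrow(m); n_t <- ncol(m)
  z <- matrix(NA_real_, n_s, n_t)
  for (ti in seq_len(n_t)) {
    mu <- mean(m[, ti])
    s <- sqrt(sum((m[, ti] - mu)^2) / (n_s - 1))
    z[, ti] <- (m[, ti] - mu) / s
  }
  s_z <- numeric(n_s)
  for (j in seq_len(n_s)) {
    mu <- mean(z[j, ])
    s_z[j] <- sqrt(sum((z[j, ] - mu)^2) / (n_t - 1))
  }
  1 - mean(s_z)
}

# TPSI by explicit pair enumeration (independent of pair_concatenation)
enumerate_tpsi <- function(m) {
  X <- c(); Y <- c()
  n <- nrow(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      X <- c(X, m[i, ])
      Y <- c(Y, m[j, ])
    }
  }
  cor(X, Y)
}

# Ward (ward.D2 convention) agglomeration via the Lance-Williams update;
# returns merge heights sorted ascending
lw_ward_heights <- function(M) {
  n <- nrow(M)
  d2 <- as.matrix(dist(M))^2
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- NA; bj <- NA
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1)) {
        i <- active[a]; j <- active[b]
        if (d2[i, j] < best) { best <- d2[i, j]; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, sqrt(best))
    # merge bj into bi with Ward's Lance-Williams coefficients on squared d
    for (k in setdiff(active, c(bi, bj))) {
      ai <- size[bi]; aj <- size[bj]; ak <- size[k]
      d2[bi, k] <- d2[k, bi] <-
        ((ai + ak) * d2[bi, k] + (aj + ak) * d2[bj, k] -
           ak * d2[bi, bj]) / (ai + aj + ak)
    }
    size[bi] <- size[bi] + size[bj]
    active <- setdiff(active, bj)
  }
  sort(heights)
}

# brute-force betweenness by enumerating all simple paths (n <= 8);
# returns raw (unnormalized) betweenness per node of the adjacency matrix
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    found <- list()
    walk <- function(v, visited) {
      if (v == t) {
        found[[length(found) + 1]] <<- visited
        return(invisible(NULL))
      }
      for (w in which(adj[v, ] > 0)) {
        if (!(w %in% visited)) walk(w, c(visited, w))
      }
    }
    walk(s, s)
    found
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      len <- vapply(ps, length, integer(1))
      geod <- ps[len == min(len)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(geod, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + through / length(geod)
      }
    }
  }
  b
}
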