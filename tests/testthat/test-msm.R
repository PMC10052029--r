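test_that("k-means microstates separate well-separated clouds", {
  set.seed(2)
  X <- rbind(matrix(rnorm(100, mean = 0, sd = 0.3), ncol = 2),
             matrix(rnorm(100, mean = 10, sd = 0.3), ncol = 2))
  lab <- cluster_microstates(X, k = 2, seed = 5)
  expect_equal(length(unique(lab[1:50])), 1L)
  expect_equal(length(unique(lab[51:100])), 1L)
  expect_false(lab[1] == lab[51])

  expect_error(cluster_microstates(X, k = 1, seed = 1), "k >= 2")
  expect_identical(cluster_microstates(X, 4, seed = 9),
                   cluster_microstates(X, 4, seed = 9))
})

test_that("transition estimation reproduces deterministic and planted chains", {
  alt <- rep(c(1L, 2L), 50)
  m <- estimate_transition_matrix(alt, lag = 1, mode = "raw")
  expect_equal(m$transition, rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)

  planted <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  s <- sample_markov_chain(planted, 1e5, seed = 7)
  est <- estimate_transition_matrix(s, lag = 1, mode = "raw")
  expect_lt(max(abs(est$transition - planted)), 0.01)
  expect_equal(unname(rowSums(est$transition)), c(1, 1), tolerance = 1e-10)
  # spectral invariants
  expect_equal(Mod(est$eigenvalues[1]), 1, tolerance = 1e-8)
  expect_equal(as.vector(est$stationary %*% est$transition), est$stationary,
               tolerance = 1e-8)

  expect_error(estimate_transition_matrix(alt, lag = 100), "shorter")
})

test_that("replica boundaries contribute no transition counts", {
  # two replicas stuck in different states: no cross-counts may appear
  reps <- list(rep(1L, 50), rep(2L, 50))
  # both states self-absorbing -> connected set is a single state
  m <- estimate_transition_matrix(reps, lag = 1)
  expect_equal(nrow(m$transition), 1L)
  expect_length(m$trimmed, 1L)
})

test_that("symmetrized estimates satisfy detailed balance", {
  planted <- rbind(c(0.85, 0.1, 0.05), c(0.15, 0.8, 0.05), c(0.1, 0.2, 0.7))
  s <- sample_markov_chain(planted, 2e4, seed = 9)
  m <- estimate_transition_matrix(s, lag = 1, mode = "symmetrized")
  Tm <- m$transition; pi_v <- m$stationary
  # detailed balance: pi_i T_ij == pi_j T_ji
  expect_equal(pi_v * Tm, t(pi_v * Tm), tolerance = 1e-8)
})

test_that("implied timescales follow the spectral closed form and stay flat", {
  # engineered sequence with exact raw counts C = [[3,1],[1,3]] per cycle:
  # raw T = [[0.75, 0.25], [0.25, 0.75]], lambda2 = 0.5
  s <- c(rep(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), 100), 1L)
  its1 <- implied_timescales(s, lags = 1, n_timescales = 1, mode = "raw")
  expect_equal(its1$timescale, -1 / log(0.5), tolerance = 1e-6)

  planted <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  true_t2 <- -1 / log(0.7)            # lambda2 = 0.7
  s2 <- sample_markov_chain(planted, 1e5, seed = 3)
  its <- implied_timescales(s2, lags = c(1, 2, 3, 5, 8), n_timescales = 1)
  expect_true(all(its$defined))
  expect_lt(max(abs(its$timescale - true_t2)) / true_t2, 0.05)
  expect_error(implied_timescales(s2, integer(0)), "empty")
})

test_that("chapman-kolmogorov accepts Markov data and rejects lumped chains", {
  planted <- rbind(c(0.95, 0.05), c(0.1, 0.9))
  s <- sample_markov_chain(planted, 1e5, seed = 5)
  ck <- chapman_kolmogorov(s, lag = 2, n_multiples = 5, n_metastates = 2)
  expect_true(attr(ck, "pass"))

  # hide one state of a 3-state chain: states 1 and 2 have very different
  # exit rates toward 3, so the lumped process is strongly non-Markov
  T3 <- rbind(c(0.78, 0.02, 0.20), c(0.02, 0.975, 0.005),
              c(0.15, 0.015, 0.835))
  s3 <- sample_markov_chain(T3, 2e5, seed = 6)
  lumped <- ifelse(s3 == 3L, 2L, 1L)
  ck_bad <- chapman_kolmogorov(lumped, lag = 1, n_multiples = 5,
                               n_metastates = 2)
  expect_false(attr(ck_bad, "pass"))
  expect_gt(max(ck_bad$max_deviation), attr(ck_bad, "tolerance"))
})

test_that("pcca recovers nearly uncoupled blocks crisply", {
  k <- 9
  blocks <- list(1:3, 4:6, 7:9)
  Tm <- matrix(0, k, k)
  for (b in blocks) for (i in b) {
    Tm[i, b] <- 0.98 / 3
    Tm[i, setdiff(1:k, b)] <- 0.02 / 6
  }
  Tm <- Tm / rowSums(Tm)
  model <- msm_from_matrix(Tm)
  part <- pcca_metastates(model, 3)
  expect_equal(rowSums(part$membership), rep(1, k), tolerance = 1e-8)
  expect_true(all(part$membership >= -1e-12 & part$membership <= 1 + 1e-12))
  for (b in blocks)
    expect_length(unique(part$assignment[b]), 1L)
  expect_length(unique(part$assignment[c(1, 4, 7)]), 3L)

  ident <- pcca_metastates(model, k)
  expect_equal(ident$membership, diag(k), tolerance = 1e-12)
})

test_that("mean first passage times match closed form and simulation", {
  # two-state chain with p(source -> sink) = 0.1: geometric mean 10 steps
  m2 <- msm_from_matrix(rbind(c(0.9, 0.1), c(0.3, 0.7)))
  expect_equal(mfpt(m2, 1, 2)$steps, 10, tolerance = 1e-12)
  expect_equal(mfpt(m2, 1, 1)$steps, 0)
  # lag conversion: frames = steps * lag
  m2l <- msm_from_matrix(rbind(c(0.9, 0.1), c(0.3, 0.7)), lag = 4)
  expect_equal(mfpt(m2l, 1, 2)$frames, 40)
  expect_equal(mfpt(m2l, 1, 2, frame_interval = 0.5)$time, 20)

  # three-state linear chain vs a vectorised first-passage simulation
  T3 <- rbind(c(0.9, 0.1, 0), c(0.05, 0.85, 0.1), c(0, 0.1, 0.9))
  m3 <- msm_from_matrix(T3)
  analytic <- mfpt(m3, 1, 3)$steps
  n_traj <- 1e5
  withr::with_seed(42, {
    state <- rep(1L, n_traj)
    steps <- numeric(n_traj)
    alive <- rep(TRUE, n_traj)
    t <- 0L
    cum <- t(apply(T3, 1, cumsum))
    while (any(alive) && t < 1e4) {
      t <- t + 1L
      idx <- which(alive)
      u <- stats::runif(length(idx))
      nxt <- ifelse(u <= cum[state[idx], 1], 1L,
                    ifelse(u <= cum[state[idx], 2], 2L, 3L))
      state[idx] <- nxt
      arrived <- idx[nxt == 3L]
      steps[arrived] <- t
      alive[arrived] <- FALSE
    }
    expect_true(!any(alive))
    expect_lt(abs(mean(steps) - analytic) / analytic, 0.02)
  })

  # unreachable sink
  mu <- msm_from_matrix(rbind(c(1, 0), c(0.5, 0.5)))
  res <- mfpt(mu, 1, 2)
  expect_false(res$reachable)
  expect_identical(res$steps, Inf)
})

test_that("mfpt decreases when the direct escape probability grows", {
  withr::with_seed(77, {
    for (trial in 1:5) {
      # random 4-state chain
      Tm <- matrix(stats::runif(16, 0.05, 1), 4)
      Tm <- Tm / rowSums(Tm)
      base <- mfpt(msm_from_matrix(Tm), 1, 4)$steps
      T2 <- Tm
      boost <- 0.5 * (1 - T2[1, 4])
      T2[1, 4] <- T2[1, 4] + boost
      T2[1, 1:3] <- T2[1, 1:3] * (1 - T2[1, 4]) / sum(T2[1, 1:3])
      faster <- mfpt(msm_from_matrix(T2), 1, 4)$steps
      expect_lte(faster, base + 1e-9)
    }
  })
})

test_that("representative frames sit at metastate centroids with tie rules", {
  # two clean clouds -> two metastates; the representative is the frame
  # nearest each occupancy-weighted centroid (exhaustive oracle)
  withr::with_seed(8, {
    X <- rbind(matrix(stats::rnorm(400, 0, 0.5), ncol = 2),
               matrix(stats::rnorm(400, 8, 0.5), ncol = 2))
    # alternate cloud blocks so transitions run in both directions and the
    # chain over microstates is strongly connected
    X <- X[c(1:100, 201:300, 101:200, 301:400), ]
  })
  lab <- cluster_microstates(X, k = 8, seed = 2)
  model <- estimate_transition_matrix(lab, lag = 1)
  part <- pcca_metastates(model, 2)
  reps <- representative_frames(part, X)
  meta_of <- rep(NA_integer_, model$n_states)
  meta_of[model$active] <- part$assignment
  fm <- meta_of[lab]
  for (m in 1:2) {
    idx <- which(fm == m)
    cen <- colMeans(X[idx, ])
    d <- sqrt(rowSums(sweep(X[idx, ], 2, cen)^2))
    expect_lte(d[match(reps[m], idx)], stats::quantile(d, 0.1))
  }

  # degenerate one-frame metastate and tie-breaking by lowest index
  Xt <- rbind(c(0, 0), c(2, 0), c(-2, 0), c(10, 10))
  labt <- c(1L, 1L, 1L, 2L)
  modelt <- estimate_transition_matrix(list(c(labt, rev(labt))), lag = 1)
  partt <- pcca_metastates(modelt, 2)
  # frames 2 and 3 are equidistant from the centroid of metastate
  # containing frames 1-3; frame 1 sits exactly on it -> frame 1 wins;
  # remove it to expose the tie
  proj <- rbind(c(2, 0), c(1, 0), c(-1, 0), c(10, 10),
                c(10, 10), c(-1, 0), c(1, 0), c(2, 0))
  labs2 <- c(1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L)
  model2 <- estimate_transition_matrix(labs2, lag = 1)
  part2 <- pcca_metastates(model2, 2)
  reps2 <- representative_frames(part2, proj)
  meta1 <- part2$assignment[1]        # metastate of microstate 1
  # centroid of (2,0),(1,0),(-1,0),(-1,0),(1,0),(2,0) is (2/3, 0);
  # frames 2 and 7 tie at distance 1/3 -> the lower index is returned
  expect_equal(reps2[meta1], 2L)
})
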