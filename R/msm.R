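#' K-means microstate clustering with k-means++ seeding
#'
#' Discretises projected trajectory frames (typically PC1/PC2
#' projections) into k microstates. Centers are seeded with the
#' k-means++ scheme under the given seed, then refined by Lloyd
#' iterations (at most `max_iterations`); the whole procedure is
#' deterministic for a fixed seed.
#'
#' @param projections frames x d numeric matrix (a vector is treated as
#'   one column)
#' @param k number of microstates (>= 2)
#' @param max_iterations Lloyd iteration cap (default 100)
#' @param seed integer seed
#' @return integer vector of labels in `1..k` with the fitted centers in
#'   `attr(, "centers")` and the final within-cluster sum of squares in
#'   `attr(, "inertia")`.
#' @export
cluster_microstates <- function(projections, k, max_iterations = 100L, seed = 1L) {
  X <- if (is.null(dim(projections))) matrix(projections, ncol = 1L)
       else as.matrix(projections)
  if (k < 2L) stopf("need at least 2 microstates (k >= 2)")
  n_distinct <- nrow(unique(X))
  if (k > n_distinct)
    stopf("k = %d exceeds the %d distinct points", k, n_distinct)
  centers <- withr::with_seed(seed, kmeanspp_centers(X, k))
  km <- stats::kmeans(X, centers = centers, iter.max = max_iterations,
                      algorithm = "Lloyd")
  structure(as.integer(km$cluster), centers = km$centers,
            inertia = km$tot.withinss)
}

# internal: k-means++ center seeding (Arthur & Vassilvitskii)
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

# internal: transition counts at a lag with the sliding window, never
# across replica boundaries. labels: list of integer vectors.
transition_counts <- function(labels, lag, k) {
  C <- matrix(0, k, k)
  for (s in labels) {
    n <- length(s)
    if (lag >= n) next
    from <- s[seq_len(n - lag)]
    to <- s[seq_len(n - lag) + lag]
    C <- C + matrix(tabulate((to - 1L) * k + from, nbins = k * k), k, k)
  }
  C
}

# internal: largest strongly (mutually) connected state set of a count
# matrix, by total counts
largest_connected_set <- function(C) {
  k <- nrow(C)
  A <- (C > 0) | diag(TRUE, k)
  R <- A
  repeat {                       # boolean transitive closure
    R2 <- (R %*% R) > 0 | R
    if (identical(R2, R)) break
    R <- R2
  }
  comp <- integer(k); cid <- 0L
  for (i in seq_len(k)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[R[i, ] & R[, i]] <- cid
    }
  }
  size <- tapply(rowSums(C) + colSums(C), comp, sum)
  as.integer(which(comp == as.integer(names(size)[which.max(size)])))
}

#' Estimate a Markov state model transition matrix
#'
#' Counts transitions with a sliding window at the given lag (never
#' across replica boundaries), trims states outside the largest
#' mutually-connected set, and row-normalises. In `"symmetrized"` mode
#' (the default) counts are symmetrised first, `(C + C')/2`, which
#' enforces detailed balance by construction; `"raw"` mode keeps the
#' directed counts.
#'
#' @param labels integer vector of microstate labels, or list of vectors
#'   (one per replica)
#' @param lag lag time in frames (>= 1, shorter than every replica)
#' @param mode "symmetrized" (reversible, default) or "raw"
#' @param n_states total number of microstates (default: max label)
#' @return object of class `msm_model`: `transition` (row-stochastic over
#'   active states), `counts`, `active` (microstate ids kept), `trimmed`,
#'   `eigenvalues` (by decreasing modulus), `stationary` (pi, with
#'   `pi %*% T = pi`), `lag`, `mode`.
#' @export
estimate_transition_matrix <- function(labels, lag, mode = c("symmetrized", "raw"),
                                       n_states = NULL) {
  mode <- match.arg(mode)
  if (!is.list(labels)) labels <- list(labels)
  labels <- lapply(labels, as.integer)
  if (lag < 1L) stopf("lag must be >= 1 frame")
  shortest <- min(lengths(labels))
  if (lag >= shortest)
    stopf("lag (%d) must be shorter than the shortest replica (%d frames)",
          lag, shortest)
  k <- if (is.null(n_states)) max(unlist(labels)) else n_states
  C <- transition_counts(labels, lag, k)
  active <- largest_connected_set(C)
  trimmed <- setdiff(seq_len(k), active)
  Ca <- C[active, active, drop = FALSE]
  Cs <- if (mode == "symmetrized") (Ca + t(Ca)) / 2 else Ca
  rs <- rowSums(Cs)
  if (any(rs == 0)) stopf("active set still contains absorbing rows")
  T_ <- Cs / rs
  eg <- eigen(t(T_))
  ord <- order(Mod(eg$values), decreasing = TRUE)
  pi_vec <- Re(eg$vectors[, ord[1]])
  pi_vec <- abs(pi_vec) / sum(abs(pi_vec))
  structure(list(transition = T_, counts = Ca, active = active,
                 trimmed = trimmed, eigenvalues = eg$values[ord],
                 stationary = pi_vec, lag = lag, mode = mode,
                 n_states = k, labels = labels),
            class = "msm_model")
}

#' Build an MSM directly from a transition matrix
#'
#' Wraps an explicit row-stochastic matrix as an `msm_model` (all states
#' active, no counts), e.g. for closed-form kinetics on a known chain.
#'
#' @param transition row-stochastic k x k matrix
#' @param lag lag time in frames the matrix corresponds to (default 1)
#' @return an `msm_model`
#' @export
msm_from_matrix <- function(transition, lag = 1L) {
  T_ <- as.matrix(transition)
  if (any(T_ < 0) || any(abs(rowSums(T_) - 1) > 1e-10))
    stopf("matrix must be row-stochastic with non-negative entries")
  eg <- eigen(t(T_))
  ord <- order(Mod(eg$values), decreasing = TRUE)
  pi_vec <- Re(eg$vectors[, ord[1]])
  pi_vec <- abs(pi_vec) / sum(abs(pi_vec))
  structure(list(transition = T_, counts = NULL,
                 active = seq_len(nrow(T_)), trimmed = integer(0),
                 eigenvalues = eg$values[ord], stationary = pi_vec,
                 lag = as.integer(lag), mode = "explicit",
                 n_states = nrow(T_), labels = NULL),
            class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("<msm_model> %d active states (of %d), lag %d frames, %s counts\n",
              nrow(x$transition), x$n_states, x$lag, x$mode))
  invisible(x)
}

#' Implied timescale table
#'
#' For each lag, estimates a transition matrix and reports
#' `t_i = -lag / ln|lambda_i|` for the non-stationary eigenvalues
#' (i >= 2), in frame units. Lag-independence of these timescales is the
#' standard evidence of Markovianity. Eigenvalues with `|lambda| >= 1`
#' yield an infinite timescale, reported as `Inf` with `defined = FALSE`;
#' non-positive real eigenvalues close to 0 give timescales below the lag
#' and are kept as-is.
#'
#' @param labels labels (vector or list of replicas)
#' @param lags integer vector of lags (frames)
#' @param n_timescales number of timescales per lag (default 3)
#' @param mode estimation mode, see [estimate_transition_matrix()]
#' @return data.frame: `lag`, `index` (2 = slowest), `timescale`
#'   (frames), `defined`.
#' @export
implied_timescales <- function(labels, lags, n_timescales = 3L,
                               mode = "symmetrized") {
  if (length(lags) == 0L) stopf("empty lag list")
  rows <- list()
  for (lag in lags) {
    m <- estimate_transition_matrix(labels, lag, mode = mode)
    lam <- Mod(m$eigenvalues)
    for (i in seq_len(min(n_timescales, length(lam) - 1L))) {
      l <- lam[i + 1L]
      if (l >= 1) {
        ts <- Inf; def <- FALSE
      } else if (l <= 0) {
        ts <- NA_real_; def <- FALSE
      } else {
        ts <- -lag / log(l); def <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lag = lag, index = i + 1L, timescale = ts, defined = def)
    }
  }
  do.call(rbind, rows)
}

#' PCCA+ metastable coarse-graining
#'
#' Assigns kinetically similar microstates to `n_metastates` fuzzy
#' metastable sets from the sign structure of the dominant eigenvectors
#' of the transition matrix, using simplex-vertex seeding: the rows of
#' the dominant-eigenvector matrix most distant from each other span the
#' membership simplex, and every microstate's membership is its
#' barycentric coordinate (clipped to `[0, 1]`, rows renormalised).
#'
#' @param msm_model an [estimate_transition_matrix()] result with an
#'   irreducible transition matrix
#' @param n_metastates number of metastable sets (>= 2; should not exceed
#'   the count of eigenvalues near 1)
#' @return object of class `metastable_partition`: `membership`
#'   (microstates x metastates, rows sum to 1), `assignment` (crisp
#'   argmax), `coarse_transition` (stationary-weighted projection of T).
#' @export
pcca_metastates <- function(msm_model, n_metastates) {
  T_ <- msm_model$transition
  k <- nrow(T_)
  if (n_metastates < 1L || n_metastates > k)
    stopf("n_metastates must lie in 1..%d", k)
  if (length(msm_model$trimmed) > 0 && any(msm_model$counts == 0)) {
    # irreducibility within the active set is guaranteed by trimming;
    # a fully reducible input would have been rejected there
  }
  if (n_metastates == k) {
    M <- diag(1, k)
  } else {
    pi_v <- msm_model$stationary
    # symmetrise in the pi inner product for stable real eigenvectors
    S <- diag(sqrt(pi_v)) %*% T_ %*% diag(1 / sqrt(pi_v))
    S <- (S + t(S)) / 2
    eg <- eigen(S, symmetric = TRUE)
    X <- diag(1 / sqrt(pi_v)) %*% eg$vectors[, seq_len(n_metastates), drop = FALSE]
    X[, 1] <- 1                       # the stationary eigenvector is constant
    # simplex-vertex seeding: greedily pick the most mutually distant rows
    verts <- integer(n_metastates)
    verts[1] <- which.max(rowSums(X^2))
    Y <- X
    for (j in 2:n_metastates) {
      v <- Y[verts[j - 1L], ]
      # deflate the direction of the last vertex
      nv <- sqrt(sum(v^2))
      if (nv > 0) Y <- Y - (Y %*% v / nv) %*% t(v / nv)
      d <- rowSums(Y^2)
      d[verts[seq_len(j - 1L)]] <- -Inf
      verts[j] <- which.max(d)
    }
    A <- tryCatch(solve(X[verts, , drop = FALSE]),
                  error = function(e) stopf("degenerate eigenvector simplex; reduce n_metastates"))
    M <- X %*% A
    M[M < 0] <- 0
    rs <- rowSums(M)
    rs[rs == 0] <- 1
    M <- M / rs
  }
  assignment <- max.col(M, ties.method = "first")
  # stationary-weighted coarse transition matrix
  pi_v <- msm_model$stationary
  W <- t(M * pi_v)                    # metastates x microstates
  Tc <- (W %*% T_ %*% M) / rowSums(W)
  structure(list(membership = M, assignment = assignment,
                 coarse_transition = Tc, n_metastates = n_metastates,
                 msm = msm_model),
            class = "metastable_partition")
}

#' @export
print.metastable_partition <- function(x, ...) {
  cat(sprintf("<metastable_partition> %d microstates -> %d metastates (sizes: %s)\n",
              nrow(x$membership), x$n_metastates,
              paste(tabulate(x$assignment, x$n_metastates), collapse = ", ")))
  invisible(x)
}

#' Chapman-Kolmogorov test
#'
#' Coarse-grains the microstate labels into metastates (crisp PCCA+
#' assignment), estimates the metastate transition matrix at the base lag
#' and compares its matrix powers `T(lag)^n` against matrices estimated
#' directly at lag `n * lag`, for `n = 1..n_multiples`. The reported
#' statistic per multiple is the maximum absolute deviation of the
#' metastate self-transition probabilities; Markovian dynamics keep it
#' within sampling error while hidden (lumped) slow states violate it.
#'
#' @param labels labels (vector or list of replicas)
#' @param lag base lag (frames)
#' @param n_multiples largest multiple tested (default 5)
#' @param n_metastates metastates used for the comparison (default 2)
#' @param tolerance pass/fail threshold on the deviation (default 0.05)
#' @param mode estimation mode
#' @return data.frame `multiple`, `max_deviation`, `pass`; the overall
#'   verdict is `attr(, "pass")`, truncated multiples (lag beyond a
#'   replica) are dropped with a warning.
#' @export
chapman_kolmogorov <- function(labels, lag, n_multiples = 5L, n_metastates = 2L,
                               tolerance = 0.05, mode = "symmetrized") {
  if (!is.list(labels)) labels <- list(labels)
  base <- estimate_transition_matrix(labels, lag, mode = mode)
  part <- pcca_metastates(base, n_metastates)
  # map microstates -> metastates; trimmed microstates get the nearest
  # metastate by membership of the closest active state (rare; drop frames)
  meta_of <- rep(NA_integer_, base$n_states)
  meta_of[base$active] <- part$assignment
  meta_labels <- lapply(labels, function(s) {
    m <- meta_of[s]
    m[!is.na(m)]
  })
  shortest <- min(lengths(meta_labels))
  usable <- seq_len(n_multiples)
  if (lag * n_multiples >= shortest) {
    usable <- usable[lag * usable < shortest]
    warnf("multiples beyond %d exceed the replica length; truncated",
          max(usable))
  }
  Tm1 <- estimate_transition_matrix(meta_labels, lag, mode = mode,
                                    n_states = n_metastates)$transition
  rows <- lapply(usable, function(n) {
    pred <- matpow(Tm1, n)
    est <- estimate_transition_matrix(meta_labels, lag * n, mode = mode,
                                      n_states = n_metastates)$transition
    dev <- max(abs(diag(pred) - diag(est)))
    data.frame(multiple = n, max_deviation = dev, pass = dev <= tolerance)
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  attr(out, "tolerance") <- tolerance
  out
}

# internal: integer matrix power
matpow <- function(M, n) {
  R <- diag(1, nrow(M))
  P <- M
  while (n > 0) {
    if (n %% 2 == 1) R <- R %*% P
    P <- P %*% P
    n <- n %/% 2
  }
  R
}

#' Mean first passage time between state sets
#'
#' Solves the linear system `m = 1 + T[ns, ns] m` over the non-sink
#' states (the sink set made absorbing) and returns the
#' stationary-weighted mean over the source set. Times are in chain
#' steps (multiples of the model's lag); frame and physical conversions
#' are included when available.
#'
#' @param msm_model an `msm_model`
#' @param source_states,sink_states integer vectors of active-state
#'   indices (positions in the model's transition matrix)
#' @param frame_interval optional ps per frame for the physical time
#' @return list: `steps` (lag units), `frames`, `time` (ps or NA),
#'   `reachable` (FALSE when the sink cannot be reached; `steps = Inf`).
#' @export
mfpt <- function(msm_model, source_states, sink_states,
                 frame_interval = NULL) {
  T_ <- msm_model$transition
  k <- nrow(T_)
  src <- unique(as.integer(source_states))
  snk <- unique(as.integer(sink_states))
  if (any(c(src, snk) < 1L) || any(c(src, snk) > k))
    stopf("state indices out of range 1..%d", k)
  if (all(src %in% snk))
    return(list(steps = 0, frames = 0,
                time = if (is.null(frame_interval)) NA_real_ else 0,
                reachable = TRUE))
  ns <- setdiff(seq_len(k), snk)
  A <- diag(1, length(ns)) - T_[ns, ns, drop = FALSE]
  m <- tryCatch(solve(A, rep(1, length(ns))), error = function(e) NULL)
  if (is.null(m) || any(!is.finite(m)) || any(m < 0)) {
    return(list(steps = Inf, frames = Inf, time = NA_real_, reachable = FALSE))
  }
  full <- numeric(k)
  full[ns] <- m
  pi_v <- msm_model$stationary[src]
  if (sum(pi_v) <= 0) pi_v <- rep(1, length(src))
  steps <- sum(full[src] * pi_v) / sum(pi_v)
  frames <- steps * msm_model$lag
  list(steps = steps, frames = frames,
       time = if (is.null(frame_interval)) NA_real_
              else frames * frame_interval,
       reachable = TRUE)
}

#' Representative frame of each metastable state
#'
#' For every metastate, returns the frame whose projection lies closest
#' to the metastate's occupancy-weighted centroid in projection space;
#' ties are broken by the lowest frame index. Metastates left empty after
#' ergodic trimming are reported as `NA` with a warning.
#'
#' @param partition a [pcca_metastates()] result
#' @param projections frames x d projection matrix (frames concatenated
#'   in the same order as the labels the model was built from)
#' @return integer vector, one frame index per metastate (NA = empty).
#' @export
representative_frames <- function(partition, projections) {
  X <- if (is.null(dim(projections))) matrix(projections, ncol = 1L)
       else as.matrix(projections)
  model <- partition$msm
  lab <- unlist(model$labels)
  if (length(lab) != nrow(X))
    stopf("projections (%d frames) do not match the model's labels (%d)",
          nrow(X), length(lab))
  meta_of <- rep(NA_integer_, model$n_states)
  meta_of[model$active] <- partition$assignment
  frame_meta <- meta_of[lab]
  out <- rep(NA_integer_, partition$n_metastates)
  for (m in seq_len(partition$n_metastates)) {
    idx <- which(frame_meta == m)
    if (length(idx) == 0L) {
      warnf("metastate %d has no frames after trimming", m)
      next
    }
    cen <- colMeans(X[idx, , drop = FALSE])
    d2 <- rowSums(sweep(X[idx, , drop = FALSE], 2, cen)^2)
    out[m] <- idx[which.min(d2)]   # which.min returns the first minimum
  }
  out
}
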