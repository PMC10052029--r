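test_that("contact edges honour cutoff, occupancy and the boundary rule", {
  top <- bead_topology(4)
  near <- rbind(c(0, 0, 0), c(20, 0, 0), c(4, 0, 0), c(60, 0, 0))
  far <- near; far[3, ] <- c(9, 0, 0)

  always <- traj_from_frames(rep(list(near), 8), top)
  e <- contact_edges(always, cutoff = 4.5, occupancy = 0.75)
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$resid_i, e$resid_j), c(1L, 3L))

  half <- traj_from_frames(c(rep(list(near), 4), rep(list(far), 4)), top)
  expect_equal(nrow(contact_edges(half, occupancy = 0.75)), 0L)
  # occupancy exactly at the threshold is kept (>= semantics)
  three_q <- traj_from_frames(c(rep(list(near), 6), rep(list(far), 2)), top)
  expect_equal(nrow(contact_edges(three_q, occupancy = 0.75)), 1L)

  # sequence-adjacent pairs are excluded by default
  chainlike <- rbind(c(0, 0, 0), c(3, 0, 0), c(300, 0, 0), c(600, 0, 0))
  tc <- traj_from_frames(rep(list(chainlike), 3), top)
  expect_equal(nrow(contact_edges(tc)), 0L)
  expect_equal(nrow(contact_edges(tc, neighbor_offset = 1L)), 1L)

  expect_error(contact_edges(always, cutoff = -1), "cutoff")
  expect_error(contact_edges(always, occupancy = 0), "occupancy")
})

test_that("edge weights follow -ln|C| with clamping", {
  edges <- data.frame(resid_i = c(1, 1, 2), resid_j = c(2, 3, 3))
  C <- uniform_cor(1:3)
  M <- unclass(C)
  M[1, 2] <- M[2, 1] <- 1
  M[1, 3] <- M[3, 1] <- 0.1
  M[2, 3] <- M[3, 2] <- 1e-9
  C <- structure(M, class = c("correlation_matrix", "matrix"))
  g <- weight_edges(edges, C)
  expect_equal(g$edges$weight[1], 0)
  expect_equal(g$edges$weight[2], 2.302585, tolerance = 1e-6)
  expect_equal(g$edges$weight[3], -log(1e-6))
  expect_true(g$edges$clamped[3])
  expect_false(any(g$edges$clamped[1:2]))

  bad <- data.frame(resid_i = 1, resid_j = 99)
  expect_error(weight_edges(bad, C), "absent")
})

test_that("edge betweenness matches the brute-force shortest-path oracle", {
  withr::with_seed(55, {
    for (trial in 1:40) {
      n <- sample(4:12, 1)
      em <- t(utils::combn(n, 2))
      keep <- stats::runif(nrow(em)) < 0.4
      if (sum(keep) < 3) next
      em <- em[keep, , drop = FALSE]
      ed <- data.frame(resid_i = em[, 1], resid_j = em[, 2],
                       weight = stats::runif(nrow(em), 0.1, 2))
      mine <- kindyn:::edge_betweenness_impl(seq_len(n), ed)
      oracle <- fw_edge_betweenness(seq_len(n), ed)
      expect_equal(mine, oracle, tolerance = 1e-8)
    }
  })
})

test_that("edge betweenness agrees with igraph on weighted graphs", {
  skip_if_not_installed("igraph")
  withr::with_seed(66, {
    for (trial in 1:10) {
      n <- sample(5:12, 1)
      em <- t(utils::combn(n, 2))
      em <- em[stats::runif(nrow(em)) < 0.35, , drop = FALSE]
      if (nrow(em) < 3) next
      w <- stats::runif(nrow(em), 0.2, 2)
      ed <- data.frame(resid_i = em[, 1], resid_j = em[, 2], weight = w)
      mine <- kindyn:::edge_betweenness_impl(seq_len(n), ed)
      g <- igraph::graph_from_edgelist(em, directed = FALSE)
      expect_equal(mine, igraph::edge_betweenness(g, weights = w),
                   tolerance = 1e-8)
    }
  })
})

test_that("two bridged cliques split into two communities and one pathway", {
  edges <- rbind(clique_edges(1:5), clique_edges(6:10),
                 data.frame(resid_i = 5, resid_j = 6))
  g <- weight_edges(edges, uniform_cor(1:10))
  part <- girvan_newman_communities(g)
  expect_length(part$sizes, 2L)
  expect_equal(sort(part$sizes), c(5L, 5L))
  expect_length(unique(part$membership[as.character(1:5)]), 1L)
  expect_length(unique(part$membership[as.character(6:10)]), 1L)

  st <- intercommunity_strengths(g, part)
  expect_equal(nrow(st), 1L)
  # the bridge carries every cross-clique shortest path: betweenness 25
  expect_equal(st$strength, 25)
  expect_equal(network_summary(part, st),
               list(n_communities = 2L, n_pathways = 1L))
})

test_that("single cliques and pendant pairs follow the pruning rule", {
  g1 <- weight_edges(clique_edges(1:6), uniform_cor(1:6))
  p1 <- girvan_newman_communities(g1)
  expect_length(p1$sizes, 1L)
  expect_equal(network_summary(p1, residue_graph = g1),
               list(n_communities = 1L, n_pathways = 0L))

  # a clique plus a 2-node pendant pair: the pair is dropped as < 3 residues
  edges <- rbind(clique_edges(1:5), data.frame(resid_i = 8, resid_j = 9))
  g2 <- weight_edges(edges, uniform_cor(c(1:5, 8:9)))
  p2 <- girvan_newman_communities(g2)
  expect_length(p2$sizes, 1L)
  expect_setequal(p2$unassigned, c(8, 9))

  empty <- weight_edges(data.frame(resid_i = integer(0), resid_j = integer(0)),
                        uniform_cor(1:3))
  pe <- girvan_newman_communities(empty)
  expect_length(pe$sizes, 0L)
  expect_equal(network_summary(pe, residue_graph = empty)$n_communities, 0L)
})

test_that("splitting a bridge into parallel edges conserves the total flow", {
  edges <- rbind(clique_edges(1:5), clique_edges(6:10),
                 data.frame(resid_i = 5, resid_j = 6))
  g1 <- weight_edges(edges, uniform_cor(1:10))
  bt1 <- kindyn:::edge_betweenness_impl(g1$nodes, g1$edges)
  bridge1 <- bt1[nrow(g1$edges)]

  doubled <- rbind(edges, data.frame(resid_i = 5, resid_j = 6))
  g2 <- weight_edges(doubled, uniform_cor(1:10))
  bt2 <- kindyn:::edge_betweenness_impl(g2$nodes, g2$edges)
  two_bridges <- bt2[c(nrow(edges), nrow(doubled))]
  expect_equal(sum(two_bridges), bridge1, tolerance = 1e-8)
  expect_equal(two_bridges[1], two_bridges[2], tolerance = 1e-8)
})

test_that("community detection is invariant under node relabeling", {
  edges <- rbind(clique_edges(1:4), clique_edges(5:8),
                 data.frame(resid_i = 4, resid_j = 5))
  g <- weight_edges(edges, uniform_cor(1:8))
  p <- girvan_newman_communities(g)

  # permute the labels: i -> 21 - i preserves the structure
  pedges <- data.frame(resid_i = pmin(21 - edges$resid_i, 21 - edges$resid_j),
                       resid_j = pmax(21 - edges$resid_i, 21 - edges$resid_j))
  gp <- weight_edges(pedges, uniform_cor(13:20))
  pp <- girvan_newman_communities(gp)
  expect_equal(sort(pp$sizes), sort(p$sizes))
  # community of node i maps to community of node 21 - i
  for (i in 1:8) {
    same_orig <- which(p$membership == p$membership[as.character(i)])
    mapped <- sort(21 - as.integer(names(p$membership)[same_orig]))
    same_perm <- sort(as.integer(names(pp$membership)[
      pp$membership == pp$membership[as.character(21 - i)]]))
    expect_equal(mapped, same_perm)
  }
})

test_that("planted correlated blocks with proximity are recovered as communities", {
  # two parallel 8-bead strands: dense contacts within each strand, a few
  # weakly correlated rungs between them
  n <- 16
  top <- bead_topology(n)
  base <- rbind(cbind(0, 1.4 * (0:7), 0),
                cbind(4.35, 1.4 * (0:7) + 7, 0))
  withr::with_seed(3, base <- base + matrix(stats::rnorm(3 * n, sd = 0.03),
                                            n, 3))
  traj <- traj_from_frames(rep(list(base), 4), top)
  edges <- contact_edges(traj, cutoff = 4.5, occupancy = 0.75,
                         neighbor_offset = 2L)
  pc <- planted_covariance(list(1:8, 9:16), intra = 0.85, inter = 0.1,
                           amplitude = 0.3)
  sim <- sample_correlated_displacements(pc, 3000, seed = 12)
  C <- dccm(sim$trajectory, selection = sim$residue_atoms,
            fit_selection = sim$anchor_atoms)
  g <- weight_edges(edges, C)
  part <- girvan_newman_communities(g)
  # the two planted blocks dominate two communities with >= 90% agreement
  lab <- part$membership[as.character(1:n)]
  block <- rep(1:2, each = 8)
  tab <- table(block, lab, useNA = "no")
  agreement <- sum(apply(tab, 1, max)) / sum(!is.na(lab))
  expect_gte(agreement, 0.9)
})

test_that("network json export writes nodes and weighted edges", {
  edges <- rbind(clique_edges(1:4), data.frame(resid_i = 4, resid_j = 5),
                 clique_edges(5:8))
  g <- weight_edges(edges, uniform_cor(1:8))
  part <- girvan_newman_communities(g)
  f <- withr::local_tempfile(fileext = ".json")
  write_network_json(g, part, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(obj$nodes), 8L)
  expect_equal(nrow(obj$edges), nrow(edges))
  expect_true(all(c("weight", "betweenness") %in% names(obj$edges)))
})
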