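#' Residue contact edges from a trajectory
#'
#' A residue pair becomes an edge when its minimum heavy-atom distance is
#' within the cutoff for at least the given fraction of frames.
#' Sequence-adjacent pairs (|i - j| below `neighbor_offset`) are excluded,
#' the standard convention for dynamical networks whose alpha-carbons act
#' as nodes. `mode = "calpha"` measures alpha-carbon distances instead of
#' minimum heavy-atom distances.
#'
#' @param traj a [trajectory()]
#' @param cutoff contact distance (A, default 4.5)
#' @param occupancy minimum fraction of frames in contact (default 0.75;
#'   a pair exactly at the threshold is kept)
#' @param neighbor_offset minimum |i - j| residue separation (default 2,
#'   i.e. adjacent pairs dropped)
#' @param include_ligand include ligand residues as nodes (default FALSE)
#' @param mode "heavy" (default) or "calpha"
#' @return data.frame `resid_i`, `resid_j`, `occupancy` with
#'   `resid_i < resid_j`.
#' @export
contact_edges <- function(traj, cutoff = 4.5, occupancy = 0.75,
                          neighbor_offset = 2L, include_ligand = FALSE,
                          mode = c("heavy", "calpha")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stopf("cutoff must be > 0")
  if (occupancy <= 0 || occupancy > 1) stopf("occupancy must lie in (0, 1]")
  top <- traj$topology
  res <- residues(top)
  if (!include_ligand) res <- res[!res$is_ligand, , drop = FALSE]
  atom_sets <- lapply(seq_len(nrow(res)), function(r) {
    idx <- res$first_atom[r] + seq_len(res$n_atoms[r]) - 1L
    if (mode == "calpha") {
      ca <- idx[top$name[idx] == "CA"]
      if (length(ca) > 0) ca else idx
    } else idx[top$elem[idx] != "H"]
  })
  nr <- nrow(res)
  nf <- n_frames(traj)
  pair <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
  keep_pair <- abs(res$resid[pair[, 1]] - res$resid[pair[, 2]]) >= neighbor_offset |
    res$chain[pair[, 1]] != res$chain[pair[, 2]]
  pair <- pair[keep_pair, , drop = FALSE]
  hits <- numeric(nrow(pair))
  for (m in seq_len(nf)) {
    fr <- frame_coords(traj, m)
    for (p in seq_len(nrow(pair))) {
      A <- fr[atom_sets[[pair[p, 1]]], , drop = FALSE]
      B <- fr[atom_sets[[pair[p, 2]]], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      if (min(d2) <= cutoff^2) hits[p] <- hits[p] + 1
    }
  }
  occ <- hits / nf
  sel <- occ >= occupancy
  data.frame(resid_i = res$resid[pair[sel, 1]],
             resid_j = res$resid[pair[sel, 2]],
             occupancy = occ[sel])
}

#' Correlation-weighted residue graph
#'
#' Turns contact edges into a weighted graph with distances
#' `d_ij = -ln |C_ij|` (natural log): perfectly correlated residues are
#' at distance 0, weak correlations are far apart. `|C_ij|` is clamped to
#' `[eps, 1]` (eps = 1e-6) to avoid infinite distances; clamped edges are
#' flagged.
#'
#' @param edges data.frame from [contact_edges()] (`resid_i`, `resid_j`)
#' @param correlation_matrix a `correlation_matrix` whose dimnames cover
#'   every residue referenced by the edges
#' @param eps clamp floor for `|C|` (default 1e-6)
#' @return object of class `residue_graph`: `nodes` (residue ids),
#'   `edges` (data.frame with `weight = -ln|C|`, `abs_cor`, `clamped`).
#' @export
weight_edges <- function(edges, correlation_matrix, eps = 1e-6) {
  ids <- rownames(correlation_matrix)
  ei <- as.character(edges$resid_i); ej <- as.character(edges$resid_j)
  miss <- setdiff(unique(c(ei, ej)), ids)
  if (length(miss) > 0)
    stopf("edge residue(s) absent from the correlation matrix: %s",
          paste(miss, collapse = ", "))
  cor_ij <- unclass(correlation_matrix)[cbind(match(ei, ids), match(ej, ids))]
  a <- abs(cor_ij)
  clamped <- is.na(a) | a < eps
  a <- pmin(pmax(ifelse(is.na(a), eps, a), eps), 1)
  ed <- data.frame(resid_i = edges$resid_i, resid_j = edges$resid_j,
                   weight = -log(a), abs_cor = a, clamped = clamped)
  nodes <- sort(unique(c(edges$resid_i, edges$resid_j)))
  structure(list(nodes = nodes, edges = ed), class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

# internal: weighted edge betweenness (Brandes' algorithm with Dijkstra).
# nodes: vector of node ids; edges: data.frame resid_i/resid_j/weight.
# Returns per-edge betweenness counting each unordered source-target pair
# once. Edge weights are shortest-path lengths (>= 0).
edge_betweenness_impl <- function(nodes, edges, tol = 1e-9) {
  n <- length(nodes)
  m <- nrow(edges)
  bt <- numeric(m)
  if (n == 0L || m == 0L) return(bt)
  ii <- match(edges$resid_i, nodes); jj <- match(edges$resid_j, nodes)
  adj <- vector("list", n)          # per node: matrix of (neighbor, edge, w)
  for (e in seq_len(m)) {
    adj[[ii[e]]] <- rbind(adj[[ii[e]]], c(jj[e], e, edges$weight[e]))
    adj[[jj[e]]] <- rbind(adj[[jj[e]]], c(ii[e], e, edges$weight[e]))
  }
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)      # predecessor edge list per node
    done <- rep(FALSE, n)
    order_out <- integer(0)
    repeat {                        # Dijkstra (dense; graphs are small)
      u <- which(!done & is.finite(dist))
      if (length(u) == 0L) break
      u <- u[which.min(dist[u])]
      done[u] <- TRUE
      order_out <- c(order_out, u)
      nb <- adj[[u]]
      if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; e <- nb[r, 2]; w <- nb[r, 3]
        alt <- dist[u] + w
        if (alt < dist[v] - tol) {
          dist[v] <- alt
          sigma[v] <- sigma[u]
          preds[[v]] <- c(e)
        } else if (abs(alt - dist[v]) <= tol && !done[v]) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], e)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order_out)) {
      for (e in preds[[v]]) {
        u <- if (abs(dist[ii[e]] + edges$weight[e] - dist[v]) <= tol &&
                 ii[e] != v) ii[e] else jj[e]
        contrib <- sigma[u] / sigma[v] * (1 + delta[v])
        bt[e] <- bt[e] + contrib
        delta[u] <- delta[u] + contrib
      }
    }
  }
  bt / 2                            # each unordered pair counted twice
}

# internal: unweighted Newman-Girvan modularity of a partition, on the
# original edge set
modularity_score <- function(nodes, edges, membership) {
  m <- nrow(edges)
  if (m == 0L) return(0)
  ci <- membership[match(edges$resid_i, nodes)]
  cj <- membership[match(edges$resid_j, nodes)]
  deg <- tabulate(c(match(edges$resid_i, nodes), match(edges$resid_j, nodes)),
                  nbins = length(nodes))
  q <- 0
  for (c in unique(membership)) {
    e_c <- sum(ci == c & cj == c)
    d_c <- sum(deg[membership == c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# internal: connected-component labels (union-find)
components_of <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nx <- parent[x]; parent[x] <<- root; x <- nx }
    root
  }
  for (e in seq_along(i)) {
    a <- find(i[e]); b <- find(j[e])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Girvan-Newman community detection on a residue graph
#'
#' Iteratively removes the edge of highest weighted betweenness
#' (shortest paths under the `-ln|C|` distances; ties broken by the
#' lexicographically smallest residue-id pair), tracking the unweighted
#' modularity of every intermediate component partition, and returns the
#' partition of maximum modularity. Communities with fewer than
#' `min_size` residues are then dropped; their nodes are reported as
#' unassigned.
#'
#' @param residue_graph a [weight_edges()] result
#' @param min_size smallest reported community (default 3)
#' @return object of class `community_partition`: `membership` (named by
#'   residue id; `NA` = unassigned), `sizes`, `modularity`, `unassigned`.
#' @export
girvan_newman_communities <- function(residue_graph, min_size = 3L) {
  nodes <- residue_graph$nodes
  edges <- residue_graph$edges
  n <- length(nodes)
  if (n == 0L) {
    return(structure(list(membership = integer(0), sizes = integer(0),
                          modularity = NA_real_, unassigned = integer(0),
                          graph = residue_graph),
                     class = "community_partition"))
  }
  work <- edges
  best_q <- -Inf
  best_member <- components_of(n, match(edges$resid_i, nodes),
                               match(edges$resid_j, nodes))
  q0 <- modularity_score(nodes, edges, best_member)
  if (q0 > best_q) { best_q <- q0 }
  while (nrow(work) > 0L) {
    bt <- edge_betweenness_impl(nodes, work)
    mx <- max(bt)
    cand <- which(bt >= mx - 1e-12)
    if (length(cand) > 1L) {        # lexicographic tie rule
      ord <- order(work$resid_i[cand], work$resid_j[cand])
      cand <- cand[ord[1]]
    }
    work <- work[-cand, , drop = FALSE]
    member <- components_of(n, match(work$resid_i, nodes),
                            match(work$resid_j, nodes))
    q <- modularity_score(nodes, edges, member)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_member <- member
    }
  }
  sizes <- tabulate(best_member)
  keep <- which(sizes >= min_size)
  membership <- ifelse(best_member %in% keep,
                       match(best_member, keep), NA_integer_)
  names(membership) <- as.character(nodes)
  structure(list(membership = membership,
                 sizes = tabulate(membership[!is.na(membership)]),
                 modularity = best_q,
                 unassigned = nodes[is.na(membership)],
                 graph = residue_graph),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities (sizes: %s), %d unassigned, Q = %.3f\n",
              length(x$sizes), paste(x$sizes, collapse = ", "),
              length(x$unassigned), x$modularity))
  invisible(x)
}

#' Intercommunity connection strengths
#'
#' The strength of a community pair is the summed weighted edge
#' betweenness — computed on the full graph — of the edges spanning the
#' two communities, the conventional proxy for the signal flow carried by
#' that intercommunity connection. Pairs without spanning edges are
#' absent.
#'
#' @param residue_graph the full [weight_edges()] graph
#' @param partition a [girvan_newman_communities()] result on the same
#'   node set
#' @return data.frame `community_a`, `community_b`, `strength`, `n_edges`
#' @export
intercommunity_strengths <- function(residue_graph, partition) {
  nodes <- residue_graph$nodes
  if (length(nodes) == 0L && length(partition$membership) == 0L)
    return(data.frame(community_a = integer(0), community_b = integer(0),
                      strength = numeric(0), n_edges = integer(0)))
  if (!identical(as.character(nodes), names(partition$membership)))
    stopf("partition and graph node sets disagree")
  edges <- residue_graph$edges
  if (nrow(edges) == 0L)
    return(data.frame(community_a = integer(0), community_b = integer(0),
                      strength = numeric(0), n_edges = integer(0)))
  bt <- edge_betweenness_impl(nodes, edges)
  ca <- partition$membership[as.character(edges$resid_i)]
  cb <- partition$membership[as.character(edges$resid_j)]
  span <- !is.na(ca) & !is.na(cb) & ca != cb
  if (!any(span))
    return(data.frame(community_a = integer(0), community_b = integer(0),
                      strength = numeric(0), n_edges = integer(0)))
  lo <- pmin(ca[span], cb[span]); hi <- pmax(ca[span], cb[span])
  key <- paste(lo, hi)
  agg_s <- tapply(bt[span], key, sum)
  agg_n <- tapply(bt[span], key, length)
  parts <- do.call(rbind, strsplit(names(agg_s), " "))
  out <- data.frame(community_a = as.integer(parts[, 1]),
                    community_b = as.integer(parts[, 2]),
                    strength = as.numeric(agg_s),
                    n_edges = as.integer(agg_n))
  out[order(out$community_a, out$community_b), , drop = FALSE]
}

#' Community and pathway counts of a partition
#'
#' @param partition a [girvan_newman_communities()] result
#' @param strengths optional precomputed [intercommunity_strengths()]
#' @param residue_graph required when `strengths` is missing
#' @return list(n_communities, n_pathways)
#' @export
network_summary <- function(partition, strengths = NULL, residue_graph = NULL) {
  if (is.null(strengths)) {
    if (is.null(residue_graph)) residue_graph <- partition$graph
    strengths <- intercommunity_strengths(residue_graph, partition)
  }
  list(n_communities = length(partition$sizes),
       n_pathways = nrow(strengths))
}

#' Export a residue graph with its partition as JSON
#'
#' Nodes carry their community id; edges carry weight and betweenness.
#' @param residue_graph a `residue_graph`
#' @param partition a `community_partition`
#' @param path output JSON file
#' @export
write_network_json <- function(residue_graph, partition, path) {
  bt <- edge_betweenness_impl(residue_graph$nodes, residue_graph$edges)
  obj <- list(
    nodes = data.frame(resid = residue_graph$nodes,
                       community = as.integer(partition$membership)),
    edges = cbind(residue_graph$edges, betweenness = bt))
  jsonlite::write_json(obj, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
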