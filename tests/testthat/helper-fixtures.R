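# Shared fixture builders and independent oracles for the test suite.

# Four-group null configuration at desk scale (direct connectivity mode).
null_config <- function(seed, n_per_group = 12, n_regions = 20,
                        bands = default_bands()["theta"]) {
  simulation_config(
    group_sizes = c(female_PD = n_per_group, male_PD = n_per_group,
                    female_HC = n_per_group, male_HC = n_per_group),
    n_regions = n_regions, bands = bands, seed = seed)
}

# A 10-edge star component planted on regions 1..11 (hub at region 1).
# A star stays connected when any single edge drops below threshold,
# making recovery reflect edge-level detection rather than the fragility
# of a chain.
planted_star_edges <- function() cbind(1, 2:11)

# Tiny bundle with explicitly chosen edge values for one band.
toy_bundle <- function(edge_values_by_subject, n_regions) {
  ns <- nrow(edge_values_by_subject)
  a <- array(0, c(n_regions, n_regions, ns))
  for (s in seq_len(ns)) {
    m <- matrix(0, n_regions, n_regions)
    m[upper.tri(m)] <- edge_values_by_subject[s, ]
    a[, , s] <- m + t(m)
  }
  fc_bundle(list(theta = a), sprintf("s%02d", seq_len(ns)))
}

# Independent component oracle: breadth-first search over an edge list,
# returning the multiset of component edge counts (sorted decreasing).
bfs_component_sizes <- function(edges, n_nodes) {
  if (nrow(edges) == 0L) return(integer(0))
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n_nodes)
  sizes <- integer(0)
  for (start in unique(as.vector(edges))) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
          members <- c(members, u)
        }
      }
    }
    in_comp <- edges[, 1] %in% members & edges[, 2] %in% members
    sizes <- c(sizes, sum(in_comp))
  }
  sort(sizes, decreasing = TRUE)
}

# Naive per-pair per-window wPLI oracle, written independently of the
# vectorized implementation.
naive_wpli <- function(analytic, fs, spec) {
  n_reg <- nrow(analytic)
  w <- round(spec$window_s * fs)
  step <- round(w * (1 - spec$overlap))
  starts <- seq(1, ncol(analytic) - w + 1, by = step)
  out <- array(0, c(n_reg, n_reg, length(starts)))
  for (k in seq_along(starts)) {
    sel <- starts[k]:(starts[k] + w - 1)
    for (i in 1:(n_reg - 1)) {
      for (j in (i + 1):n_reg) {
        im <- Im(analytic[i, sel] * Conj(analytic[j, sel]))
        den <- mean(abs(im))
        v <- if (den < 1e-12) 0 else abs(mean(im)) / den
        out[i, j, k] <- v
        out[j, i, k] <- v
      }
    }
  }
  out
}

# Jaccard overlap between two edge sets given as two-column matrices.
edge_jaccard <- function(a, b) {
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ka <- unique(key(a)); kb <- unique(key(b))
  length(intersect(ka, kb)) / length(union(ka, kb))
}
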