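#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Reporting convention for percentages: round half-up to `digits` decimals
#' (base [round()] uses round-half-even, which differs at exact halves).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Canonical edge enumeration for an n-node undirected graph: upper triangle
# in column-major order, i < j, 1-based. All edge-major vectors in the
# package follow this order.
edge_index <- function(n_regions) {
  idx <- which(upper.tri(diag(n_regions)), arr.ind = TRUE)
  e <- cbind(i = idx[, 1], j = idx[, 2])
  e[order(e[, "j"], e[, "i"]), , drop = FALSE]
}

# Extract canonical edge-major vector from a symmetric matrix.
edge_values <- function(mat) mat[upper.tri(mat)]

# Rebuild a symmetric zero-diagonal matrix from an edge-major vector.
edge_matrix <- function(values, n_regions) {
  m <- matrix(0, n_regions, n_regions)
  m[upper.tri(m)] <- values
  m + t(m)
}

# Normalise an edge set to a sorted two-column integer matrix with i < j.
as_edge_set <- function(edges) {
  e <- as.matrix(edges)
  if (length(e) == 0L) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  if (ncol(e) != 2L) stop("edge set must have two columns (i, j)")
  storage.mode(e) <- "integer"
  swap <- e[, 1] > e[, 2]
  e[swap, ] <- e[swap, 2:1]
  if (any(e[, 1] == e[, 2])) stop("self-loop in edge set")
  e <- unique(e)
  e <- e[order(e[, 2], e[, 1]), , drop = FALSE]
  dimnames(e) <- list(NULL, c("i", "j"))
  e
}

# Row indices of `edges` within the canonical enumeration of n_regions nodes.
edge_positions <- function(edges, n_regions) {
  e <- as_edge_set(edges)
  if (any(e < 1L) || any(e > n_regions)) stop("edge index outside region range")
  # canonical order is column-major upper triangle: position of (i,j), i<j,
  # is (j-1)(j-2)/2 + i
  (e[, 2] - 1L) * (e[, 2] - 2L) / 2L + e[, 1]
}

# Maximum connected-component size (edge count) among suprathreshold edges.
# Minimal integer union-find; called once per permutation and threshold, so
# kept allocation-light (node labels are 1..n_nodes).
max_component_edges <- function(edges_mat, n_nodes) {
  m <- nrow(edges_mat)
  if (m == 0L) return(0L)
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  a <- edges_mat[, 1]
  b <- edges_mat[, 2]
  for (e in seq_len(m)) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(m), function(e) find(a[e]), 0L)
  max(tabulate(roots, nbins = n_nodes))
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's stream afterwards. Every stochastic operation in
# the package routes its `seed` argument through here.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
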