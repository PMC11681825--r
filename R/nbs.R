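#' Design specification for edge-wise group models
#'
#' @param group factor (or coercible) of per-subject group labels.
#' @param covariates optional data.frame or matrix of numeric nuisance
#'   covariates, one row per subject (kept attached to subjects under
#'   permutation).
#' @return a `design_spec` with the group factor, covariate matrix and
#'   derived degrees of freedom.
#' @export
design_spec <- function(group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 subjects")
  N <- length(group)
  X <- NULL
  if (!is.null(covariates)) {
    X <- as.matrix(as.data.frame(covariates))
    if (nrow(X) != N) stop("covariates must have one row per subject")
    if (!is.numeric(X)) stop("covariates must be numeric")
    storage.mode(X) <- "double"
  }
  ncov <- if (is.null(X)) 0L else ncol(X)
  full <- cbind(stats::model.matrix(~group), X)
  if (qr(full)$rank < ncol(full)) {
    stop("design matrix is rank deficient (collinear covariates?)")
  }
  structure(list(group = group, covariates = X, N = N, k = k,
                 ncov = ncov, df_between = k - 1L,
                 df_error = N - k - ncov),
            class = "design_spec")
}

#' Build a design from a cohort table
#'
#' @param cohort a cohort table.
#' @param covariates character vector of cohort column names to use as
#'   nuisance covariates (default: the study's NBS covariate set).
#' @return a [design_spec()].
#' @export
cohort_design <- function(cohort,
                          covariates = c("age", "duration", "ledd",
                                         "side")) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("covariate(s) not in cohort: ",
                         paste(miss, collapse = ", "))
  X <- if (length(covariates)) cohort[, covariates, drop = FALSE] else NULL
  design_spec(cohort$group, X)
}

# Edge-wise F for the group factor given a response matrix Y (subjects x
# edges). rss_reduced may be precomputed (it does not change when group
# labels are permuted with covariates fixed to subjects).
edgewise_f_stats <- function(Y, group, design, rss_reduced = NULL) {
  Xf <- cbind(stats::model.matrix(~group), design$covariates)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) stop("rank-deficient full design")
  rss_full <- colSums(qr.resid(qf, Y)^2)
  if (is.null(rss_reduced)) {
    Xr <- cbind(rep(1, nrow(Y)), design$covariates)
    rss_reduced <- colSums(qr.resid(qr(Xr), Y)^2)
  }
  f <- ((rss_reduced - rss_full) / design$df_between) /
    pmax(rss_full / design$df_error, .Machine$double.xmin)
  # edges with (numerically) no residual variance at all carry no signal
  f[rss_reduced < 1e-12 * pmax(colSums(Y^2), 1)] <- 0
  pmax(f, 0)
}

#' Edge-wise one-way ANCOVA across groups
#'
#' Fits, at every edge, the linear model
#' `fc ~ intercept + group + covariates` and the reduced model without the
#' group factor, and reports the partial F statistic for the group factor:
#' `F = [(RSS_reduced - RSS_full)/(k-1)] / [RSS_full/(N-k-Ncov)]`. With no
#' covariates this is the classical one-way ANOVA F.
#'
#' @param bundle an [fc_bundle()] (subject order must match the design).
#' @param band band name within the bundle.
#' @param design a [design_spec()].
#' @return an `edgewise_stats` list: per-edge `f`, `p` (upper-tail F),
#'   `omega2` effect sizes, degrees of freedom, edge enumeration.
#' @export
edgewise_ancova <- function(bundle, band, design) {
  Y <- bundle_edge_matrix(bundle, band)
  if (nrow(Y) != design$N) stop("bundle subjects do not match design rows")
  if (design$df_error < 1L) stop("non-positive error degrees of freedom")
  f <- edgewise_f_stats(Y, design$group, design)
  structure(list(
    f = f,
    p = stats::pf(f, design$df_between, design$df_error,
                  lower.tail = FALSE),
    omega2 = omega_squared(f, design$df_between, design$N),
    df_between = design$df_between, df_error = design$df_error,
    N = design$N, edges = edge_index(bundle$n_regions),
    n_regions = bundle$n_regions, band = band),
    class = "edgewise_stats")
}

#' Omega-squared effect size for a one-way F statistic
#'
#' `omega2 = df_between (F - 1) / (df_between (F - 1) + N)`, floored at 0
#' (the conventional fix for F < 1). Values above 0.06 are conventionally
#' read as at least a medium effect.
#'
#' @param f F statistic(s).
#' @param df_between numerator degrees of freedom (k - 1).
#' @param n total number of subjects.
#' @return effect size(s) in \[0, 1\].
#' @export
omega_squared <- function(f, df_between, n) {
  pmax(df_between * (f - 1) / (df_between * (f - 1) + n), 0)
}

# Smallest multiple of `step` whose omega-squared reaches `omega2_min`.
derive_f_initial <- function(policy, df_between, n) {
  f_min <- 1 + policy$omega2_min * n /
    (df_between * (1 - policy$omega2_min))
  policy$step * ceiling(f_min / policy$step - 1e-9)
}

#' Threshold-selection policy for the network-based statistic
#'
#' The scan starts at `f_initial` if given, otherwise at the smallest
#' multiple of `step` whose [omega_squared()] reaches `omega2_min` (the
#' "at least a medium effect" rule), and raises the threshold by `step`
#' until the largest suprathreshold component is significant at `alpha`.
#'
#' @param step F increment of the scan.
#' @param omega2_min minimum effect size defining the starting threshold.
#' @param alpha family-wise significance level.
#' @param f_initial optional explicit starting threshold overriding the
#'   effect-size rule.
#' @return a `threshold_policy` object.
#' @export
threshold_policy <- function(step = 0.1, omega2_min = 0.06, alpha = 0.05,
                             f_initial = NULL) {
  if (step <= 0) stop("step must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (omega2_min <= 0 || omega2_min >= 1) {
    stop("omega2_min must be in (0, 1)")
  }
  structure(list(step = step, omega2_min = omega2_min, alpha = alpha,
                 f_initial = f_initial), class = "threshold_policy")
}

#' Connected components of the suprathreshold graph
#'
#' Edges whose statistic strictly exceeds `f_threshold` form a graph whose
#' connected components are the candidate networks; component size is the
#' edge count (extent).
#'
#' @param stats an `edgewise_stats` object (or a list with `f`, `edges`,
#'   `n_regions`).
#' @param f_threshold primary threshold.
#' @return list of components sorted by decreasing size (ties broken by
#'   smallest node index); each has `edges`, `nodes`, `size`. Empty list
#'   if no edge passes.
#' @export
suprathreshold_components <- function(stats, f_threshold) {
  keep <- stats$f > f_threshold
  if (!any(keep)) return(list())
  e <- stats$edges[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[e[, 1]]
  comps <- lapply(split(seq_len(nrow(e)), comp_of_edge), function(rows) {
    ed <- e[rows, , drop = FALSE]
    list(edges = ed, nodes = sort(unique(as.vector(ed))),
         size = nrow(ed))
  })
  sizes <- vapply(comps, `[[`, 0L, "size")
  first_node <- vapply(comps, function(c) min(c$nodes), 0L)
  unname(comps[order(-sizes, first_node)])
}

#' Permutation null distribution of the maximum component size
#'
#' Group labels are shuffled across subjects (group sizes preserved,
#' covariates fixed to their subjects), the edge-wise ANCOVA is recomputed
#' and the maximum suprathreshold component size recorded, `n_perm` times.
#'
#' @inheritParams edgewise_ancova
#' @param f_threshold primary threshold.
#' @param n_perm number of permutations.
#' @param seed integer seed (deterministic output).
#' @return integer vector of length `n_perm` of maximum component sizes
#'   (0 when no edge passes).
#' @export
permutation_null <- function(bundle, band, design, f_threshold,
                             n_perm = 5000, seed = 1) {
  Y <- bundle_edge_matrix(bundle, band)
  fmaps <- permutation_f_maps(Y, design, n_perm, seed)
  edges <- edge_index(bundle$n_regions)
  apply(fmaps, 1, function(f) {
    max_component_edges(edges[f > f_threshold, , drop = FALSE],
                        bundle$n_regions)
  })
}

# n_perm x n_edges matrix of permuted edge-wise F statistics.
permutation_f_maps <- function(Y, design, n_perm, seed) {
  Xr <- cbind(rep(1, nrow(Y)), design$covariates)
  rss_reduced <- colSums(qr.resid(qr(Xr), Y)^2)
  with_seed(seed, {
    t(vapply(seq_len(n_perm), function(p) {
      gp <- design$group[sample.int(design$N)]
      edgewise_f_stats(Y, gp, design, rss_reduced)
    }, numeric(ncol(Y))))
  })
}

#' Family-wise error corrected p-value from a permutation null
#'
#' `p = (# null maximum sizes >= observed size) / n_perm` (pure fraction,
#' no +1 smoothing, so p can be exactly 0).
#'
#' @param observed_size observed component size (edge count), >= 1.
#' @param null_max_sizes integer vector from [permutation_null()].
#' @return p-value in \[0, 1\].
#' @export
fwer_pvalue <- function(observed_size, null_max_sizes) {
  if (length(null_max_sizes) == 0L) stop("empty permutation null")
  if (observed_size < 1) stop("observed component size must be >= 1")
  mean(null_max_sizes >= observed_size)
}

#' Run the network-based statistic with effect-size-guided thresholding
#'
#' Computes the observed edge-wise ANCOVA map and a permutation null of
#' maximum component size, then scans the primary threshold from the
#' policy's starting F upward in steps, testing the largest suprathreshold
#' component at each threshold, and stops at the first threshold whose
#' component is significant at `policy$alpha`. The permuted F maps are
#' computed once and re-thresholded during the scan, so the scan itself is
#' cheap. If no threshold up to the maximum observed edge F yields a
#' significant component, a non-significant result carrying the scan trace
#' is returned.
#'
#' @inheritParams edgewise_ancova
#' @param policy a [threshold_policy()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param max_steps maximum number of thresholds to test (default
#'   unlimited; `1` tests only the starting threshold).
#' @return an `nbs_result`: `significant`, `f_threshold`, `component`
#'   (largest component at the final threshold, or NULL), `components`,
#'   `p_fwer`, `null_max_sizes`, `edgewise`, `trace` (one row per
#'   threshold tested), `n_perm`, `seed`.
#' @export
run_nbs <- function(bundle, band, design, policy = threshold_policy(),
                    n_perm = 5000, seed = 1, max_steps = Inf) {
  stats <- edgewise_ancova(bundle, band, design)
  Y <- bundle_edge_matrix(bundle, band)
  fmaps <- permutation_f_maps(Y, design, n_perm, seed)
  f0 <- policy$f_initial %||%
    derive_f_initial(policy, design$df_between, design$N)
  edges <- stats$edges
  n_reg <- bundle$n_regions
  f_max <- max(stats$f)
  trace <- list()
  f <- f0
  step_i <- 0L
  result <- NULL
  while (f <= f_max && step_i < max_steps) {
    step_i <- step_i + 1L
    comps <- suprathreshold_components(stats, f)
    if (length(comps) == 0L) break
    obs_size <- comps[[1]]$size
    null_sizes <- apply(fmaps, 1, function(fv) {
      max_component_edges(edges[fv > f, , drop = FALSE], n_reg)
    })
    p <- fwer_pvalue(obs_size, null_sizes)
    trace[[step_i]] <- data.frame(f_threshold = f, max_size = obs_size,
                                  p_fwer = p)
    if (p < policy$alpha) {
      result <- list(significant = TRUE, f_threshold = f,
                     component = comps[[1]], components = comps,
                     p_fwer = p, null_max_sizes = null_sizes)
      break
    }
    f <- f + policy$step
  }
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(f_threshold = numeric(0), max_size = integer(0),
               p_fwer = numeric(0))
  if (is.null(result)) {
    result <- list(significant = FALSE, f_threshold = f0,
                   component = NULL, components = list(),
                   p_fwer = NA_real_,
                   null_max_sizes = integer(0))
  }
  structure(c(result,
              list(edgewise = stats, trace = trace_df, n_perm = n_perm,
                   seed = seed, policy = policy, band = band)),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  if (x$significant) {
    cat(sprintf(
      "<nbs_result> band %s: significant network at F = %.2f (p = %.4g)\n",
      x$band, x$f_threshold, x$p_fwer))
    cat(sprintf("  %d nodes, %d links; %d permutations\n",
                length(x$component$nodes), x$component$size, x$n_perm))
  } else {
    cat(sprintf(
      "<nbs_result> band %s: no significant network (%d thresholds tested)\n",
      x$band, nrow(x$trace)))
  }
  invisible(x)
}
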