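#' Mean network connectivity
#'
#' Per-subject average of the connectivity values over the edges of an
#' identified network component.
#'
#' @param bundle an [fc_bundle()].
#' @param band band name.
#' @param edges two-column matrix of region index pairs (or a component
#'   from [suprathreshold_components()]).
#' @return an `mnc_vector`: `mnc` (numeric per subject), `edges`, `band`,
#'   `subjects`.
#' @export
mean_network_connectivity <- function(bundle, band, edges) {
  if (is.list(edges) && !is.null(edges$edges)) edges <- edges$edges
  e <- as_edge_set(edges)
  if (nrow(e) == 0L) stop("empty edge set")
  pos <- edge_positions(e, bundle$n_regions)
  Y <- bundle_edge_matrix(bundle, band)
  structure(list(mnc = rowMeans(Y[, pos, drop = FALSE]),
                 edges = e, band = band, subjects = bundle$subjects),
            class = "mnc_vector")
}

# Tukey-Kramer machinery shared by the omnibus test and the edge-level
# post-hoc: vectorized over response columns.
tukey_kramer_pairs <- function(Y, group) {
  Y <- as.matrix(Y)
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  ns <- as.vector(table(group))
  N <- length(group)
  df_error <- N - k
  gm <- rowsum(Y, group) / ns                       # k x E group means
  ssw <- colSums(Y^2) - colSums(gm^2 * ns)
  msw <- ssw / df_error
  pairs <- utils::combn(levels(group), 2)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    na <- ns[match(a, levels(group))]; nb <- ns[match(b, levels(group))]
    diff <- gm[a, ] - gm[b, ]
    se <- sqrt((msw / 2) * (1 / na + 1 / nb))
    q <- abs(diff) / pmax(se, .Machine$double.xmin)
    p_adj <- stats::ptukey(q, nmeans = k, df = df_error,
                           lower.tail = FALSE)
    list(group1 = a, group2 = b, mean_diff = diff, q = q, p_adj = p_adj)
  })
  list(pairs = res, msw = msw, df_error = df_error, k = k,
       levels = levels(group), ns = ns)
}

#' Group comparison of mean network connectivity
#'
#' One-way ANOVA omnibus test on the per-subject mNC followed by
#' Tukey-Kramer pairwise comparisons (studentized-range p-values, valid
#' for unequal group sizes).
#'
#' @param mnc an `mnc_vector` (or numeric vector).
#' @param design a [design_spec()] (only the group factor is used).
#' @return list with `f`, `p` (omnibus), `df`, `tukey` (data.frame of all
#'   pairs: mean difference, q, adjusted p), `degenerate` flag (zero
#'   within-group variance).
#' @export
mnc_group_test <- function(mnc, design) {
  y <- if (is.list(mnc)) mnc$mnc else mnc
  group <- design$group
  if (length(y) != length(group)) stop("mnc does not align with design")
  tk <- tukey_kramer_pairs(matrix(y, ncol = 1), group)
  degenerate <- tk$msw < .Machine$double.eps
  k <- tk$k; N <- length(y)
  gm <- rowsum(y, group) / tk$ns
  ssb <- sum(tk$ns * (gm - mean(y))^2)
  f <- (ssb / (k - 1)) / max(tk$msw, .Machine$double.xmin)
  tukey <- do.call(rbind, lapply(tk$pairs, function(p) {
    data.frame(group1 = p$group1, group2 = p$group2,
               mean_diff = p$mean_diff, q = p$q, p_adj = p$p_adj)
  }))
  rownames(tukey) <- NULL
  list(f = f,
       p = stats::pf(f, k - 1, tk$df_error, lower.tail = FALSE),
       df = c(k - 1, tk$df_error), tukey = tukey,
       degenerate = degenerate)
}

#' Directional post-hoc subnetworks of an identified network
#'
#' For every edge of the parent component, runs a Tukey-Kramer comparison
#' of the edge's connectivity across all groups and retains the edge when
#' the adjusted p-value of the named contrast falls below `alpha`. Retained
#' edges are split by the sign of the group mean difference, giving at most
#' two directional subnetworks (e.g. "A > B" and "B > A").
#'
#' @param bundle an [fc_bundle()].
#' @param band band name.
#' @param parent a component (list with `edges`) from a prior network scan.
#' @param design a [design_spec()].
#' @param contrast character vector of two group labels, `c(g1, g2)`.
#' @param alpha per-edge adjusted significance level.
#' @return list of `subnetwork` objects (possibly empty); each carries
#'   `edges`, `nodes`, `direction` (`"g1>g2"` or `"g2>g1"`), `contrast`,
#'   `parent_size`, and per-edge adjusted p-values.
#' @export
extract_subnetwork <- function(bundle, band, parent, design, contrast,
                               alpha = 0.05) {
  if (length(contrast) != 2L ||
      !all(contrast %in% levels(design$group))) {
    stop("contrast must name two groups present in the design")
  }
  e <- as_edge_set(parent$edges)
  pos <- edge_positions(e, bundle$n_regions)
  Y <- bundle_edge_matrix(bundle, band)[, pos, drop = FALSE]
  tk <- tukey_kramer_pairs(Y, design$group)
  hit <- NULL
  for (p in tk$pairs) {
    if (setequal(c(p$group1, p$group2), contrast)) hit <- p
  }
  # pairs are stored in factor-level order; flip sign if contrast reversed
  sgn <- if (identical(hit$group1, contrast[1])) 1 else -1
  diff <- sgn * hit$mean_diff
  keep <- hit$p_adj < alpha
  out <- list()
  for (dir_up in c(TRUE, FALSE)) {
    sel <- keep & (if (dir_up) diff > 0 else diff < 0)
    if (!any(sel)) next
    ed <- e[sel, , drop = FALSE]
    out[[length(out) + 1L]] <- structure(
      list(edges = ed, nodes = sort(unique(as.vector(ed))),
           direction = if (dir_up) {
             paste(contrast[1], ">", contrast[2])
           } else {
             paste(contrast[2], ">", contrast[1])
           },
           contrast = contrast, parent_size = nrow(e),
           p_adj = hit$p_adj[sel], alpha = alpha, band = band),
      class = "subnetwork")
  }
  if (length(out) > 1L) {
    out <- out[order(-vapply(out, function(s) nrow(s$edges), 0L))]
  }
  out
}

#' Summary statistics of a (sub)network
#'
#' Reporting conventions for identified networks: node and link counts,
#' the percentage of parent links retained (rounded half-up to one
#' decimal), hemispheric lateralization in three variants (node share,
#' link share with cross-hemisphere links split half-half, and
#' degree-mass share), the per-node degree table sorted by decreasing
#' degree, and per-lobe shares of total degree.
#'
#' @param sub a subnetwork or component (list with `edges`), or a
#'   two-column edge matrix; may be empty.
#' @param parent parent component (list with `edges`) or edge matrix; the
#'   denominator of the percentage.
#' @param atlas an atlas from [load_atlas()].
#' @return a `subnetwork_summary` list.
#' @export
summarize_subnetwork <- function(sub, parent, atlas = load_atlas()) {
  get_edges <- function(x) {
    if (is.list(x) && !is.null(x$edges)) x$edges else x
  }
  e <- as_edge_set(get_edges(sub))
  pe <- as_edge_set(get_edges(parent))
  n_atlas <- nrow(atlas)
  if (nrow(e) > 0 && max(e) > n_atlas) {
    stop("subnetwork references nodes outside the atlas")
  }
  n_links <- nrow(e)
  nodes <- if (n_links) sort(unique(as.vector(e))) else integer(0)
  pct <- if (nrow(pe) > 0) {
    round_half_up(100 * n_links / nrow(pe), 1)
  } else NA_real_
  degree <- tabulate(as.vector(e), nbins = n_atlas)
  hemi <- atlas$hemisphere
  lat <- function(x) if (sum(x) > 0) 100 * x / sum(x) else c(left = NA,
                                                             right = NA)
  node_count <- c(left = sum(hemi[nodes] == "left"),
                  right = sum(hemi[nodes] == "right"))
  link_w <- c(left = 0, right = 0)
  if (n_links) {
    h1 <- hemi[e[, 1]]; h2 <- hemi[e[, 2]]
    link_w["left"] <- sum((h1 == "left") + (h2 == "left")) / 2
    link_w["right"] <- sum((h1 == "right") + (h2 == "right")) / 2
  }
  deg_mass <- c(left = sum(degree[hemi == "left"]),
                right = sum(degree[hemi == "right"]))
  lobe_mass <- tapply(degree, atlas$lobe, sum)
  lobe_share <- if (sum(degree) > 0) {
    round_half_up(100 * lobe_mass / sum(degree), 1)
  } else lobe_mass * NA_real_
  deg_tab <- data.frame(region = atlas$name, lobe = atlas$lobe,
                        hemisphere = hemi, degree = degree)
  deg_tab <- deg_tab[deg_tab$degree > 0, , drop = FALSE]
  deg_tab <- deg_tab[order(-deg_tab$degree, deg_tab$region), ]
  rownames(deg_tab) <- NULL
  structure(list(
    n_nodes = length(nodes), n_links = n_links,
    pct_of_parent_links = pct,
    lateralization_pct = list(
      node_share = round_half_up(lat(node_count), 1),
      link_share = round_half_up(lat(link_w), 1),
      degree_mass = round_half_up(lat(deg_mass), 1)),
    degree = deg_tab,
    lobe_composition = lobe_share,
    direction = if (is.list(sub)) sub$direction else NULL),
    class = "subnetwork_summary")
}

#' @export
print.subnetwork_summary <- function(x, ...) {
  cat(sprintf("<subnetwork_summary> %d nodes, %d links (%.1f %% of parent)\n",
              x$n_nodes, x$n_links, x$pct_of_parent_links))
  if (!is.null(x$direction)) cat("  direction:", x$direction, "\n")
  ls <- x$lateralization_pct$node_share
  cat(sprintf("  lateralization (node share): left %.1f %%, right %.1f %%\n",
              ls["left"], ls["right"]))
  if (nrow(x$degree)) {
    cat("  top-degree regions:\n")
    print(utils::head(x$degree, 5))
  }
  invisible(x)
}
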