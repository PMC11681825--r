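#' Configuration for suprathreshold-edge leave-one-out classification
#'
#' @param contrast character vector of two group labels; the first is the
#'   positive class for precision/sensitivity and scores.
#' @param f_threshold primary edge-selection threshold (two-group F, i.e.
#'   squared t); `NULL` derives it as the smallest multiple of 0.1 whose
#'   omega-squared reaches 0.06 for the training sample size.
#' @param ci_boot bootstrap resamples for the metric confidence intervals.
#' @param seed integer seed.
#' @return a `cv_config` object.
#' @export
cv_config <- function(contrast, f_threshold = NULL, ci_boot = 1000,
                      seed = 1) {
  if (length(contrast) != 2L || contrast[1] == contrast[2]) {
    stop("contrast must name two distinct groups")
  }
  structure(list(contrast = contrast, f_threshold = f_threshold,
                 ci_boot = ci_boot, seed = seed), class = "cv_config")
}

# Two-group edge-wise F (= squared pooled t), vectorized over edges.
two_group_f <- function(Y, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  ma <- colMeans(Y[is_a, , drop = FALSE])
  mb <- colMeans(Y[!is_a, , drop = FALSE])
  va <- colSums(sweep(Y[is_a, , drop = FALSE], 2, ma)^2)
  vb <- colSums(sweep(Y[!is_a, , drop = FALSE], 2, mb)^2)
  sp2 <- (va + vb) / (na + nb - 2)
  (ma - mb)^2 / pmax(sp2 * (1 / na + 1 / nb), .Machine$double.xmin)
}

#' Leave-one-out evaluation of suprathreshold-edge networks
#'
#' Out-of-sample discrimination of two groups from their connectivity, in
#' the style of connectome-based predictive NBS tools: for each left-out
#' subject, a two-group edge statistic is computed on the training
#' subjects only, the largest connected component among suprathreshold
#' edges is taken as the feature set, the selected edges' connectivity
#' values (standardized with training-fold statistics) feed a linear
#' discriminant, and the held-out subject's label and score are recorded.
#' When no edge passes the threshold in a fold, the fold falls back to the
#' single highest-statistic edge (counted in `n_fallback`).
#'
#' @param bundle an [fc_bundle()].
#' @param band band name.
#' @param cohort cohort table aligned to the bundle.
#' @param cfg a [cv_config()].
#' @return a `cv_report`: `metrics` (point value and 95 % CI per metric),
#'   `folds` (per-fold truth, prediction, score), `edge_frequency`
#'   (selection frequency per edge across folds), `positive`,
#'   `n_fallback`.
#' @export
loo_cv <- function(bundle, band, cohort, cfg) {
  stopifnot(inherits(cfg, "cv_config"))
  grp <- as.character(cohort$group)
  sel <- grp %in% cfg$contrast
  if (sum(grp == cfg$contrast[1] & sel) < 4L ||
      sum(grp == cfg$contrast[2] & sel) < 4L) {
    stop("need at least 4 subjects per contrast group")
  }
  Y <- bundle_edge_matrix(bundle, band)[sel, , drop = FALSE]
  g <- factor(grp[sel], levels = cfg$contrast)
  n <- nrow(Y)
  edges <- edge_index(bundle$n_regions)
  thr <- cfg$f_threshold %||% {
    pol <- threshold_policy()
    derive_f_initial(pol, 1L, n - 1L)
  }
  n_edges <- ncol(Y)
  freq <- numeric(n_edges)
  pred <- character(n)
  score <- numeric(n)
  fold_edges <- vector("list", n)
  n_fallback <- 0L
  for (fold in seq_len(n)) {
    tr <- setdiff(seq_len(n), fold)
    f <- two_group_f(Y[tr, , drop = FALSE], g[tr] == cfg$contrast[1])
    keep <- which(f > thr)
    if (length(keep) == 0L) {
      keep <- which.max(f)
      n_fallback <- n_fallback + 1L
    } else {
      e <- edges[keep, , drop = FALSE]
      gr <- igraph::graph_from_edgelist(e, directed = FALSE)
      memb <- igraph::components(gr)$membership
      comp_id <- memb[e[, 1]]
      sizes <- table(comp_id)
      best <- as.integer(names(sizes)[which.max(sizes)])
      keep <- keep[comp_id == best]
    }
    # keep the discriminant well-posed: cap the feature count below the
    # training sample size, preferring the strongest training-fold edges
    if (length(keep) > length(tr) - 3L) {
      keep <- keep[order(f[keep], decreasing = TRUE)[seq_len(length(tr) - 3L)]]
    }
    freq[keep] <- freq[keep] + 1
    fold_edges[[fold]] <- keep
    Xtr <- Y[tr, keep, drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv < .Machine$double.eps] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    Xte <- sweep(sweep(Y[fold, keep, drop = FALSE], 2, mu), 2, sdv, `/`)
    fit <- MASS::lda(Xtr, grouping = g[tr])
    pr <- stats::predict(fit, Xte)
    pred[fold] <- as.character(pr$class)
    score[fold] <- pr$posterior[1, cfg$contrast[1]]
  }
  folds <- data.frame(subject = bundle$subjects[sel],
                      truth = as.character(g), pred = pred,
                      score = score, stringsAsFactors = FALSE)
  point <- classification_metrics(folds$truth, folds$pred, folds$score,
                                  positive = cfg$contrast[1])
  ci <- metric_ci(folds, n_boot = cfg$ci_boot, seed = cfg$seed,
                  positive = cfg$contrast[1])
  metrics <- lapply(names(point), function(m) {
    list(value = point[[m]], ci = ci[[m]])
  })
  names(metrics) <- names(point)
  structure(list(metrics = metrics, folds = folds,
                 edge_frequency = freq / n, fold_edges = fold_edges,
                 f_threshold = thr, positive = cfg$contrast[1],
                 n_fallback = n_fallback, band = band),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> band ", x$band, ", positive class ", x$positive,
      "\n", sep = "")
  for (m in names(x$metrics)) {
    v <- x$metrics[[m]]
    cat(sprintf("  %-12s %.2f [%.2f %.2f]\n", m, v$value,
                v$ci[1], v$ci[2]))
  }
  invisible(x)
}

#' Binary classification metrics
#'
#' Accuracy, precision, Cohen's kappa, AUC (Mann-Whitney rank statistic
#' with ties counted one half), sensitivity and specificity. Metrics whose
#' denominator is empty (e.g. precision with no positive predictions) are
#' returned as NA.
#'
#' @param y_true,y_pred character/factor vectors of true and predicted
#'   labels.
#' @param scores numeric scores for the positive class (used for AUC;
#'   `NULL` omits AUC).
#' @param positive label treated as the positive class.
#' @return named list of metrics.
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL,
                                   positive) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  pos_t <- y_true == positive
  pos_p <- y_pred == positive
  tp <- sum(pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  n <- length(y_true)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  auc <- NA_real_
  if (!is.null(scores)) {
    n1 <- sum(pos_t); n0 <- n - n1
    if (n1 > 0 && n0 > 0) {
      rk <- rank(scores)
      auc <- (sum(rk[pos_t]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(accuracy = p_o,
       precision = safe_div(tp, tp + fp),
       kappa = kappa,
       auc = auc,
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp))
}

#' Bootstrap confidence intervals for cross-validation metrics
#'
#' Resamples the fold-level prediction rows with replacement and reports
#' percentile 95 % bounds per metric.
#'
#' @param folds data.frame with columns `truth`, `pred`, `score`.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param positive positive class label.
#' @return named list of length-2 CI vectors.
#' @export
metric_ci <- function(folds, n_boot = 1000, seed = 1, positive) {
  n <- nrow(folds)
  if (n < 8L) stop("need at least 8 folds for metric CIs")
  metric_names <- c("accuracy", "precision", "kappa", "auc",
                    "sensitivity", "specificity")
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      m <- classification_metrics(folds$truth[idx], folds$pred[idx],
                                  folds$score[idx], positive)
      unlist(m)[metric_names]
    }, numeric(length(metric_names)))
  })
  out <- lapply(metric_names, function(m) {
    v <- draws[m, ]
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
  })
  names(out) <- metric_names
  out
}
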