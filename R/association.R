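#' Covariate-adjusted partial Pearson correlation
#'
#' Correlation between the least-squares residuals of `x` and `y` after
#' regressing each on an intercept plus the covariates. The p-value comes
#' from `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - ncov`, two-sided.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame (n rows).
#' @return list with `r`, `p`, `n`, `df`, `degenerate` (TRUE when either
#'   residual has essentially no variance; `r` is then NA).
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  ncov <- 0L
  if (!is.null(covariates)) {
    Z <- as.matrix(as.data.frame(covariates))
    if (nrow(Z) != n) stop("covariates must have one row per observation")
    if (anyNA(Z)) stop("missing values in covariates")
    ncov <- ncol(Z)
    qz <- qr(cbind(rep(1, n), Z))
    rx <- qr.resid(qz, x)
    ry <- qr.resid(qz, y)
  } else {
    rx <- x - mean(x)
    ry <- y - mean(y)
  }
  df <- n - 2L - ncov
  if (df < 1L) stop("need n > ncov + 2 observations")
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  tol <- .Machine$double.eps^0.5 * sqrt(n)
  if (sx < tol * max(1, abs(mean(x))) || sy < tol * max(1, abs(mean(y)))) {
    return(list(r = NA_real_, p = NA_real_, n = n, df = df,
                degenerate = TRUE))
  }
  r <- sum(rx * ry) / (sx * sy)
  r <- max(-1, min(1, r))
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(t), df)
  list(r = r, p = min(p, 1), n = n, df = df, degenerate = FALSE)
}

#' Bootstrap percentile confidence interval for a partial correlation
#'
#' Resamples subjects (rows of `x`, `y` and the covariates jointly) with
#' replacement, recomputes the partial correlation per resample, and
#' returns the 2.5/97.5 percentile bounds. Degenerate resamples (no
#' residual variance) are skipped; more than 20 % of them is treated as an
#' instability error.
#'
#' @inheritParams partial_pearson
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed (deterministic output).
#' @return list with `ci_low`, `ci_high`, `n_boot`, `n_used`, `boot_r`.
#' @export
bootstrap_ci <- function(x, y, covariates = NULL, n_boot = 1000,
                         seed = 1) {
  n <- length(x)
  if (n < 8L) stop("need at least 8 subjects for the bootstrap")
  Z <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  boot_r <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- partial_pearson(x[idx], y[idx],
                             if (is.null(Z)) NULL else
                               Z[idx, , drop = FALSE])
      if (res$degenerate) NA_real_ else res$r
    }, 0)
  })
  used <- boot_r[!is.na(boot_r)]
  if (length(used) < 0.8 * n_boot) {
    stop("bootstrap unstable: more than 20 % of resamples degenerate")
  }
  ci <- stats::quantile(used, c(0.025, 0.975), names = FALSE, type = 7)
  list(ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
       n_used = length(used), boot_r = boot_r)
}

#' Partial-correlation table for networks against cohort variables
#'
#' One row per (network, variable, stratum): covariate-adjusted partial
#' Pearson correlation of the network's mean connectivity with the cohort
#' variable, plus bootstrap percentile 95 % confidence bounds. The study's
#' reporting format is `r, p, [ci_low ci_high]`.
#'
#' @param mnc_sets named list of `mnc_vector`s (or numeric vectors aligned
#'   to the cohort).
#' @param cohort a cohort table.
#' @param variables character vector of cohort columns to correlate.
#' @param covariates character vector of cohort columns used as nuisance
#'   covariates.
#' @param stratify optional cohort column name; correlations are computed
#'   within each level (e.g. sex within patients). `NULL` uses all rows.
#' @param subset optional logical vector selecting cohort rows before
#'   stratification (e.g. the patient group).
#' @param n_boot bootstrap resamples per row.
#' @param seed integer seed.
#' @return data.frame with columns network, variable, stratum, n, r, p,
#'   ci_low, ci_high, degenerate. Variables absent from the cohort are
#'   skipped with a warning.
#' @export
correlation_table <- function(mnc_sets, cohort, variables,
                              covariates = c("age", "duration", "bmi",
                                             "side"),
                              stratify = NULL, subset = NULL,
                              n_boot = 1000, seed = 1) {
  if (!is.list(mnc_sets) || is.null(names(mnc_sets))) {
    stop("mnc_sets must be a named list")
  }
  missing_vars <- setdiff(variables, names(cohort))
  if (length(missing_vars)) {
    warning("variable(s) not in cohort, skipped: ",
            paste(missing_vars, collapse = ", "))
    variables <- setdiff(variables, missing_vars)
  }
  keep <- subset %||% rep(TRUE, nrow(cohort))
  strata <- if (is.null(stratify)) {
    list(all = keep)
  } else {
    lv <- unique(as.character(cohort[[stratify]][keep]))
    stats::setNames(lapply(lv, function(s) {
      keep & !is.na(cohort[[stratify]]) & cohort[[stratify]] == s
    }), lv)
  }
  rows <- list()
  ri <- 0L
  for (net in names(mnc_sets)) {
    m <- mnc_sets[[net]]
    mv <- if (is.list(m)) m$mnc else m
    for (v in variables) {
      for (st in names(strata)) {
        sel <- strata[[st]] & !is.na(cohort[[v]])
        x <- mv[sel]
        y <- cohort[[v]][sel]
        Z <- if (length(covariates)) {
          as.matrix(cohort[sel, covariates, drop = FALSE])
        } else NULL
        ri <- ri + 1L
        pc <- partial_pearson(x, y, Z)
        if (pc$degenerate) {
          rows[[ri]] <- data.frame(network = net, variable = v,
                                   stratum = st, n = pc$n, r = NA, p = NA,
                                   ci_low = NA, ci_high = NA,
                                   degenerate = TRUE)
        } else {
          ci <- bootstrap_ci(x, y, Z, n_boot = n_boot,
                             seed = seed + ri)
          rows[[ri]] <- data.frame(network = net, variable = v,
                                   stratum = st, n = pc$n, r = pc$r,
                                   p = pc$p, ci_low = ci$ci_low,
                                   ci_high = ci$ci_high,
                                   degenerate = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(network = character(0), variable = character(0),
               stratum = character(0), n = integer(0), r = numeric(0),
               p = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               degenerate = logical(0))
  rownames(out) <- NULL
  out
}
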