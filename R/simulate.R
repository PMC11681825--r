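#' Simulation configuration for synthetic cohorts
#'
#' Describes a four-group (or general k-group) cohort of region-level
#' recordings: sampling rate, duration, parcellation size, frequency bands,
#' coupling and noise levels, and the edge-weight model used by the direct
#' connectivity generator. Defaults mirror the study protocol the package
#' targets: groups female_PD/male_PD/female_HC/male_HC of sizes
#' 27/42/30/39, 1024 Hz sampling and 180 s of retained signal, with
#' covariate distributions taken from the cohort description (age, disease
#' duration in months, LEDD mg/day, BMI, most-affected side) and hormone
#' panels by sex.
#'
#' @param group_sizes named integer vector of per-group subject counts
#'   (every group needs at least 2 subjects).
#' @param fs sampling rate in Hz.
#' @param duration_s recording length in seconds.
#' @param n_regions number of atlas regions.
#' @param bands named list of [band_definition()]s.
#' @param base_coupling baseline coupling strength applied to every planted
#'   edge before group offsets (time-series generator).
#' @param noise_sd standard deviation of the additive broadband noise
#'   (time-series generator).
#' @param fc_base_mean baseline edge-weight location in (0, 1) (direct
#'   connectivity generator, logit-normal).
#' @param fc_logit_sd edge-weight spread on the logit scale.
#' @param seed integer seed; all generators are deterministic given the
#'   configuration and seed.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(group_sizes = c(female_PD = 27, male_PD = 42,
                                              female_HC = 30, male_HC = 39),
                              fs = 1024, duration_s = 180, n_regions = 68,
                              bands = default_bands(),
                              base_coupling = 0, noise_sd = 1,
                              fc_base_mean = 0.3, fc_logit_sd = 0.5,
                              seed = 1) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    stop("group_sizes must be a named vector")
  }
  if (any(group_sizes < 2)) {
    stop("every group needs at least 2 subjects (within-group variance)")
  }
  if (duration_s <= 0) stop("duration_s must be positive")
  f_max <- max(vapply(bands, function(b) b$f_high, 0))
  if (fs <= 2 * f_max) {
    stop("fs = ", fs, " Hz violates Nyquist for band edge ", f_max, " Hz")
  }
  if (fc_base_mean <= 0 || fc_base_mean >= 1) {
    stop("fc_base_mean must lie in (0, 1)")
  }
  structure(list(group_sizes = group_sizes, fs = fs,
                 duration_s = duration_s, n_regions = n_regions,
                 bands = bands, base_coupling = base_coupling,
                 noise_sd = noise_sd, fc_base_mean = fc_base_mean,
                 fc_logit_sd = fc_logit_sd, seed = seed),
            class = "simulation_config")
}

#' Planted group-differential coupling effect
#'
#' @param band band name (must match a band in the configuration).
#' @param edges two-column matrix of region index pairs (1-based, i < j).
#' @param group_deltas named numeric vector of per-group coupling (or
#'   edge-weight mean) offsets.
#' @param phase_lag phase lag in radians, strictly inside (0, pi): zero-lag
#'   (and anti-phase) coupling produces all-real cross-terms and is
#'   invisible to wPLI by construction, so it is rejected.
#' @return a `planted_effect` object.
#' @export
planted_effect <- function(band, edges, group_deltas, phase_lag = pi / 4) {
  if (phase_lag <= 0 || phase_lag >= pi) {
    stop("phase_lag must lie strictly in (0, pi): a lag of 0 or pi has ",
         "zero imaginary cross-spectrum and cannot be detected by wPLI")
  }
  if (is.null(names(group_deltas))) stop("group_deltas must be named")
  structure(list(band = band, edges = as_edge_set(edges),
                 group_deltas = group_deltas, phase_lag = phase_lag),
            class = "planted_effect")
}

# Cohort covariate distributions (per-group mean/sd), matching the target
# study population tables; HC have no disease-specific covariates (0).
cohort_covariate_model <- function() {
  list(
    age  = list(female_PD = c(61.8, 9.0), male_PD = c(62.8, 9.0),
                female_HC = c(57.2, 11.8), male_HC = c(60.1, 10.5),
                default = c(60, 10)),
    duration = list(female_PD = c(29.3, 19.5), male_PD = c(27.5, 19.4),
                    default = c(0, 0)),
    ledd = list(female_PD = c(110.3, 133.2), male_PD = c(100.8, 138.7),
                default = c(0, 0)),
    bmi  = list(female_PD = c(24.9, 2.6), male_PD = c(25.5, 3.8),
                female_HC = c(24.9, 2.6), male_HC = c(25.5, 3.8),
                default = c(25.2, 3.2)))
}

hormone_model <- function() {
  list(E2  = list(female = c(0.5, 0.5),  male = c(28.6, 16.9)),
       TT  = list(female = c(26.5, 19.8), male = c(484.8, 182.9)),
       FSH = list(female = c(64.9, 26.5), male = c(8.6, 12.3)),
       LH  = list(female = c(22.6, 10.5), male = c(3.7, 2.9)))
}

# Draw the covariate/hormone table for one cohort. Uses the ambient RNG
# stream (callers wrap in with_seed).
draw_cohort <- function(cfg) {
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n <- length(groups)
  df <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = groups, stringsAsFactors = FALSE)
  df$sex <- ifelse(grepl("female", groups), "female",
                   ifelse(grepl("male", groups), "male", NA))
  cm <- cohort_covariate_model()
  for (cv in names(cm)) {
    spec <- cm[[cv]]
    ms <- t(vapply(groups, function(g) spec[[g]] %||% spec$default,
                   c(0, 0)))
    df[[cv]] <- pmax(0, stats::rnorm(n, ms[, 1], ms[, 2]))
  }
  is_pd <- grepl("PD", groups)
  df$duration[!is_pd] <- 0
  df$ledd[!is_pd] <- 0
  df$side <- ifelse(is_pd, stats::rbinom(n, 1, 0.55), 0)
  if (!anyNA(df$sex)) {
    hm <- hormone_model()
    for (h in names(hm)) {
      ms <- t(vapply(df$sex, function(s) hm[[h]][[s]], c(0, 0)))
      df[[h]] <- ifelse(is_pd, pmax(0, stats::rnorm(n, ms[, 1], ms[, 2])),
                        NA)
    }
  }
  as_cohort(df, group_levels = names(cfg$group_sizes))
}

# Unit-variance narrowband noise: white noise band-passed to `band`.
narrowband_noise <- function(n_regions, n_samples, fs, band) {
  x <- matrix(stats::rnorm(n_regions * n_samples), n_regions)
  y <- bandpass(region_timeseries(x, fs), band)$data
  y / apply(y, 1, stats::sd)
}

#' Simulate region-level time series with planted phase-lagged coupling
#'
#' Each region signal is a sum over bands of a region-private narrowband
#' stochastic oscillator (band-passed white noise, so wPLI estimates have
#' realistic variance) plus, on planted edges, a shared band-limited latent
#' source injected into both endpoint regions with a phase offset
#' `phase_lag` between them, scaled by `base_coupling + group_deltas[g]`;
#' broadband white noise of sd `noise_sd` is added on top. The phase offset
#' is applied by rotating the analytic extension of the latent source, so
#' coupling is genuinely lagged (detectable by wPLI) rather than
#' instantaneous.
#'
#' @param cfg a [simulation_config()].
#' @param effects list of [planted_effect()]s.
#' @return list with `ts` (list of [region_timeseries()]) and `cohort`
#'   (covariate table aligned to `ts`). Deterministic given `cfg$seed`.
#' @export
simulate_timeseries <- function(cfg, effects = list()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  band_names <- names(cfg$bands)
  for (ef in effects) {
    if (!ef$band %in% band_names) {
      stop("planted effect references unknown band '", ef$band, "'")
    }
    if (any(ef$edges > cfg$n_regions)) {
      stop("planted edge references region outside the parcellation")
    }
    if (any(cfg$base_coupling + ef$group_deltas < 0)) {
      stop("negative total coupling on a planted edge")
    }
  }
  n_samp <- as.integer(round(cfg$duration_s * cfg$fs))
  with_seed(cfg$seed, {
    cohort <- draw_cohort(cfg)
    ts <- vector("list", nrow(cohort))
    for (s in seq_len(nrow(cohort))) {
      g <- as.character(cohort$group[s])
      x <- matrix(0, cfg$n_regions, n_samp)
      for (b in band_names) {
        x <- x + narrowband_noise(cfg$n_regions, n_samp, cfg$fs,
                                  cfg$bands[[b]])
        for (ef in effects) {
          if (ef$band != b) next
          coup <- cfg$base_coupling + (ef$group_deltas[g] %||% 0)
          if (is.na(coup)) coup <- cfg$base_coupling
          # the latent source is drawn even at zero coupling so the draw
          # sequence (and hence the noise realisation) does not depend on
          # parameter values: runs differing only in coupling strength
          # share their randomness
          for (e in seq_len(nrow(ef$edges))) {
            src <- narrowband_noise(1L, n_samp, cfg$fs, cfg$bands[[b]])
            z <- analytic_signal(region_timeseries(src, cfg$fs))[1, ]
            i <- ef$edges[e, 1]; j <- ef$edges[e, 2]
            x[i, ] <- x[i, ] + coup * Re(z)
            x[j, ] <- x[j, ] + coup * Re(z * exp(-1i * ef$phase_lag))
          }
        }
      }
      x <- x + cfg$noise_sd * matrix(stats::rnorm(length(x)),
                                     cfg$n_regions)
      ts[[s]] <- region_timeseries(x, cfg$fs, cohort$subject_id[s])
    }
    list(ts = ts, cohort = cohort)
  })
}

#' Simulate static connectivity matrices directly
#'
#' Fast path for testing the statistical stages without the oscillator
#' model: each edge weight is drawn independently from a logit-normal
#' distribution (bounded to (0, 1), like wPLI), with location
#' `qlogis(fc_base_mean + delta_g)` on planted edges for subjects of group
#' g and `qlogis(fc_base_mean)` elsewhere, spread `fc_logit_sd` on the
#' logit scale. `phase_lag` is irrelevant in this mode.
#'
#' @inheritParams simulate_timeseries
#' @return list with `bundle` (an [fc_bundle()]) and `cohort`.
#'   Deterministic given `cfg$seed`.
#' @export
simulate_fc_directly <- function(cfg, effects = list()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  band_names <- names(cfg$bands)
  for (ef in effects) {
    if (!ef$band %in% band_names) {
      stop("planted effect references unknown band '", ef$band, "'")
    }
    shifted <- cfg$fc_base_mean + ef$group_deltas
    if (any(shifted <= 0 | shifted >= 1)) {
      stop("group delta pushes planted edge-weight mean outside (0, 1)")
    }
  }
  n <- cfg$n_regions
  n_edge <- n * (n - 1) / 2
  base_loc <- stats::qlogis(cfg$fc_base_mean)
  with_seed(cfg$seed, {
    cohort <- draw_cohort(cfg)
    ns <- nrow(cohort)
    mats <- lapply(band_names, function(b) {
      loc <- matrix(base_loc, ns, n_edge)
      for (ef in effects) {
        if (ef$band != b) next
        pos <- edge_positions(ef$edges, n)
        for (g in names(ef$group_deltas)) {
          rows <- which(as.character(cohort$group) == g)
          loc[rows, pos] <- stats::qlogis(cfg$fc_base_mean +
                                            ef$group_deltas[[g]])
        }
      }
      w <- stats::plogis(loc + matrix(stats::rnorm(ns * n_edge,
                                                   sd = cfg$fc_logit_sd),
                                      ns, n_edge))
      a <- array(0, c(n, n, ns))
      for (s in seq_len(ns)) a[, , s] <- edge_matrix(w[s, ], n)
      a
    })
    names(mats) <- band_names
    bundle <- fc_bundle(mats, cohort$subject_id,
                        manifest = list(source = "simulate_fc_directly",
                                        seed = cfg$seed))
    list(bundle = bundle, cohort = cohort)
  })
}

#' Attach a hormone-like variable with a chosen partial correlation
#'
#' Adds a column `name` to the cohort constructed as
#' `a + b * m + noise`, where `m` is the mean network connectivity
#' residualized on the covariates and `b` is chosen so the population
#' partial correlation between the new variable and the connectivity,
#' given the covariates, equals `r_target`.
#'
#' @param cohort a cohort table.
#' @param mnc numeric vector of per-subject mean network connectivity
#'   aligned to `cohort` rows (or an object with an `mnc` field).
#' @param r_target target partial correlation, `|r_target| < 1`.
#' @param noise_sd residual standard deviation of the hormone variable.
#' @param seed integer seed.
#' @param name column name for the new variable.
#' @param covariates character vector of cohort columns to residualize on
#'   (NULL for a plain correlation target).
#' @param intercept location of the new variable.
#' @return the cohort with the new column. Deterministic given `seed`.
#' @export
attach_hormone <- function(cohort, mnc, r_target, noise_sd = 1, seed = 1,
                           name = "hormone",
                           covariates = c("age", "duration", "bmi", "side"),
                           intercept = 0) {
  if (abs(r_target) >= 1) stop("|r_target| must be < 1")
  if (is.list(mnc) && !is.null(mnc$mnc)) mnc <- mnc$mnc
  n <- nrow(cohort)
  if (length(mnc) != n) stop("mnc must align with cohort rows")
  X <- matrix(1, n, 1)
  if (!is.null(covariates) && length(covariates)) {
    miss <- setdiff(covariates, names(cohort))
    if (length(miss)) stop("covariate(s) not in cohort: ",
                           paste(miss, collapse = ", "))
    X <- cbind(X, as.matrix(cohort[, covariates, drop = FALSE]))
  }
  m <- stats::lsfit(X, mnc, intercept = FALSE)$residuals
  s_m <- stats::sd(m)
  if (s_m < .Machine$double.eps) stop("mnc has no residual variance")
  b <- r_target * noise_sd / (s_m * sqrt(1 - r_target^2))
  with_seed(seed, {
    cohort[[name]] <- intercept + b * m + stats::rnorm(n, 0, noise_sd)
  })
  cohort
}
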