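#' Frequency band definition
#'
#' @param name band label.
#' @param f_low,f_high band edges in Hz, `0 < f_low < f_high`.
#' @return a `band_definition` object.
#' @export
band_definition <- function(name, f_low, f_high) {
  if (!(f_low > 0 && f_high > f_low)) {
    stop("band edges must satisfy 0 < f_low < f_high")
  }
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "band_definition")
}

#' Canonical EEG bands
#'
#' theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, low gamma 30-45 Hz.
#'
#' @return named list of [band_definition()] objects.
#' @export
default_bands <- function() {
  list(theta     = band_definition("theta", 4, 8),
       alpha     = band_definition("alpha", 8, 13),
       beta      = band_definition("beta", 13, 30),
       low_gamma = band_definition("low_gamma", 30, 45))
}

#' Region-level time series container
#'
#' @param data numeric matrix, regions x samples; region order must match
#'   the atlas used downstream.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier.
#' @return a `region_timeseries` object.
#' @export
region_timeseries <- function(data, fs, subject_id = "s1") {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("non-finite values in time series")
  if (ncol(data) < fs) stop("time series must be at least 1 s long")
  structure(list(data = data, fs = fs, subject_id = subject_id),
            class = "region_timeseries")
}

#' Sliding-window specification for dynamic connectivity
#'
#' Defaults follow the analysis protocol: 1-s windows with 50 % overlap
#' inside 30-s epochs, six epochs (180 s) per recording.
#'
#' @param window_s window length in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @param epoch_s epoch length in seconds.
#' @param n_epochs number of consecutive epochs used.
#' @return a `window_spec` object.
#' @export
window_spec <- function(window_s = 1, overlap = 0.5, epoch_s = 30,
                        n_epochs = 6) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (window_s <= 0 || epoch_s <= 0 || n_epochs < 1) {
    stop("window_s, epoch_s must be positive; n_epochs >= 1")
  }
  structure(list(window_s = window_s, overlap = overlap,
                 epoch_s = epoch_s, n_epochs = n_epochs),
            class = "window_spec")
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]) over a reflect-padded copy of each region signal,
#' so the output is zero-phase and edge transients are pushed into the
#' padding, which is discarded.
#'
#' @param ts a [region_timeseries()].
#' @param band a [band_definition()].
#' @return filtered [region_timeseries()] of the same shape.
#' @export
bandpass <- function(ts, band) {
  stopifnot(inherits(ts, "region_timeseries"))
  fs <- ts$fs
  if (band$f_high >= fs / 2) {
    stop("band edge ", band$f_high, " Hz at or above Nyquist (fs = ", fs, ")")
  }
  bf <- signal::butter(4, c(band$f_low, band$f_high) / (fs / 2),
                       type = "pass")
  n <- ncol(ts$data)
  pad <- min(n - 1L, as.integer(3 * fs))
  out <- t(apply(ts$data, 1, function(x) {
    xp <- c(rev(x[seq_len(pad) + 1L]), x, x[n - seq_len(pad)])
    y <- signal::filtfilt(bf, xp)
    y[(pad + 1L):(pad + n)]
  }))
  region_timeseries(out, fs, ts$subject_id)
}

#' Analytic signal via the FFT half-spectrum construction
#'
#' Returns the complex analytic extension of each (band-limited) region
#' signal: the real part equals the input and the argument is the
#' instantaneous phase. Implemented by zeroing negative frequencies and
#' doubling positive ones in the discrete Fourier transform.
#'
#' @param ts a [region_timeseries()] (band-limited input expected).
#' @return complex matrix, regions x samples.
#' @export
analytic_signal <- function(ts) {
  stopifnot(inherits(ts, "region_timeseries"))
  x <- ts$data
  if (!all(is.finite(x))) stop("non-finite values in input")
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  ft <- t(apply(x, 1, stats::fft))
  if (nrow(x) == 1L) ft <- matrix(ft, nrow = 1L)
  z <- t(apply(sweep(ft, 2, h, `*`), 1,
               function(f) stats::fft(f, inverse = TRUE) / n))
  if (nrow(x) == 1L) z <- matrix(z, nrow = 1L)
  z
}

#' Dynamic weighted phase lag index on sliding windows
#'
#' For each window and region pair (i, j), wPLI is the modulus of the mean
#' imaginary cross-term divided by the mean modulus of the imaginary
#' cross-term over samples:
#' \deqn{wPLI_{ij} = \frac{|\,\mathrm{mean}_t\, \Im(z_i \bar z_j)\,|}
#'                       {\mathrm{mean}_t\, |\Im(z_i \bar z_j)|}}
#' Zero-lag (or identical) signals have all-zero imaginary cross-terms; by
#' convention the index is 0 when the denominator falls below `1e-12`,
#' which is what makes the measure insensitive to volume-conduction-like
#' instantaneous mixing.
#'
#' @param analytic complex matrix regions x samples (from
#'   [analytic_signal()]).
#' @param fs sampling rate in Hz.
#' @param spec a [window_spec()]; only `window_s` and `overlap` are used
#'   (epoch handling lives in [compute_fc()]).
#' @return 3-d array regions x regions x windows; each slice is symmetric,
#'   zero-diagonal, in \[0, 1\].
#' @export
dynamic_wpli <- function(analytic, fs, spec = window_spec()) {
  n_reg <- nrow(analytic)
  n_samp <- ncol(analytic)
  w <- as.integer(round(spec$window_s * fs))
  if (w < 8L) stop("window must span at least 8 samples")
  if (w > n_samp) stop("window longer than the data")
  step <- max(1L, as.integer(round(w * (1 - spec$overlap))))
  starts <- seq.int(1L, n_samp - w + 1L, by = step)
  out <- array(0, c(n_reg, n_reg, length(starts)))
  X <- Re(analytic)
  Y <- Im(analytic)
  for (k in seq_along(starts)) {
    sel <- starts[k]:(starts[k] + w - 1L)
    Xw <- X[, sel, drop = FALSE]
    Yw <- Y[, sel, drop = FALSE]
    # Im(z_i conj(z_j)) = Y_i X_j - X_i Y_j; numerator is antisymmetric so
    # one matrix product pair gives all pairs, the denominator needs the
    # per-sample modulus, done with one vectorized sweep per region row.
    num <- Yw %*% t(Xw) - Xw %*% t(Yw)
    den <- matrix(0, n_reg, n_reg)
    for (i in seq_len(n_reg)) {
      den[i, ] <- rowSums(abs(
        Xw * rep(Yw[i, ], each = n_reg) - Yw * rep(Xw[i, ], each = n_reg)))
    }
    m <- abs(num) / pmax(den, .Machine$double.eps)
    m[den < 1e-12 * w] <- 0
    diag(m) <- 0
    out[, , k] <- (m + t(m)) / 2
  }
  out
}

#' Average dynamic connectivity into a static matrix
#'
#' Element-wise arithmetic mean over all windows (pooled across epochs).
#'
#' @param windows 3-d array regions x regions x windows, or a list of such
#'   arrays (one per epoch), all with identical region dimensions.
#' @return symmetric static connectivity matrix.
#' @export
static_fc <- function(windows) {
  if (is.list(windows)) {
    dims <- vapply(windows, function(a) dim(a)[1], 0)
    if (length(unique(dims)) != 1L) {
      stop("inconsistent region dimension across epochs")
    }
    windows <- array(unlist(windows),
                     c(dim(windows[[1]])[1:2],
                       sum(vapply(windows, function(a) dim(a)[3], 0))))
  }
  if (dim(windows)[3] < 1L) stop("need at least one window")
  apply(windows, c(1, 2), mean)
}

#' Band-limited static connectivity for one subject
#'
#' Full per-subject pipeline: band-pass filter, analytic signal, dynamic
#' wPLI on overlapping windows within consecutive epochs, pooled average.
#' Up to `trim_s` seconds are trimmed from each end of the analytic signal
#' (when the recording is longer than the epoch budget) to suppress
#' residual filter transients.
#'
#' @param ts a [region_timeseries()].
#' @param bands named list of [band_definition()]s.
#' @param spec a [window_spec()].
#' @param trim_s maximum edge trim in seconds (actual trim is limited by
#'   the samples available beyond `n_epochs * epoch_s`).
#' @return named list of static connectivity matrices, one per band.
#' @export
compute_fc <- function(ts, bands = default_bands(), spec = window_spec(),
                       trim_s = 1) {
  stopifnot(inherits(ts, "region_timeseries"))
  fs <- ts$fs
  need <- as.integer(round(spec$n_epochs * spec$epoch_s * fs))
  n_samp <- ncol(ts$data)
  if (n_samp < need) {
    stop("recording shorter than n_epochs * epoch_s (",
         n_samp / fs, " s < ", need / fs, " s)")
  }
  trim <- min(as.integer(round(trim_s * fs)), (n_samp - need) %/% 2L)
  epoch_len <- as.integer(round(spec$epoch_s * fs))
  out <- lapply(bands, function(band) {
    z <- analytic_signal(bandpass(ts, band))
    z <- z[, (trim + 1L):(trim + need), drop = FALSE]
    per_epoch <- lapply(seq_len(spec$n_epochs), function(e) {
      sel <- ((e - 1L) * epoch_len + 1L):(e * epoch_len)
      dynamic_wpli(z[, sel, drop = FALSE], fs, spec)
    })
    static_fc(per_epoch)
  })
  names(out) <- vapply(bands, function(b) b$name, "")
  out
}

#' Static connectivity bundle for a cohort of recordings
#'
#' @param ts_list list of [region_timeseries()], one per subject.
#' @param bands named list of [band_definition()]s.
#' @param spec a [window_spec()].
#' @param trim_s see [compute_fc()].
#' @return an [fc_bundle()] with one matrix per (subject, band).
#' @export
compute_fc_bundle <- function(ts_list, bands = default_bands(),
                              spec = window_spec(), trim_s = 1) {
  subjects <- vapply(ts_list, function(t) t$subject_id, "")
  per_subj <- lapply(ts_list, compute_fc, bands = bands, spec = spec,
                     trim_s = trim_s)
  n <- nrow(ts_list[[1]]$data)
  band_names <- names(per_subj[[1]])
  mats <- lapply(band_names, function(b) {
    a <- array(0, c(n, n, length(subjects)))
    for (s in seq_along(subjects)) a[, , s] <- per_subj[[s]][[b]]
    a
  })
  names(mats) <- band_names
  fc_bundle(mats, subjects,
            manifest = list(source = "compute_fc_bundle",
                            window_s = spec$window_s,
                            overlap = spec$overlap,
                            epoch_s = spec$epoch_s,
                            n_epochs = spec$n_epochs))
}
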