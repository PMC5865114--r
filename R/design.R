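#' Canonical double-gamma hemodynamic response function
#'
#' Standard two-gamma HRF: response peak at 6 s, undershoot peaking at 16 s
#' with a 1/6 amplitude ratio, normalized to unit peak.
#'
#' @param t time in seconds (vector).
#' @param peak,undershoot gamma mode positions in seconds.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  # gamma densities parameterized by mode (shape a, rate b => mode (a-1)/b)
  b1 <- 1; b2 <- 1
  a1 <- peak * b1 + 1
  a2 <- undershoot * b2 + 1
  h <- stats::dgamma(t, shape = a1, rate = b1) -
    stats::dgamma(t, shape = a2, rate = b2) / ratio
  h[t < 0] <- 0
  # unit-peak normalization on a fine grid
  tt <- seq(0, 32, by = 0.01)
  hh <- stats::dgamma(tt, shape = a1, rate = b1) -
    stats::dgamma(tt, shape = a2, rate = b2) / ratio
  h / max(hh)
}

#' Event table constructor/validator
#'
#' @param onset onsets in seconds from the first retained scan.
#' @param duration durations in seconds (>= 0; 0 gives stick events).
#' @param condition condition labels.
#' @param trial_id optional per-trial identifiers (defaults to row order).
#' @return validated data.frame of class `event_table`.
#' @export
event_table <- function(onset, duration, condition, trial_id = NULL) {
  if (is.null(trial_id)) trial_id <- seq_along(onset)
  if (any(onset < 0)) stop("onsets must be nonnegative")
  if (any(duration < 0)) stop("durations must be nonnegative")
  ev <- data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
                   condition = as.character(condition),
                   trial_id = trial_id, stringsAsFactors = FALSE)
  for (cond in unique(ev$condition)) {
    o <- ev$onset[ev$condition == cond]
    if (is.unsorted(o, strictly = TRUE)) {
      stop("onsets must be strictly increasing within condition '", cond, "'")
    }
  }
  class(ev) <- c("event_table", "data.frame")
  ev
}

# boxcar (duration 0 -> stick) convolved with the canonical HRF, built on a
# fine grid and sampled at scan times; shared by the design builder and the
# BOLD simulator so noiseless recovery is exact. Boxcar bins are weighted by
# dt so the result approximates the continuous convolution integral
# independently of the microtime resolution; a duration-0 stick is a unit
# impulse, so a single stick reproduces the sampled HRF exactly.
convolve_events_hrf <- function(onsets, durations, tr, n_scans, dt = 0.1,
                                amplitudes = NULL) {
  run_len <- n_scans * tr
  n_fine <- ceiling(run_len / dt) + 1L
  x <- numeric(n_fine)
  if (is.null(amplitudes)) amplitudes <- rep(1, length(onsets))
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] / dt) + 1L
    if (durations[i] > 0) {
      i1 <- min(round((onsets[i] + durations[i]) / dt), n_fine)
      x[i0:i1] <- x[i0:i1] + amplitudes[i] * dt
    } else {
      x[i0] <- x[i0] + amplitudes[i]
    }
  }
  h <- canonical_hrf(seq(0, 48, by = dt))  # 48 s support: undershoot tail < 1e-7
  conv <- stats::convolve(x, rev(h), type = "open")[seq_len(n_fine)]
  scan_idx <- round((seq_len(n_scans) - 1L) * tr / dt) + 1L
  conv[scan_idx]
}

# discrete-cosine drift basis, SPM convention: K = floor(2*N*TR/cutoff) + 1
# columns including the constant term
cosine_drift <- function(n_scans, tr, highpass_s = 128) {
  K <- floor(2 * n_scans * tr / highpass_s) + 1L
  t <- seq_len(n_scans) - 1L
  X <- vapply(seq_len(K) - 1L, function(k) {
    if (k == 0L) rep(1 / sqrt(n_scans), n_scans)
    else sqrt(2 / n_scans) * cos(pi * k * (2 * t + 1) / (2 * n_scans))
  }, numeric(n_scans))
  dim(X) <- c(n_scans, K)
  colnames(X) <- c("constant", if (K > 1L) paste0("drift_", seq_len(K - 1L)))
  X
}

#' Build a GLM design matrix (canonical HRF or FIR basis)
#'
#' Constructs the first-level design for one run: either one column per
#' condition, the duration-boxcar convolved with the canonical double-gamma
#' HRF, or a 7-bin finite impulse response basis (one stick column per
#' condition and post-stimulus lag 0..6 TR, covering 0-15 s at TR 2.5 s).
#' A discrete-cosine drift set up to the high-pass cutoff (constant
#' included) is appended; high-pass filtering is thereby part of the model
#' rather than a preprocessing step.
#'
#' @param events an [event_table].
#' @param tr repetition time in seconds.
#' @param n_scans number of scans in the run.
#' @param basis `"canonical"` or `"fir"`.
#' @param fir_bins number of FIR bins (default 7).
#' @param highpass_s high-pass cutoff in seconds (default 128); `Inf`
#'   drops all drift columns except the constant.
#' @param dt microtime resolution in seconds for HRF convolution.
#' @return An object of class `design_matrix`: list with the matrix `X`
#'   (n_scans x n_regressors, named columns), `tr`, `basis`, `task_cols`
#'   (names of task columns), `conditions`.
#' @export
build_design_matrix <- function(events, tr, n_scans,
                                basis = c("canonical", "fir"),
                                fir_bins = 7L, highpass_s = 128, dt = 0.1) {
  basis <- match.arg(basis)
  stopifnot(tr > 0, n_scans >= 1)
  if (!inherits(events, "event_table")) {
    events <- event_table(events$onset, events$duration, events$condition,
                          events$trial_id)
  }
  run_len <- n_scans * tr
  if (any(events$onset >= run_len)) {
    stop("event onset at ", max(events$onset), " s beyond run end (",
         run_len, " s)")
  }
  conditions <- unique(events$condition)
  for (cond in conditions) {
    if (sum(events$condition == cond) == 0L)
      stop("condition with zero events: ", cond)
  }
  cols <- list()
  if (basis == "canonical") {
    for (cond in conditions) {
      ev <- events[events$condition == cond, , drop = FALSE]
      cols[[cond]] <- convolve_events_hrf(ev$onset, ev$duration, tr,
                                          n_scans, dt)
    }
  } else {
    for (cond in conditions) {
      ev <- events[events$condition == cond, , drop = FALSE]
      scan0 <- round(ev$onset / tr)  # nearest-scan bin assignment
      for (lag in seq_len(fir_bins) - 1L) {
        v <- numeric(n_scans)
        idx <- scan0 + lag + 1L
        idx <- idx[idx >= 1L & idx <= n_scans]
        v[idx] <- v[idx] + 1
        cols[[sprintf("%s_bin%d", cond, lag)]] <- v
      }
    }
  }
  Xtask <- do.call(cbind, cols)
  colnames(Xtask) <- names(cols)
  if (any(colSums(abs(Xtask)) == 0)) {
    stop("all-zero task column(s): ",
         paste(colnames(Xtask)[colSums(abs(Xtask)) == 0], collapse = ", "))
  }
  drift <- if (is.finite(highpass_s)) cosine_drift(n_scans, tr, highpass_s)
  else cosine_drift(n_scans, tr, 2 * n_scans * tr + 1)
  X <- cbind(Xtask, drift)
  structure(list(X = X, tr = tr, basis = basis, fir_bins = fir_bins,
                 highpass_s = highpass_s, task_cols = colnames(Xtask),
                 conditions = conditions, events = events),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " scans x ", ncol(x$X),
      " regressors (", x$basis, " basis, ", length(x$task_cols),
      " task columns, TR ", x$tr, " s)\n", sep = "")
  invisible(x)
}

#' Fit an ROI-level GLM, optionally with AR(1) prewhitening
#'
#' Ordinary least squares of a single (ROI-averaged) time series on a
#' design matrix. With `prewhiten_ar1 = TRUE` the lag-1 autocorrelation of
#' the OLS residuals is estimated once, both sides of the model are
#' filtered with the corresponding whitening transform (first sample scaled
#' by \eqn{\sqrt{1-\phi^2}}), and the model is refit; standard errors come
#' from the whitened fit.
#'
#' @param y numeric time series (length n_scans).
#' @param design a [design_matrix] (or plain numeric matrix).
#' @param prewhiten_ar1 logical; estimate and remove AR(1) serial
#'   correlation.
#' @return list with `betas`, `se`, `sigma2`, `df`, `phi` (0 when
#'   prewhitening is off), `residuals`, and the column names.
#' @export
fit_glm <- function(y, design, prewhiten_ar1 = FALSE) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (length(y) != nrow(X)) stop("series length does not match design rows")
  if (anyNA(y) || anyNA(X)) stop("missing values in series or design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  ols <- function(yy, XX) {
    fit <- stats::lm.fit(XX, yy)
    res <- fit$residuals
    df <- length(yy) - ncol(XX)
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qr(XX)))
    list(betas = fit$coefficients, se = sqrt(diag(XtXinv) * sigma2),
         sigma2 = sigma2, df = df, residuals = res)
  }
  fit <- ols(y, X)
  phi <- 0
  if (prewhiten_ar1) {
    r <- fit$residuals
    phi <- if (sum(r^2) > 0) sum(r[-1] * r[-length(r)]) / sum(r^2) else 0
    W_first <- sqrt(max(1 - phi^2, .Machine$double.eps))
    whiten <- function(v) {
      n <- length(v)
      c(v[1] * W_first, v[-1] - phi * v[-n])
    }
    yw <- whiten(y)
    Xw <- apply(X, 2, whiten)
    fit <- ols(yw, Xw)
  }
  names(fit$betas) <- names(fit$se) <- colnames(X)
  c(fit, list(phi = phi, names = colnames(X)))
}
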