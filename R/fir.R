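#' Deconvolve an ROI time course with an FIR basis
#'
#' Fits the 7-bin finite impulse response model (bin spacing = TR, covering
#' the first 15 s after stimulus onset at TR 2.5 s) to an ROI-averaged time
#' series, one response curve per condition. This estimates the shape of
#' the event-locked response without assuming a hemodynamic response
#' function, so differences in response shape across regions and
#' participants are preserved.
#'
#' @param y ROI-averaged time series.
#' @param events an [event_table].
#' @param tr repetition time in seconds.
#' @param fir_bins number of post-stimulus bins (default 7).
#' @param highpass_s high-pass cutoff in seconds.
#' @param prewhiten_ar1 logical, passed to [fit_glm()].
#' @return Object of class `fir_curve`: list with `estimates` and `se`
#'   (condition x bin matrices), `tr`, `bins_s` (bin centres in seconds).
#' @export
fit_fir <- function(y, events, tr, fir_bins = 7L, highpass_s = 128,
                    prewhiten_ar1 = FALSE) {
  dm <- build_design_matrix(events, tr, length(y), basis = "fir",
                            fir_bins = fir_bins, highpass_s = highpass_s)
  fit <- fit_glm(y, dm, prewhiten_ar1 = prewhiten_ar1)
  conds <- dm$conditions
  est <- se <- matrix(NA_real_, length(conds), fir_bins,
                      dimnames = list(conds, paste0("bin", seq_len(fir_bins) - 1L)))
  for (i in seq_along(conds)) {
    cn <- sprintf("%s_bin%d", conds[i], seq_len(fir_bins) - 1L)
    est[i, ] <- fit$betas[cn]
    se[i, ] <- fit$se[cn]
  }
  structure(list(estimates = est, se = se, tr = tr,
                 bins_s = (seq_len(fir_bins) - 1L) * tr),
            class = "fir_curve")
}

#' @export
print.fir_curve <- function(x, ...) {
  cat("<fir_curve> ", nrow(x$estimates), " condition(s) x ",
      ncol(x$estimates), " bins (", min(x$bins_s), "-", max(x$bins_s),
      " s)\n", sep = "")
  print(round(x$estimates, 3))
  invisible(x)
}

#' Group-defined peak window for FIR time courses
#'
#' Defines the peak response as the average over the FIR bins whose
#' condition-collapsed responses do not significantly (p > 0.05, paired
#' two-tailed t across participants, uncorrected) differ from the
#' numerically largest bin. The selected window is shared across conditions
#' and participants within an ROI; the per-participant, per-condition peak
#' value is then the mean of that condition's estimates over the selected
#' bins. With the study's timing this typically selects the 5 s and 7.5 s
#' bins in hippocampal ROIs.
#'
#' @param curves list of [fit_fir()] results, one per participant, with
#'   identical bin structure.
#' @param alpha significance level for the bin-vs-peak t-tests.
#' @return list with `selected_bins` (integer indices), `bins_s` (their
#'   latencies in seconds), `bin_p` (p-value of each bin vs the peak bin;
#'   NA at the peak itself), `peak_bin`, and `peak` (participant x
#'   condition matrix of peak values).
#' @export
fir_peak_window <- function(curves, alpha = 0.05) {
  if (length(curves) < 2L) stop("need at least 2 participants")
  nb <- ncol(curves[[1L]]$estimates)
  if (!all(vapply(curves, function(cv) ncol(cv$estimates) == nb, TRUE))) {
    stop("participants have differing bin structures")
  }
  # collapse conditions within participant
  collapsed <- t(vapply(curves, function(cv) colMeans(cv$estimates),
                        numeric(nb)))
  peak_bin <- which.max(colMeans(collapsed))
  bin_p <- rep(NA_real_, nb)
  for (b in seq_len(nb)[-peak_bin]) {
    d <- collapsed[, b] - collapsed[, peak_bin]
    if (stats::sd(d) == 0) {
      bin_p[b] <- if (all(d == 0)) 1 else 0
    } else {
      bin_p[b] <- stats::t.test(collapsed[, b], collapsed[, peak_bin],
                                paired = TRUE)$p.value
    }
  }
  selected <- sort(unique(c(peak_bin, which(bin_p > alpha))))
  conds <- rownames(curves[[1L]]$estimates)
  peak <- do.call(rbind, lapply(curves, function(cv)
    rowMeans(cv$estimates[, selected, drop = FALSE])))
  colnames(peak) <- conds
  list(selected_bins = selected, bins_s = curves[[1L]]$bins_s[selected],
       bin_p = bin_p, peak_bin = peak_bin, peak = peak)
}

#' Single-trial t-patterns (least-squares-all)
#'
#' Estimates one response amplitude per trial with all trial regressors in
#' a single GLM (least-squares-all), plus the cosine drift terms, and
#' converts each voxel's estimate to a t-value (beta / SE). The resulting
#' trials x voxels matrix is the input to the representational similarity
#' analysis.
#'
#' @param Y matrix of voxel time series (n_scans x n_voxels).
#' @param events an [event_table] with one row per trial.
#' @param tr repetition time in seconds.
#' @param highpass_s high-pass cutoff in seconds.
#' @param method `"lsa"` (all trials simultaneously, default) or `"lss"`
#'   (least-squares-separate: one model per trial, remaining trials
#'   aggregated into a single nuisance regressor).
#' @param dt microtime resolution for HRF convolution.
#' @return Object of class `trial_pattern_matrix`: t-value matrix
#'   (n_trials x n_voxels, rows ordered by onset) with a `labels`
#'   attribute (data.frame `trial_id`, `onset`, `condition`).
#' @export
single_trial_tmaps <- function(Y, events, tr, highpass_s = 128,
                               method = c("lsa", "lss"), dt = 0.1) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  if (!inherits(events, "event_table")) {
    events <- event_table(events$onset, events$duration, events$condition,
                          events$trial_id)
  }
  if (anyDuplicated(events$onset)) {
    stop("overlapping identical onsets: trials ",
         paste(events$trial_id[duplicated(events$onset)], collapse = ", "))
  }
  ord <- order(events$onset)
  events <- events[ord, , drop = FALSE]
  n_scans <- nrow(Y)
  n_trials <- nrow(events)
  drift <- cosine_drift(n_scans, tr, highpass_s)
  trial_reg <- sapply(seq_len(n_trials), function(i) {
    convolve_events_hrf(events$onset[i], events$duration[i], tr, n_scans, dt)
  })
  tmap_from_fit <- function(X, col) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("single-trial design is rank deficient")
    B <- qr.coef(qrX, Y)
    res <- Y - X %*% B
    df <- n_scans - ncol(X)
    sigma2 <- colSums(res^2) / df
    v <- chol2inv(qr.R(qrX))[col, col]
    B[col, ] / sqrt(v * sigma2)
  }
  if (method == "lsa") {
    X <- cbind(trial_reg, drift)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("single-trial design is rank deficient")
    B <- qr.coef(qrX, Y)
    res <- Y - X %*% B
    df <- n_scans - ncol(X)
    sigma2 <- colSums(res^2) / df
    vars <- diag(chol2inv(qr.R(qrX)))[seq_len(n_trials)]
    tmat <- B[seq_len(n_trials), , drop = FALSE] /
      sqrt(outer(vars, sigma2))
  } else {
    tmat <- t(vapply(seq_len(n_trials), function(i) {
      other <- rowSums(trial_reg[, -i, drop = FALSE])
      tmap_from_fit(cbind(trial_reg[, i], other, drift), 1L)
    }, numeric(ncol(Y))))
  }
  labels <- data.frame(trial_id = events$trial_id, onset = events$onset,
                       condition = events$condition, stringsAsFactors = FALSE)
  structure(tmat, labels = labels, class = c("trial_pattern_matrix", "matrix"))
}

#' Build a generalized PPI model
#'
#' Constructs the generalized psychophysiological interaction design for a
#' seed region: for each task condition an interaction regressor is formed
#' as the product of the condition's unconvolved boxcar indicator (sampled
#' at TR) and the mean-centred seed time course, then convolved with the
#' canonical HRF. The model contains the HRF-convolved psychological
#' regressors, one interaction per condition, the raw seed time course, and
#' the cosine drift terms.
#'
#' @param seed seed-region time series (ROI mean), length n_scans.
#' @param events an [event_table] with the task conditions.
#' @param tr repetition time in seconds.
#' @param highpass_s high-pass cutoff in seconds.
#' @param dt microtime resolution for HRF convolution of the psychological
#'   regressors.
#' @return Object of class `ppi_model`: list with the full design matrix
#'   `X`, `interaction_cols`, `psych_cols`, and a `collinear` character
#'   vector naming near-collinear interaction columns (empty when none).
#' @export
build_gppi_model <- function(seed, events, tr, highpass_s = 128, dt = 0.1) {
  if (!inherits(events, "event_table")) {
    events <- event_table(events$onset, events$duration, events$condition,
                          events$trial_id)
  }
  n_scans <- length(seed)
  dm <- build_design_matrix(events, tr, n_scans, basis = "canonical",
                            highpass_s = highpass_s, dt = dt)
  conds <- dm$conditions
  seed_c <- seed - mean(seed)
  scan_t <- (seq_len(n_scans) - 1L) * tr
  h <- canonical_hrf(seq(0, 48, by = tr))
  inter <- sapply(conds, function(cond) {
    ev <- events[events$condition == cond, , drop = FALSE]
    box <- numeric(n_scans)
    for (i in seq_len(nrow(ev))) {
      on <- ev$onset[i]
      off <- on + max(ev$duration[i], tr / 2)
      box[scan_t >= on & scan_t < off] <- 1
    }
    neural <- box * seed_c
    stats::convolve(neural, rev(h), type = "open")[seq_len(n_scans)]
  })
  colnames(inter) <- paste0("ppi_", conds)
  psych <- dm$X[, dm$task_cols, drop = FALSE]
  drift <- dm$X[, setdiff(colnames(dm$X), dm$task_cols), drop = FALSE]
  X <- cbind(psych, inter, seed = seed, drift)
  # flag interactions indistinguishable from the seed's own hemodynamic
  # response or from the psychological regressors (degenerate designs,
  # e.g. one condition spanning the whole run)
  conv_seed <- stats::convolve(seed_c, rev(h), type = "open")[seq_len(n_scans)]
  collinear <- character()
  for (cn in colnames(inter)) {
    v <- inter[, cn]
    if (stats::sd(v) == 0) next
    others <- cbind(psych, seed = seed, conv_seed = conv_seed)
    rr <- abs(stats::cor(v, others))
    if (any(rr > 0.999, na.rm = TRUE)) collinear <- c(collinear, cn)
  }
  structure(list(X = X, tr = tr, conditions = conds,
                 interaction_cols = colnames(inter),
                 psych_cols = dm$task_cols, collinear = collinear),
            class = "ppi_model")
}

#' Fit a gPPI model to a target ROI
#'
#' @param target target-ROI time series.
#' @param model a [build_gppi_model()] result.
#' @param prewhiten_ar1 logical, passed to [fit_glm()].
#' @return data.frame with one row per condition: interaction `beta`, `se`,
#'   `t`.
#' @export
fit_gppi <- function(target, model, prewhiten_ar1 = FALSE) {
  stopifnot(inherits(model, "ppi_model"))
  fit <- fit_glm(target, model$X, prewhiten_ar1 = prewhiten_ar1)
  cn <- model$interaction_cols
  data.frame(condition = model$conditions, beta = unname(fit$betas[cn]),
             se = unname(fit$se[cn]),
             t = unname(fit$betas[cn] / fit$se[cn]),
             stringsAsFactors = FALSE)
}

#' Hippocampal long-axis label from an MNI Y coordinate
#'
#' Splits the hippocampus into three segments of approximately equal length
#' along the anterior-posterior axis by MNI Y coordinate: posterior (pHC)
#' Y in [-40, -30], middle (mHC) Y in [-29, -19], anterior (aHC) Y in
#' [-18, -4]; anything else is labelled `outside`. Intervals are inclusive.
#'
#' @param y_mni MNI Y coordinate(s) in millimetres.
#' @return character vector with values in `{"aHC","mHC","pHC","outside"}`.
#' @export
long_axis_label <- function(y_mni) {
  if (any(!is.finite(y_mni))) stop("y coordinates must be finite")
  out <- rep("outside", length(y_mni))
  out[y_mni >= -40 & y_mni <= -30] <- "pHC"
  out[y_mni >= -29 & y_mni <= -19] <- "mHC"
  out[y_mni >= -18 & y_mni <= -4] <- "aHC"
  out
}

#' Relabel events by response and confidence
#'
#' Recodes the six picture-type conditions into the five
#' behavior-conditioned regressors used to compare high- and low-confidence
#' hits: high-confidence hits (confidence 3), low-confidence hits
#' (confidence 0-2), related correct rejections, novel correct rejections,
#' and all incorrect answers (misses, related and novel false alarms, and
#' trials without a press).
#'
#' @param events an [event_table] whose `trial_id` values match
#'   `responses$picture_id`.
#' @param responses trial data.frame with `picture_id`, `picture_type`,
#'   `response`, `confidence`.
#' @return A relabelled [event_table] with conditions in
#'   `{"high_conf_hit","low_conf_hit","related_cr","novel_cr","incorrect"}`.
#' @export
relabel_events_by_confidence <- function(events, responses) {
  if (!inherits(events, "event_table")) {
    events <- event_table(events$onset, events$duration, events$condition,
                          events$trial_id)
  }
  idx <- match(events$trial_id, responses$picture_id)
  if (anyNA(idx)) {
    stop("event trial(s) with no matching response record: ",
         paste(events$trial_id[is.na(idx)], collapse = ", "))
  }
  ty <- responses$picture_type[idx]
  rs <- responses$response[idx]
  cf <- responses$confidence[idx]
  lab <- rep("incorrect", nrow(events))
  hit <- ty == "old" & rs == "yes"
  lab[hit & cf == 3] <- "high_conf_hit"
  lab[hit & cf < 3] <- "low_conf_hit"
  lab[ty == "related" & rs == "no"] <- "related_cr"
  lab[ty == "novel" & rs == "no"] <- "novel_cr"
  out <- events
  out$condition <- lab
  class(out) <- c("event_table", "data.frame")
  out
}
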