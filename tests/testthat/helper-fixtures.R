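# shared fixture builders (all data generated in code)

# minimal trial row
trial_row <- function(picture_id, picture_type, response, confidence = NA,
                      pair_id = NA, emotion = "neutral") {
  data.frame(picture_id = picture_id, pair_id = pair_id,
             picture_type = picture_type, emotion = emotion,
             response = response, confidence = confidence,
             stringsAsFactors = FALSE)
}

# subject with n_pairs pairs in given (old_resp, rel_resp) states plus novels
toy_subject <- function(pairs, novels = NULL, id = "s1", group = "1d") {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pid <- sprintf("p%03d", i)
    rows[[length(rows) + 1L]] <- trial_row(
      paste0(pid, "_old"), "old", pairs$old_resp[i],
      confidence = if (pairs$old_resp[i] == "yes") pairs$old_conf[i] else NA,
      pair_id = pid,
      emotion = if ("emotion" %in% names(pairs)) pairs$emotion[i] else "neutral")
    rows[[length(rows) + 1L]] <- trial_row(
      paste0(pid, "_rel"), "related", pairs$rel_resp[i],
      confidence = if (pairs$rel_resp[i] == "yes") 1 else NA,
      pair_id = pid,
      emotion = if ("emotion" %in% names(pairs)) pairs$emotion[i] else "neutral")
  }
  if (!is.null(novels)) {
    for (i in seq_len(nrow(novels))) {
      rows[[length(rows) + 1L]] <- trial_row(
        sprintf("n%03d", i), "novel", novels$response[i],
        confidence = if (novels$response[i] == "yes") 0 else NA)
    }
  }
  subject_behavior(id, group, do.call(rbind, rows))
}

# subject scoring the confidence ceiling: 60 hits all rated 3
ceiling_subject <- function() {
  pairs <- data.frame(old_resp = rep("yes", 60), old_conf = rep(3, 60),
                      rel_resp = rep("no", 60), stringsAsFactors = FALSE)
  toy_subject(pairs)
}

# small, fast config for BOLD-level tests
quick_cfg <- function(...) {
  sim_config(n_scans = 200L, n_voxels = 30L, ...)
}

# trivariate normal sample with given 3x3 correlation matrix
rmvnorm3 <- function(n, R) {
  Z <- matrix(stats::rnorm(n * 3), n, 3)
  Z %*% chol(R)
}

# hand-built fir_curve
fake_curve <- function(est, conds = "pic") {
  est <- matrix(est, nrow = length(conds), byrow = TRUE)
  rownames(est) <- conds
  colnames(est) <- paste0("bin", seq_len(ncol(est)) - 1L)
  structure(list(estimates = est, se = est * 0 + 1, tr = 2.5,
                 bins_s = (seq_len(ncol(est)) - 1L) * 2.5),
            class = "fir_curve")
}
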