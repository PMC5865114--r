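#' Simulation configuration
#'
#' Collects the free parameters of the synthetic cohort: group sizes, the
#' per-group memory-state distribution (probability that a studied
#' picture/lure pair is retained in detail, transformed to gist, or
#' forgotten), response and confidence behavior, the latent-pattern model
#' for the hippocampal-like ROIs, and the BOLD acquisition/noise model.
#' Defaults emulate the study conditions: 24 subjects per delay group, 60
#' old/related pairs plus 60 novel pictures (half negative, half neutral),
#' TR 2.5 s, 832 retained scans, pictures shown 3.5 s with jittered 7 +/- 2
#' s fixation intervals. The state probabilities are free parameters chosen
#' to reproduce the qualitative delay effect (fewer detailed, more
#' transformed and forgotten pairs after 28 days).
#'
#' @param n_per_group subjects per delay group.
#' @param n_pairs number of old/related picture pairs (60).
#' @param n_novel number of novel pictures (60).
#' @param state_probs named list (`"1d"`, `"28d"`) of probability triples
#'   `(p_detailed, p_transformed, p_forgotten)`, each summing to 1.
#' @param emotion_shift additive log-odds shift (detailed as reference) of
#'   the transformed and forgotten probabilities for negative pairs.
#' @param p_old_yes_gist probability that the old picture is also endorsed
#'   when only the gist is retained.
#' @param p_fa_novel false-alarm probability on novel pictures.
#' @param p_no_response probability a trial receives no button press.
#' @param conf_probs named list of confidence distributions over ratings
#'   0..3 for `detailed` hits, `gist` endorsements, and `novel` false
#'   alarms.
#' @param gist_weight named nonnegative vector: weight `a` of the
#'   pair-shared gist component per ROI.
#' @param item_weight nonnegative weight `b` of the trial-unique component.
#' @param pattern_noise_sd SD of the i.i.d. Gaussian voxel noise.
#' @param n_voxels voxels per ROI.
#' @param tr_seconds repetition time (s).
#' @param n_scans retained scans per run.
#' @param picture_duration_s picture presentation time (s).
#' @param iti_mean,iti_jitter mean and half-range of the uniform jittered
#'   inter-trial fixation (s).
#' @param ar1_phi AR(1) coefficient of the BOLD noise, in (-1, 1).
#' @param bold_noise_sd innovation SD of the BOLD noise.
#' @param drift_amplitude amplitude of the low-frequency scanner drift.
#' @param rng_seed master seed; subject k draws from a stream seeded at a
#'   fixed offset from it, so any subject is reproducible in isolation.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 24L, n_pairs = 60L, n_novel = 60L,
                       state_probs = list(
                         "1d" = c(0.70, 0.15, 0.15),
                         "28d" = c(0.30, 0.35, 0.35)),
                       emotion_shift = 0.25,
                       p_old_yes_gist = 0.5,
                       p_fa_novel = 0.05,
                       p_no_response = 0,
                       conf_probs = list(
                         detailed = c(0, 0.05, 0.15, 0.80),
                         gist = c(0.10, 0.40, 0.40, 0.10),
                         novel = c(0.60, 0.30, 0.10, 0)),
                       gist_weight = c(aHC = 1.0, mHC = 0.7, pHC = 0.4),
                       item_weight = 1, pattern_noise_sd = 1,
                       n_voxels = 100L,
                       tr_seconds = 2.5, n_scans = 832L,
                       picture_duration_s = 3.5,
                       iti_mean = 7, iti_jitter = 2,
                       ar1_phi = 0.3, bold_noise_sd = 1,
                       drift_amplitude = 1, rng_seed = 42L) {
  for (g in names(state_probs)) {
    p <- state_probs[[g]]
    if (length(p) != 3L || any(p < 0) || any(p > 1)) {
      stop("state_probs[['", g, "']] must be three probabilities in [0,1]")
    }
    if (abs(sum(p) - 1) > 1e-12) {
      stop("state_probs[['", g, "']] must sum to 1 (got ", sum(p), ")")
    }
  }
  if (any(gist_weight < 0) || item_weight < 0 || pattern_noise_sd < 0) {
    stop("gist_weight, item_weight and pattern_noise_sd must be nonnegative")
  }
  if (abs(ar1_phi) >= 1) stop("ar1_phi must lie in (-1, 1)")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  for (nm in names(conf_probs)) {
    p <- conf_probs[[nm]]
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("conf_probs[['", nm, "']] must be 4 probabilities summing to 1")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

subject_seed <- function(config, k) {
  (as.integer(config$rng_seed) + 7919L * as.integer(k)) %% 2147483647L
}

#' Draw memory states for all picture pairs
#'
#' Assigns each of the `n_pairs` old/related pairs one latent memory state
#' (`detailed`, `gist`, `forgotten`) from the group's categorical
#' distribution. For negative pairs the transformed/forgotten log-odds
#' (relative to detailed) are shifted by `emotion_shift` before
#' normalization. Uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param config a [sim_config()].
#' @param group `"1d"` or `"28d"`.
#' @return data.frame with `pair_id`, `emotion`, `state`.
#' @export
simulate_memory_states <- function(config, group) {
  stopifnot(inherits(config, "sim_config"))
  if (!group %in% names(config$state_probs)) {
    stop("unknown group key: ", group, " (expected one of ",
         paste(names(config$state_probs), collapse = ", "), ")")
  }
  p <- config$state_probs[[group]]
  n <- config$n_pairs
  emotion <- rep(c("negative", "neutral"), length.out = n)
  shift_probs <- function(p, s) {
    # multinomial-logit shift, detailed as reference
    w <- c(p[1], p[2] * exp(s), p[3] * exp(s))
    w / sum(w)
  }
  states <- character(n)
  lv <- c("detailed", "gist", "forgotten")
  for (i in seq_len(n)) {
    pi <- if (emotion[i] == "negative")
      shift_probs(p, config$emotion_shift) else p
    states[i] <- sample(lv, 1L, prob = pi)
  }
  data.frame(pair_id = sprintf("pair%03d", seq_len(n)), emotion = emotion,
             state = states, stringsAsFactors = FALSE)
}

sample_conf <- function(probs) sample(0:3, 1L, prob = probs)

#' Generate recognition responses from latent memory states
#'
#' Translates pair states into button presses: a detailed pair yields a
#' confident "yes" to the old picture and a correct rejection of the lure;
#' a gist pair yields a "yes" to the related lure (and, with probability
#' `p_old_yes_gist`, also to the old picture); a forgotten pair yields "no"
#' to both. Novel pictures draw a false alarm with probability
#' `p_fa_novel`. Confidence ratings are sampled from the per-state
#' distributions; trial order is randomized.
#'
#' @param states output of [simulate_memory_states()].
#' @param config a [sim_config()].
#' @return data.frame of trials (`picture_id`, `pair_id`, `picture_type`,
#'   `emotion`, `response`, `confidence`) in randomized presentation order.
#' @export
generate_responses <- function(states, config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  answer <- function(p_yes, conf_probs) {
    if (stats::runif(1) < config$p_no_response) {
      return(list(resp = "none", conf = NA_integer_))
    }
    if (stats::runif(1) < p_yes) {
      list(resp = "yes", conf = sample_conf(conf_probs))
    } else list(resp = "no", conf = NA_integer_)
  }
  for (i in seq_len(nrow(states))) {
    st <- states$state[i]
    old_ans <- switch(st,
      detailed = answer(1, config$conf_probs$detailed),
      gist = answer(config$p_old_yes_gist, config$conf_probs$gist),
      forgotten = answer(0, config$conf_probs$gist))
    rel_ans <- switch(st,
      detailed = answer(0, config$conf_probs$gist),
      gist = answer(1, config$conf_probs$gist),
      forgotten = answer(0, config$conf_probs$gist))
    rows[[length(rows) + 1L]] <- data.frame(
      picture_id = paste0(states$pair_id[i], "_old"),
      pair_id = states$pair_id[i], picture_type = "old",
      emotion = states$emotion[i], response = old_ans$resp,
      confidence = old_ans$conf, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      picture_id = paste0(states$pair_id[i], "_rel"),
      pair_id = states$pair_id[i], picture_type = "related",
      emotion = states$emotion[i], response = rel_ans$resp,
      confidence = rel_ans$conf, stringsAsFactors = FALSE)
  }
  nov_emotion <- rep(c("negative", "neutral"), length.out = config$n_novel)
  for (i in seq_len(config$n_novel)) {
    ans <- answer(config$p_fa_novel, config$conf_probs$novel)
    rows[[length(rows) + 1L]] <- data.frame(
      picture_id = sprintf("novel%03d", i), pair_id = NA_character_,
      picture_type = "novel", emotion = nov_emotion[i],
      response = ans$resp, confidence = ans$conf, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate voxel patterns for one ROI
#'
#' Simulates the trials x voxels activity patterns underlying the RSA:
#' \deqn{pattern(trial) = a\,g + b\,u + \epsilon}
#' with `g` a latent component shared according to `sharing`, `u` a
#' trial-unique component, and i.i.d. Gaussian voxel noise. Under
#' `sharing = "pair"` (the gist-sharing structure) an old picture and its
#' related lure share `g`, so their expected pattern correlation is
#' \eqn{a^2 / (a^2 + b^2 + \sigma^2)}; novel trials get unique `g`. Under
#' `sharing = "old"` all old trials share one common `g` while related and
#' novel trials get unique ones (the structure the "Old Distinct"
#' hypothesis describes).
#'
#' @param trials trial table from [generate_responses()] (row order defines
#'   pattern row order).
#' @param config a [sim_config()].
#' @param roi_label name of the ROI (must index `config$gist_weight`).
#' @param sharing `"pair"` or `"old"`.
#' @return `trial_pattern_matrix` (trials x voxels) with a `labels`
#'   attribute (`trial_id`, `condition`, `picture_type`, `emotion`,
#'   `pair_id`).
#' @export
generate_patterns <- function(trials, config, roi_label = "aHC",
                              sharing = c("pair", "old")) {
  stopifnot(inherits(config, "sim_config"))
  sharing <- match.arg(sharing)
  nv <- config$n_voxels
  if (nv < 2L) stop("n_voxels must be at least 2 (correlation undefined)")
  if (!roi_label %in% names(config$gist_weight)) {
    stop("unknown ROI label: ", roi_label)
  }
  a <- config$gist_weight[[roi_label]]
  b <- config$item_weight
  sg <- config$pattern_noise_sd
  n <- nrow(trials)
  key <- if (sharing == "pair") {
    ifelse(trials$picture_type %in% c("old", "related"),
           trials$pair_id, trials$picture_id)
  } else {
    ifelse(trials$picture_type == "old", ".shared_old", trials$picture_id)
  }
  g_pool <- matrix(stats::rnorm(length(unique(key)) * nv), ncol = nv,
                   dimnames = list(unique(key), NULL))
  P <- matrix(NA_real_, n, nv)
  for (i in seq_len(n)) {
    P[i, ] <- a * g_pool[key[i], ] + b * stats::rnorm(nv) +
      stats::rnorm(nv, sd = sg)
  }
  labels <- data.frame(trial_id = trials$picture_id,
                       condition = paste(trials$picture_type, trials$emotion,
                                         sep = "_"),
                       picture_type = trials$picture_type,
                       emotion = trials$emotion, pair_id = trials$pair_id,
                       stringsAsFactors = FALSE)
  structure(P, labels = labels, class = c("trial_pattern_matrix", "matrix"))
}

#' Event table for one simulated recognition run
#'
#' Lays the trials out in presentation order with the picture duration and
#' jittered uniform inter-trial fixation intervals; conditions are the
#' picture type x emotion combinations.
#'
#' @param trials trial table from [generate_responses()].
#' @param config a [sim_config()].
#' @param start_s onset of the first trial (s).
#' @return an [event_table] with `trial_id` set to the picture ids.
#' @export
simulate_events <- function(trials, config, start_s = 4) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(trials)
  iti <- stats::runif(n, config$iti_mean - config$iti_jitter,
                      config$iti_mean + config$iti_jitter)
  onsets <- start_s + cumsum(c(0, (config$picture_duration_s + iti)[-n]))
  run_len <- config$n_scans * config$tr_seconds
  if (max(onsets) + config$picture_duration_s > run_len) {
    stop("events exceed run length (", run_len, " s)")
  }
  ev <- data.frame(onset = onsets,
                   duration = rep(config$picture_duration_s, n),
                   condition = paste(trials$picture_type, trials$emotion,
                                     sep = "_"),
                   trial_id = trials$picture_id, stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Simulate an ROI-averaged BOLD time series
#'
#' Sums per-condition responses (duration-boxcars convolved with the
#' canonical HRF, scaled by the condition amplitude), a slow sinusoidal
#' scanner drift with random phase, and stationary AR(1) Gaussian noise,
#' sampled at the TR.
#'
#' @param events an [event_table].
#' @param amplitudes named numeric vector, one amplitude per condition in
#'   `events`.
#' @param config a [sim_config()].
#' @return numeric vector of length `config$n_scans`.
#' @export
generate_bold <- function(events, amplitudes, config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$tr_seconds
  n_scans <- config$n_scans
  if (any(events$onset >= n_scans * tr)) {
    stop("event onset beyond scan duration")
  }
  conds <- unique(events$condition)
  miss <- setdiff(conds, names(amplitudes))
  if (length(miss) > 0L) {
    stop("no amplitude for condition(s): ", paste(miss, collapse = ", "))
  }
  y <- numeric(n_scans)
  for (cond in conds) {
    ev <- events[events$condition == cond, , drop = FALSE]
    y <- y + amplitudes[[cond]] *
      convolve_events_hrf(ev$onset, ev$duration, tr, n_scans)
  }
  t_s <- (seq_len(n_scans) - 1L) * tr
  if (config$drift_amplitude != 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    y <- y + config$drift_amplitude *
      (cos(2 * pi * t_s / 300 + ph[1]) + 0.5 * cos(2 * pi * t_s / 180 + ph[2]))
  }
  if (config$bold_noise_sd > 0) {
    phi <- config$ar1_phi
    e <- numeric(n_scans)
    e[1] <- stats::rnorm(1, sd = config$bold_noise_sd / sqrt(1 - phi^2))
    innov <- stats::rnorm(n_scans - 1L, sd = config$bold_noise_sd)
    for (i in 2:n_scans) e[i] <- phi * e[i - 1L] + innov[i - 1L]
    y <- y + e
  }
  y
}

#' Simulate one complete subject
#'
#' Draws the subject's RNG stream from the master seed, then generates
#' memory states, recognition responses, the run's event table, and voxel
#' patterns for each configured ROI.
#'
#' @param config a [sim_config()].
#' @param group `"1d"` or `"28d"`.
#' @param k subject index (drives the per-subject seed offset).
#' @param subject_id identifier (default `"s<k>"`).
#' @param patterns logical; also simulate ROI voxel patterns.
#' @return list with `behavior` (a [subject_behavior]), `states`, `events`,
#'   and (optionally) `patterns` (named list of `trial_pattern_matrix` per
#'   ROI).
#' @export
simulate_subject <- function(config, group, k, subject_id = NULL,
                             patterns = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(subject_id)) subject_id <- sprintf("s%02d", k)
  set.seed(subject_seed(config, k))
  states <- simulate_memory_states(config, group)
  trials <- generate_responses(states, config)
  beh <- subject_behavior(subject_id, group, trials)
  events <- simulate_events(trials, config)
  pats <- NULL
  if (patterns) {
    pats <- lapply(stats::setNames(nm = names(config$gist_weight)),
                   function(roi) generate_patterns(trials, config, roi))
  }
  list(subject_id = subject_id, group = group, behavior = beh,
       states = states, events = events, patterns = pats)
}

#' Simulate the full two-group cohort
#'
#' @param config a [sim_config()].
#' @param patterns logical; simulate ROI voxel patterns per subject.
#' @return list of [simulate_subject()] results, `1d` subjects first.
#' @export
simulate_study <- function(config, patterns = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  groups <- rep(c("1d", "28d"), each = config$n_per_group)
  lapply(seq_along(groups), function(k) {
    simulate_subject(config, groups[k], k,
                     subject_id = sprintf("%s_s%02d", groups[k],
                                          ((k - 1L) %% config$n_per_group) + 1L),
                     patterns = patterns)
  })
}
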