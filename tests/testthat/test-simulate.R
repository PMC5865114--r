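test_that("memory states follow the group's categorical distribution", {
  cfg <- sim_config(state_probs = list("1d" = c(1, 0, 0),
                                       "28d" = c(0.3, 0.35, 0.35)))
  set.seed(1)
  st <- simulate_memory_states(cfg, "1d")
  expect_true(all(st$state == "detailed"))
  expect_identical(nrow(st), 60L)

  # same seed, same sequence
  set.seed(99); a <- simulate_memory_states(cfg, "28d")
  set.seed(99); b <- simulate_memory_states(cfg, "28d")
  expect_identical(a, b)

  expect_error(simulate_memory_states(cfg, "7d"), "unknown group")
  expect_error(sim_config(state_probs = list("1d" = c(0.5, 0.3, 0.1),
                                             "28d" = c(0.3, 0.35, 0.35))),
               "sum to 1")
})

test_that("state frequencies match the binomial oracle at large n", {
  p <- c(0.5, 0.3, 0.2)
  cfg <- sim_config(n_pairs = 10000L, emotion_shift = 0,
                    state_probs = list("1d" = p, "28d" = p))
  set.seed(42)
  st <- simulate_memory_states(cfg, "1d")
  freq <- table(factor(st$state, c("detailed", "gist", "forgotten"))) / 10000
  for (i in 1:3) {
    se <- sqrt(p[i] * (1 - p[i]) / 10000)
    expect_lt(abs(freq[[i]] - p[i]), 3 * se)
  }
})

test_that("emotion shift moves negative pairs toward gist/forgetting", {
  cfg <- sim_config(n_pairs = 20000L, emotion_shift = 1,
                    state_probs = list("1d" = c(0.6, 0.2, 0.2),
                                       "28d" = c(0.3, 0.35, 0.35)))
  set.seed(8)
  st <- simulate_memory_states(cfg, "1d")
  p_det <- tapply(st$state == "detailed", st$emotion, mean)
  expect_lt(p_det[["negative"]], p_det[["neutral"]])
})

test_that("responses reflect the planted states deterministically", {
  cfg <- sim_config(p_fa_novel = 0, p_old_yes_gist = 0)
  all_det <- data.frame(pair_id = sprintf("p%02d", 1:60),
                        emotion = "neutral", state = "detailed")
  set.seed(2)
  s <- subject_behavior("s", "1d", generate_responses(all_det, cfg))
  r <- score_recognition(s)
  expect_equal(r$hit_pct, 100)
  expect_equal(r$fa_related_pct, 0)
  expect_equal(r$fa_novel_pct, 0)

  all_gist <- within(all_det, state <- "gist")
  set.seed(3)
  s2 <- subject_behavior("s", "1d", generate_responses(all_gist, cfg))
  r2 <- score_recognition(s2)
  expect_equal(r2$fa_related_pct, 100)
  expect_equal(r2$hit_pct, 0)
})

test_that("categorize_pairs recovers planted state counts (round trip)", {
  cfg <- sim_config()   # p_no_response = 0 by default
  set.seed(11)
  for (group in c("1d", "28d")) {
    st <- simulate_memory_states(cfg, group)
    s <- subject_behavior("s", group, generate_responses(st, cfg))
    counts <- attr(categorize_pairs(s), "counts")
    planted <- table(factor(st$state, c("detailed", "gist", "forgotten")))
    expect_identical(counts[["detailed"]], unname(planted[["detailed"]]))
    expect_identical(counts[["transformed"]], unname(planted[["gist"]]))
    expect_identical(counts[["forgotten"]], unname(planted[["forgotten"]]))
    expect_identical(counts[["unclassified"]], 0L)
  }
})

test_that("pattern model matches its closed-form correlation expectation", {
  # identical patterns when only the gist component is present
  cfg0 <- sim_config(gist_weight = c(aHC = 1), item_weight = 0,
                     pattern_noise_sd = 0, n_voxels = 40)
  st <- data.frame(pair_id = sprintf("p%02d", 1:10), emotion = "neutral",
                   state = "detailed")
  set.seed(4)
  tr <- generate_responses(st, cfg0)
  P <- generate_patterns(tr, cfg0, "aHC")
  D <- compute_rdm(P)
  lab <- attr(P, "labels")
  for (pid in st$pair_id) {
    i <- which(lab$pair_id == pid & lab$picture_type == "old")
    j <- which(lab$pair_id == pid & lab$picture_type == "related")
    expect_lt(abs(D[i, j]), 1e-12)
  }

  # a = 0: all trials independent, mean off-diagonal distance ~ 1
  cfg_a0 <- sim_config(gist_weight = c(aHC = 0), n_voxels = 100)
  set.seed(5)
  P0 <- generate_patterns(generate_responses(st, cfg_a0), cfg_a0, "aHC")
  D0 <- compute_rdm(P0)
  off <- D0[lower.tri(D0)]
  expect_lt(abs(mean(off) - 1), 3 * stats::sd(off) / sqrt(length(off)))

  # a = b = sigma = 1, 500 voxels: own-lure r ~ 1/3
  cfg1 <- sim_config(gist_weight = c(aHC = 1), item_weight = 1,
                     pattern_noise_sd = 1, n_voxels = 500)
  st60 <- data.frame(pair_id = sprintf("p%02d", 1:60), emotion = "neutral",
                     state = "detailed")
  set.seed(6)
  tr1 <- generate_responses(st60, cfg1)
  P1 <- generate_patterns(tr1, cfg1, "aHC")
  lab1 <- attr(P1, "labels")
  rs <- vapply(st60$pair_id, function(pid) {
    i <- which(lab1$pair_id == pid & lab1$picture_type == "old")
    j <- which(lab1$pair_id == pid & lab1$picture_type == "related")
    stats::cor(P1[i, ], P1[j, ])
  }, 1)
  expect_lt(abs(mean(rs) - 1 / 3), 3 * stats::sd(rs) / sqrt(length(rs)))
})

test_that("own-lure similarity increases monotonically with gist weight", {
  grid <- c(0.3, 1, 3)
  means <- vapply(seq_along(grid), function(gi) {
    cfg <- sim_config(gist_weight = c(aHC = grid[gi]), n_voxels = 60,
                      n_pairs = 30L, n_novel = 0L)
    set.seed(500 + gi)
    mean(replicate(30, {
      st <- simulate_memory_states(cfg, "1d")
      tr <- generate_responses(st, cfg)
      P <- generate_patterns(tr, cfg, "aHC")
      lab <- attr(P, "labels")
      mean(vapply(st$pair_id, function(pid) {
        i <- which(lab$pair_id == pid & lab$picture_type == "old")
        j <- which(lab$pair_id == pid & lab$picture_type == "related")
        stats::cor(P[i, ], P[j, ])
      }, 1))
    }))
  }, 1)
  expect_true(all(diff(means) > 0))
  expect_gt(stats::cor(grid, means, method = "spearman"), 0)
})

test_that("BOLD generator: pure noise gives near-zero betas; errors caught", {
  cfg <- quick_cfg(drift_amplitude = 0.5)
  ev <- event_table(onset = seq(10, 400, by = 40), duration = 3.5,
                    condition = "pic")
  set.seed(21)
  y <- generate_bold(ev, c(pic = 0), cfg)
  dm <- build_design_matrix(ev, cfg$tr_seconds, cfg$n_scans, "canonical")
  fit <- fit_glm(y, dm)
  expect_lt(abs(fit$betas[["pic"]]), 4 * fit$se[["pic"]])

  expect_error(generate_bold(event_table(1e5, 0, "pic"), c(pic = 1), cfg),
               "beyond scan duration")
  expect_error(generate_bold(ev, c(other = 1), cfg), "no amplitude")
})

test_that("a fixed master seed reproduces a subject byte-identically", {
  cfg <- sim_config(n_voxels = 20L)
  a <- simulate_subject(cfg, "28d", k = 3)
  b <- simulate_subject(cfg, "28d", k = 3)
  expect_identical(a, b)
  # different subject index gives a different draw
  c3 <- simulate_subject(cfg, "28d", k = 4)
  expect_false(identical(a$behavior$trials, c3$behavior$trials))
})
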