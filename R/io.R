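#' Write / read the canonical responses table
#'
#' The canonical tabular dialect is tab-delimited UTF-8 with a header row
#' (comma-delimited files are accepted on read). One row per trial:
#' `subject`, `group`, `trial`, `picture_id`, `pair_id`, `picture_type`,
#' `emotion`, `response`, `confidence`.
#'
#' @param subjects list of [subject_behavior] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_responses <- function(subjects, path) {
  rows <- lapply(subjects, function(s) {
    tr <- s$trials
    data.frame(subject = as.character(s$subject_id), group = s$group,
               trial = seq_len(nrow(tr)), tr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @param check_confidence error if a confidence rating accompanies a
#'   non-"yes" response.
#' @return `read_responses()`: list of [subject_behavior] objects.
#' @export
read_responses <- function(path, check_confidence = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  required <- c("subject", "group", "picture_id", "pair_id", "picture_type",
                "emotion", "response", "confidence")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L) {
    stop("responses file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (check_confidence) {
    bad <- which(tab$response != "yes" & !is.na(tab$confidence))
    if (length(bad) > 0L) {
      stop("confidence on a non-'yes' response at row ", bad[1L],
           " (column 'confidence')")
    }
  }
  tab$pair_id <- as.character(tab$pair_id)
  lapply(split(tab, factor(tab$subject, levels = unique(tab$subject))),
         function(df) {
           subject_behavior(df$subject[1L], df$group[1L],
                            df[, c("picture_id", "pair_id", "picture_type",
                                   "emotion", "response", "confidence")])
         })
}

#' Write / read an event table (TSV)
#'
#' @param events an [event_table].
#' @param path file path.
#' @return `path` / an [event_table].
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  event_table(tab$onset, tab$duration, tab$condition, tab$trial_id)
}

#' Write / read a plain-text numeric matrix
#'
#' Whitespace-delimited numeric matrices (one row per line), used for
#' trial-pattern matrices, RDMs and ROI time series.
#'
#' @param m numeric matrix or vector.
#' @param path file path.
#' @return `path` / a numeric matrix.
#' @export
write_matrix <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates the two-group cohort, writes the responses table, computes
#' per-subject behavioral summaries and the group-level mixed ANOVAs
#' (hits, false alarms with the Group x Picture-Type interaction, the
#' confidence score), fits the two model RDMs per subject in each ROI, and
#' emits a run manifest with the configuration snapshot, seed, file digests
#' and package version.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param patterns logical; include the RSA stage (slower).
#' @return the manifest, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, patterns = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config, patterns = patterns)
  subjects <- lapply(study, `[[`, "behavior")
  paths <- character()

  p <- file.path(out_dir, "responses.tsv")
  write_responses(subjects, p); paths["responses"] <- p

  summaries <- do.call(rbind, lapply(subjects, behavior_summary))
  p <- file.path(out_dir, "behavior_summaries.csv")
  utils::write.csv(summaries, p, row.names = FALSE)
  paths["behavior_summaries"] <- p

  long <- group_behavior_table(subjects)
  p <- file.path(out_dir, "behavior_long.tsv")
  utils::write.table(long, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["behavior_long"] <- p

  fa <- long[long$measure == "fa_pct", ]
  anova_fa <- mixed_anova(fa, dv = "value", between = "group",
                          within = c("picture_type", "emotion"),
                          subject = "subject_id")
  hit <- long[long$measure == "hit_pct", ]
  anova_hit <- mixed_anova(hit, dv = "value", between = "group",
                           within = "emotion", subject = "subject_id")
  conf <- long[long$measure == "confidence_score", ]
  t_conf <- welch_t(conf$value[conf$group == "1d"],
                    conf$value[conf$group == "28d"])
  stats_out <- rbind(
    cbind(analysis = "fa_anova", anova_fa),
    cbind(analysis = "hit_anova", anova_hit))
  p <- file.path(out_dir, "anova_results.csv")
  utils::write.csv(stats_out, p, row.names = FALSE)
  paths["anova_results"] <- p

  rsa_fits <- NULL
  if (patterns) {
    rows <- list()
    for (s in study) {
      for (roi in names(s$patterns)) {
        rdm <- compute_rdm(s$patterns[[roi]])
        ty <- attr(s$patterns[[roi]], "labels")$picture_type
        fit_od <- model_fit(rdm, build_model_rdm(ty, "old_distinct"))
        fit_or <- model_fit(rdm, build_model_rdm(ty, "old_related_similar"))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s$subject_id, group = s$group, roi = roi,
          mean_similarity = mean_pattern_similarity(rdm),
          fit_old_distinct = fit_od, fit_old_related_similar = fit_or,
          stringsAsFactors = FALSE)
      }
    }
    rsa_fits <- do.call(rbind, rows)
    p <- file.path(out_dir, "rsa_model_fits.csv")
    utils::write.csv(rsa_fits, p, row.names = FALSE)
    paths["rsa_model_fits"] <- p
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gistmem")),
    seed = config$rng_seed,
    config = config[setdiff(names(config), "conf_probs")],
    conf_probs = config$conf_probs,
    outputs = lapply(stats::setNames(nm = names(paths)), function(nm) {
      list(path = unname(paths[[nm]]),
           md5 = unname(tools::md5sum(paths[[nm]])))
    }),
    welch_t_confidence = as.list(t_conf)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, summaries = summaries, long = long,
                 anova_fa = anova_fa, anova_hit = anova_hit,
                 t_confidence = t_conf, rsa_fits = rsa_fits))
}
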