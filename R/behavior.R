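#' Construct a subject's recognition record
#'
#' Bundles one participant's recognition-test trials with their identifier
#' and delay group. Trials are one row per presented picture with the
#' "old?" yes/no response and, for "yes" answers, a 0-3 confidence rating
#' (not at all = 0 ... very confident = 3).
#'
#' @param subject_id character or integer identifier, unique within a study.
#' @param group delay group, `"1d"` or `"28d"`.
#' @param trials data.frame with columns `picture_id`, `pair_id` (NA for
#'   novel pictures), `picture_type` (`"old"`, `"related"`, `"novel"`),
#'   `emotion` (`"negative"`, `"neutral"`), `response` (`"yes"`, `"no"`,
#'   `"none"`) and `confidence` (integer 0-3, NA unless response is "yes").
#' @return An object of class `subject_behavior`.
#' @export
subject_behavior <- function(subject_id, group, trials) {
  group <- match.arg(group, c("1d", "28d"))
  required <- c("picture_id", "pair_id", "picture_type", "emotion",
                "response", "confidence")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trials is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(trials$picture_type %in% c("old", "related", "novel"))) {
    stop("picture_type must be 'old', 'related' or 'novel'")
  }
  if (!all(trials$emotion %in% c("negative", "neutral"))) {
    stop("emotion must be 'negative' or 'neutral'")
  }
  if (!all(trials$response %in% c("yes", "no", "none"))) {
    stop("response must be 'yes', 'no' or 'none'")
  }
  bad_conf <- which(trials$response != "yes" & !is.na(trials$confidence))
  if (length(bad_conf) > 0L) {
    stop("confidence present on non-'yes' response at trial row(s): ",
         paste(utils::head(bad_conf, 5L), collapse = ", "))
  }
  bad_pair <- which(trials$picture_type %in% c("old", "related") &
                      is.na(trials$pair_id))
  if (length(bad_pair) > 0L) {
    stop("old/related trial without pair_id at row(s): ",
         paste(utils::head(bad_pair, 5L), collapse = ", "))
  }
  structure(list(subject_id = subject_id, group = group,
                 trials = as.data.frame(trials, stringsAsFactors = FALSE)),
            class = "subject_behavior")
}

#' @export
print.subject_behavior <- function(x, ...) {
  cat("<subject_behavior> ", x$subject_id, " (", x$group, " group), ",
      nrow(x$trials), " trials\n", sep = "")
  invisible(x)
}

rate_pct <- function(trials, type, emotion = NULL) {
  sel <- trials$picture_type == type
  if (!is.null(emotion)) sel <- sel & trials$emotion == emotion
  sel <- sel & trials$response != "none"   # non-responses leave the denominator
  n <- sum(sel)
  if (n == 0L) return(NA_real_)
  100 * sum(trials$response[sel] == "yes") / n
}

#' Hit and false-alarm rates for one subject
#'
#' Computes the percentage of "yes" responses to old pictures (hits) and to
#' related and novel lures (false alarms), overall and split by emotional
#' valence. Trials without a response are excluded from the denominators; a
#' picture type with no responded trials yields `NA`, never zero.
#'
#' @param subject a [subject_behavior] object.
#' @return A one-row data.frame with columns `hit_pct`, `fa_related_pct`,
#'   `fa_novel_pct` and their `_negative`/`_neutral` splits.
#' @export
score_recognition <- function(subject) {
  stopifnot(inherits(subject, "subject_behavior"))
  tr <- subject$trials
  if (nrow(tr) == 0L) stop("subject has no trials")
  out <- data.frame(
    hit_pct        = rate_pct(tr, "old"),
    fa_related_pct = rate_pct(tr, "related"),
    fa_novel_pct   = rate_pct(tr, "novel")
  )
  for (em in c("negative", "neutral")) {
    out[[paste0("hit_pct_", em)]]        <- rate_pct(tr, "old", em)
    out[[paste0("fa_related_pct_", em)]] <- rate_pct(tr, "related", em)
    out[[paste0("fa_novel_pct_", em)]]   <- rate_pct(tr, "novel", em)
  }
  out
}

#' Confidence-weighted memory score
#'
#' Sums the confidence ratings (0-3) over all hits, i.e. weights each hit
#' by how confident the participant was. With 60 old pictures the maximum
#' score is 180 (60 "very confident" hits).
#'
#' @param subject a [subject_behavior] object.
#' @return Integer score in `[0, 3 * n_old]`.
#' @export
confidence_score <- function(subject) {
  stopifnot(inherits(subject, "subject_behavior"))
  tr <- subject$trials
  hits <- tr$picture_type == "old" & tr$response == "yes"
  conf <- tr$confidence[hits]
  if (anyNA(conf)) {
    bad <- tr$picture_id[hits][is.na(conf)]
    stop("hit with missing confidence rating: picture ",
         paste(bad, collapse = ", "))
  }
  if (length(conf) > 0L && (any(conf < 0) || any(conf > 3))) {
    stop("confidence ratings must lie in 0..3")
  }
  as.integer(sum(conf))
}

categorize_one_pair <- function(old_resp, rel_resp) {
  if (old_resp == "none" || rel_resp == "none") return("unclassified")
  if (rel_resp == "yes") return("transformed")  # regardless of old response
  if (old_resp == "yes") return("detailed")
  "forgotten"
}

#' Categorize old/related picture pairs
#'
#' Assigns each studied picture and its related lure to one of three memory
#' categories based on the two recognition responses: *detailed* (old
#' endorsed, lure correctly rejected - details retained), *transformed*
#' (lure endorsed, irrespective of the old response - gist retained without
#' details), *forgotten* (both rejected). A pair in which either member
#' received no response is *unclassified*.
#'
#' @param subject a [subject_behavior] object.
#' @return A data.frame with one row per pair (`pair_id`, `emotion`,
#'   `category`) carrying a `counts` attribute (named integer vector over
#'   the four categories).
#' @export
categorize_pairs <- function(subject) {
  stopifnot(inherits(subject, "subject_behavior"))
  tr <- subject$trials
  pr <- tr[tr$picture_type %in% c("old", "related"), , drop = FALSE]
  pair_ids <- unique(pr$pair_id)
  res <- lapply(pair_ids, function(pid) {
    old <- pr[pr$pair_id == pid & pr$picture_type == "old", , drop = FALSE]
    rel <- pr[pr$pair_id == pid & pr$picture_type == "related", , drop = FALSE]
    if (nrow(old) != 1L || nrow(rel) != 1L) {
      stop("pair ", pid, " must have exactly one old and one related trial")
    }
    data.frame(pair_id = pid, emotion = old$emotion,
               category = categorize_one_pair(old$response, rel$response),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  lv <- c("detailed", "transformed", "forgotten", "unclassified")
  counts <- table(factor(out$category, levels = lv))
  attr(out, "counts") <- stats::setNames(as.integer(counts), lv)
  out
}

#' Full behavioral summary for one subject
#'
#' @param subject a [subject_behavior] object.
#' @return One-row data.frame: recognition rates, `confidence_score`, and
#'   pair category counts (`n_detailed`, `n_transformed`, `n_forgotten`,
#'   `n_unclassified`).
#' @export
behavior_summary <- function(subject) {
  rates <- score_recognition(subject)
  counts <- attr(categorize_pairs(subject), "counts")
  cbind(
    data.frame(subject_id = subject$subject_id, group = subject$group,
               stringsAsFactors = FALSE),
    rates,
    data.frame(confidence_score = confidence_score(subject),
               n_detailed = counts[["detailed"]],
               n_transformed = counts[["transformed"]],
               n_forgotten = counts[["forgotten"]],
               n_unclassified = counts[["unclassified"]])
  )
}

#' Long-format group behavior table
#'
#' Reshapes per-subject summaries into the long format consumed by the
#' mixed-ANOVA routines: one row per subject x measure x within-subject
#' cell (picture type, emotion), with the delay group carried along.
#'
#' @param subjects list of [subject_behavior] objects (both groups).
#' @return data.frame with columns `subject_id`, `group`, `measure`,
#'   `picture_type`, `emotion`, `value`.
#' @export
group_behavior_table <- function(subjects) {
  if (length(subjects) == 0L) stop("no subjects supplied")
  ids <- vapply(subjects, function(s) as.character(s$subject_id), "")
  if (anyDuplicated(ids)) {
    stop("duplicated subject_id: ", ids[duplicated(ids)][1L])
  }
  rows <- lapply(subjects, function(s) {
    tr <- s$trials
    base <- data.frame(subject_id = as.character(s$subject_id),
                       group = s$group, stringsAsFactors = FALSE)
    long <- list()
    for (em in c("negative", "neutral")) {
      long[[length(long) + 1L]] <- cbind(base, data.frame(
        measure = "hit_pct", picture_type = "old", emotion = em,
        value = rate_pct(tr, "old", em), stringsAsFactors = FALSE))
      for (ty in c("related", "novel")) {
        long[[length(long) + 1L]] <- cbind(base, data.frame(
          measure = "fa_pct", picture_type = ty, emotion = em,
          value = rate_pct(tr, ty, em), stringsAsFactors = FALSE))
      }
    }
    long[[length(long) + 1L]] <- cbind(base, data.frame(
      measure = "confidence_score", picture_type = "old", emotion = "all",
      value = as.numeric(confidence_score(s)), stringsAsFactors = FALSE))
    counts <- attr(categorize_pairs(s), "counts")
    n_pairs <- sum(counts)
    for (cat in c("detailed", "transformed", "forgotten")) {
      long[[length(long) + 1L]] <- cbind(base, data.frame(
        measure = paste0("pct_", cat), picture_type = "pair", emotion = "all",
        value = 100 * counts[[cat]] / n_pairs, stringsAsFactors = FALSE))
    }
    do.call(rbind, long)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
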