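#' Representational dissimilarity matrix from trial patterns
#'
#' Computes the trials x trials RDM with correlation distance
#' \eqn{1 - r} (Pearson), the dissimilarity measure used throughout:
#' identical patterns have distance 0, perfectly anticorrelated patterns
#' distance 2.
#'
#' @param patterns trials x voxels matrix (e.g. a
#'   [single_trial_tmaps()] result); a `labels` attribute, if present, is
#'   carried through.
#' @return Object of class `rdm`: symmetric matrix with zero diagonal and
#'   values in \[0, 2\].
#' @export
compute_rdm <- function(patterns) {
  P <- as.matrix(patterns)
  if (nrow(P) < 2L) stop("need at least 2 trials")
  if (ncol(P) < 2L) stop("need at least 2 voxels (correlation undefined)")
  sds <- apply(P, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant pattern (zero variance) at trial row(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  D <- 1 - stats::cor(t(P))
  diag(D) <- 0
  structure(D, labels = attr(patterns, "labels"), class = c("rdm", "matrix"))
}

as_rdm <- function(D, labels = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("RDM must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("RDM must be symmetric")
  structure(D, labels = labels, class = c("rdm", "matrix"))
}

lower_vec <- function(D) D[lower.tri(D)]

#' Mean pattern similarity of an RDM
#'
#' The mean Pearson similarity \eqn{r = 1 - d} over the strictly lower
#' triangle (diagonal excluded): an overall index of how similar activity
#' patterns are across all trials of the task.
#'
#' @param rdm a square dissimilarity matrix.
#' @return scalar mean similarity.
#' @export
mean_pattern_similarity <- function(rdm) {
  D <- as.matrix(rdm)
  if (nrow(D) < 2L) stop("RDM must be at least 2 x 2")
  mean(1 - lower_vec(D))
}

#' Cell-wise average of RDMs
#'
#' Averages single-subject RDMs into a group RDM. All RDMs must have the
#' same dimension and trial ordering; subjects with differently sized RDMs
#' (missing trials) must be excluded beforehand.
#'
#' @param rdms list of RDMs.
#' @return the element-wise mean, as an `rdm`.
#' @export
average_rdm <- function(rdms) {
  if (length(rdms) == 0L) stop("no RDMs supplied")
  dims <- vapply(rdms, function(d) nrow(as.matrix(d)), 1L)
  if (length(unique(dims)) != 1L) {
    stop("RDMs of mixed sizes (", paste(sort(unique(dims)), collapse = ", "),
         "); exclude differently sized RDMs before averaging")
  }
  M <- Reduce(`+`, lapply(rdms, as.matrix)) / length(rdms)
  as_rdm(M, labels = attr(rdms[[1L]], "labels"))
}

#' Rank-transform an RDM and scale into \[0, 1\]
#'
#' For visualization: the off-diagonal dissimilarities are replaced by
#' their ranks (average ranks for ties) mapped linearly onto \[0, 1\], so
#' the smallest distance becomes 0 and the largest 1 while the rank order
#' is preserved. Each unordered trial pair is ranked once (the matrix is
#' symmetric; the lower triangle is the rank population) and mirrored.
#'
#' @param rdm a square symmetric dissimilarity matrix.
#' @return rank-scaled `rdm` with zero diagonal.
#' @export
rank_scale_rdm <- function(rdm) {
  D <- as.matrix(rdm)
  v <- lower_vec(D)
  if (length(unique(v)) < 2L) stop("all off-diagonal values identical")
  r <- (rank(v) - 1) / (length(v) - 1)
  out <- matrix(0, nrow(D), ncol(D))
  out[lower.tri(out)] <- r
  out <- out + t(out)
  as_rdm(out, labels = attr(rdm, "labels"))
}

#' Spearman similarity between two RDMs
#'
#' Spearman rank correlation of the strictly-lower-triangle vectors, used
#' to compare a single-subject RDM of one delay group against the average
#' RDM of the other group (ties receive average ranks).
#'
#' @param single,reference RDMs of identical dimension and trial ordering.
#' @return Spearman r.
#' @export
cross_group_similarity <- function(single, reference) {
  A <- as.matrix(single); B <- as.matrix(reference)
  if (!all(dim(A) == dim(B))) stop("RDM size mismatch: ", nrow(A), " vs ",
                                   nrow(B))
  stats::cor(lower_vec(A), lower_vec(B), method = "spearman")
}

#' Categorical model RDM over picture types
#'
#' Builds the two hypothesis matrices compared against brain RDMs:
#' \describe{
#'   \item{`old_distinct`}{all old pictures share a pattern distinct from
#'     everything else: old-old cells 0, all other cells 1.}
#'   \item{`old_related_similar`}{old pictures and their related lures
#'     share a pattern distinct from novel pictures: cells within
#'     \{old, related\} 0, any cell involving a novel picture 1.}
#' }
#' With `masked = TRUE`, cells the hypothesis does not constrain are
#' excluded from model fits: within-related and within-novel cells for
#' `old_distinct`, within-novel cells for `old_related_similar`.
#'
#' @param labels character vector of picture types
#'   (`"old"`/`"related"`/`"novel"`), one per trial.
#' @param model `"old_distinct"` or `"old_related_similar"`.
#' @param masked logical; attach a cell mask excluding unconstrained cells.
#' @return Object of class `model_rdm`: 0/1 matrix with zero diagonal, a
#'   `model` attribute, and (if `masked`) a logical `mask` attribute
#'   (TRUE = cell used).
#' @export
build_model_rdm <- function(labels, model = c("old_distinct",
                                              "old_related_similar"),
                            masked = FALSE) {
  model <- match.arg(model)
  if (!all(labels %in% c("old", "related", "novel"))) {
    stop("unknown picture type label: ",
         paste(setdiff(unique(labels), c("old", "related", "novel")),
               collapse = ", "))
  }
  n <- length(labels)
  M <- matrix(1, n, n)
  mask <- matrix(TRUE, n, n)
  if (model == "old_distinct") {
    same <- outer(labels == "old", labels == "old", `&`)
    M[same] <- 0
    if (masked) {
      for (ty in c("related", "novel")) {
        within <- outer(labels == ty, labels == ty, `&`)
        mask[within] <- FALSE
      }
    }
  } else {
    in_set <- labels %in% c("old", "related")
    M[outer(in_set, in_set, `&`)] <- 0
    if (masked) {
      within <- outer(labels == "novel", labels == "novel", `&`)
      mask[within] <- FALSE
    }
  }
  diag(M) <- 0
  structure(M, model = model, mask = if (masked) mask else NULL,
            labels = labels, class = c("model_rdm", "matrix"))
}

#' Spearman fit of a brain RDM to a model RDM
#'
#' Spearman rank correlation between the strictly-lower-triangle cells of
#' the brain RDM and the model RDM; rank correlation is appropriate because
#' no linear match between brain distances and the binary hypothesis can be
#' assumed. Masked model cells (see [build_model_rdm()]) are excluded from
#' both vectors.
#'
#' @param rdm brain RDM.
#' @param model a [build_model_rdm()] result of matching dimension.
#' @return Spearman r.
#' @export
model_fit <- function(rdm, model) {
  D <- as.matrix(rdm); M <- as.matrix(model)
  if (!all(dim(D) == dim(M))) stop("RDM/model dimension mismatch")
  keep <- lower.tri(D)
  mask <- attr(model, "mask")
  if (!is.null(mask)) keep <- keep & mask
  x <- D[keep]; y <- M[keep]
  if (length(x) < 3L) stop("fewer than 3 usable cells")
  stats::cor(x, y, method = "spearman")
}

#' Compare two model fits with a one-tailed paired t-test
#'
#' Given per-subject Spearman fits of two candidate model RDMs, tests
#' whether one model fits reliably better with a paired t-test in the
#' stated direction; Cohen's d is the mean fit difference over its SD.
#'
#' @param fits_a,fits_b per-subject model fits (paired).
#' @param direction `"greater"` (a > b), `"less"`, or `"two.sided"`.
#' @return data.frame with `t`, `df`, `p`, `cohens_d`, `mean_diff`.
#' @export
compare_model_fits <- function(fits_a, fits_b,
                               direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  paired_t(fits_a, fits_b, tails = direction)
}
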