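#' Mixed-design ANOVA with generalized eta squared
#'
#' Fits a mixed ANOVA with one between-subject factor and up to two
#' within-subject factors (one observation per subject and within-cell,
#' balanced design), the workhorse design for comparing delay groups on
#' recognition rates, confidence scores and ROI peak responses. Sums of
#' squares come from [stats::aov()] with the appropriate `Error()` strata;
#' for balanced designs the Type I/II/III distinction is moot. Generalized
#' eta squared per effect is computed as
#' \eqn{SS_{effect} / (SS_{effect} + \sum SS_{error})} with the sum over
#' all error strata (no factor treated as observed). For within-subject
#' effects involving a factor with more than two levels, Mauchly's
#' sphericity test is run and Greenhouse-Geisser-corrected degrees of
#' freedom and p-values are reported alongside the uncorrected ones.
#'
#' @param data data.frame in long format, one row per subject x within-cell.
#' @param dv name of the dependent-variable column.
#' @param between name of the between-subject factor column.
#' @param within character vector (length 0-2) of within-subject factor
#'   columns.
#' @param subject name of the subject identifier column.
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`,
#'   `ss`, `ss_error`, `F`, `p`, `ges`, and for within effects with > 2
#'   levels `mauchly_w`, `mauchly_p`, `gg_epsilon`, `df1_gg`, `df2_gg`,
#'   `p_gg` (NA elsewhere).
#' @export
mixed_anova <- function(data, dv, between, within = character(), subject) {
  data <- as.data.frame(data)
  for (v in c(dv, between, within, subject)) {
    if (!v %in% names(data)) stop("column not found: ", v)
  }
  if (anyNA(data[[dv]])) stop("missing values in dependent variable")
  data[[subject]] <- factor(data[[subject]])
  data[[between]] <- factor(data[[between]])
  for (w in within) data[[w]] <- factor(data[[w]])

  # one observation per subject x within-cell; subjects nested in groups
  if (length(within) > 0L) {
    cell <- interaction(data[c(subject, within)], drop = FALSE)
    tab <- table(data[[subject]],
                 interaction(data[within], drop = FALSE))
    if (any(tab != 1L)) {
      bad <- which(tab != 1L, arr.ind = TRUE)
      stop("design not balanced: subject/within cell(s) with count != 1, e.g. ",
           rownames(tab)[bad[1, 1]], " x ", colnames(tab)[bad[1, 2]])
    }
  } else if (anyDuplicated(data[[subject]])) {
    stop("multiple observations per subject with no within factor")
  }
  grp_per_subj <- tapply(data[[between]], data[[subject]],
                         function(g) length(unique(g)))
  if (any(grp_per_subj != 1L)) stop("a subject appears in more than one group")

  within_rhs <- if (length(within) > 0L)
    paste(within, collapse = "*") else NULL
  rhs <- paste(c(between, within), collapse = "*")
  err <- if (is.null(within_rhs)) subject else
    sprintf("%s/(%s)", subject, within_rhs)
  fml <- stats::as.formula(sprintf("%s ~ %s + Error(%s)", dv, rhs, err))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)

  rows <- list()
  err_ss_total <- 0
  for (stratum in sm) {
    tbl <- if (is.list(stratum)) stratum[[1L]] else stratum
    terms_here <- trimws(rownames(tbl))
    res_i <- which(terms_here == "Residuals")
    err_ss <- tbl[res_i, "Sum Sq"]
    err_df <- tbl[res_i, "Df"]
    err_ss_total <- err_ss_total + err_ss
    for (i in seq_len(nrow(tbl))[-res_i]) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms_here[i], df1 = tbl[i, "Df"], df2 = err_df,
        ss = tbl[i, "Sum Sq"], ss_error = err_ss,
        F = tbl[i, "F value"], p = tbl[i, "Pr(>F)"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$ges <- out$ss / (out$ss + err_ss_total)
  out$mauchly_w <- out$mauchly_p <- out$gg_epsilon <- NA_real_
  out$df1_gg <- out$df2_gg <- out$p_gg <- NA_real_

  # sphericity: per pure-within effect, shared with its group interaction
  if (length(within) > 0L) {
    wide <- within_cell_matrix(data, dv, within, subject, between)
    for (k in seq_along(within)) {
      combos <- utils::combn(within, k, simplify = FALSE)
      for (eff_factors in combos) {
        sph <- sphericity_stats(wide, data, eff_factors, within, between)
        eff_name <- paste(eff_factors, collapse = ":")
        targets <- c(eff_name, paste(between, eff_name, sep = ":"))
        for (tg in targets) {
          i <- which(out$effect == tg)
          if (length(i) != 1L) next
          if (sph$d > 1L) {
            out$mauchly_w[i] <- sph$w
            out$mauchly_p[i] <- sph$p
            out$gg_epsilon[i] <- sph$epsilon
            out$df1_gg[i] <- out$df1[i] * sph$epsilon
            out$df2_gg[i] <- out$df2[i] * sph$epsilon
            out$p_gg[i] <- stats::pf(out$F[i], out$df1_gg[i], out$df2_gg[i],
                                     lower.tail = FALSE)
          }
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

# subjects x within-cells matrix of the dv, cells in a fixed factor order
within_cell_matrix <- function(data, dv, within, subject, between) {
  cells <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  subj <- data[[subject]]
  wide <- tapply(data[[dv]], list(subj, cells), identity)
  grp <- tapply(as.character(data[[between]]), subj, function(g) g[1L])
  attr(wide, "group") <- grp[rownames(wide)]
  wide
}

# orthonormal contrast matrix for one within effect (Kronecker over factors,
# normalized Helmert contrasts for involved factors, unit mean vector else)
effect_contrast <- function(data, eff_factors, within) {
  M <- matrix(1, 1, 1)
  for (w in within) {  # must match lex.order of within_cell_matrix
    k <- nlevels(factor(data[[w]]))
    if (w %in% eff_factors) {
      C <- stats::contr.helmert(k)
      C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
    } else {
      C <- matrix(1 / sqrt(k), k, 1)
    }
    M <- kronecker(M, C)
  }
  M
}

# GG epsilon + Mauchly test from the pooled within-group covariance of the
# contrast-transformed subject x cell matrix
sphericity_stats <- function(wide, data, eff_factors, within, between) {
  M <- effect_contrast(data, eff_factors, within)
  d <- ncol(M)
  if (d <= 1L) return(list(d = d, epsilon = 1, w = NA_real_, p = NA_real_))
  Y <- wide %*% M
  grp <- attr(wide, "group")
  # pool covariance within groups
  E <- matrix(0, d, d)
  df_pool <- 0L
  for (g in unique(grp)) {
    Yg <- Y[grp == g, , drop = FALSE]
    if (nrow(Yg) > 1L) {
      E <- E + stats::cov(Yg) * (nrow(Yg) - 1L)
      df_pool <- df_pool + nrow(Yg) - 1L
    }
  }
  E <- E / df_pool
  ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  epsilon <- sum(ev)^2 / (d * sum(ev^2))
  w <- det(E) / (sum(diag(E)) / d)^d
  if (!is.finite(w) || w <= 0) {
    return(list(d = d, epsilon = epsilon, w = NA_real_, p = NA_real_))
  }
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * df_pool)
  chi <- -df_pool * f * log(w)
  df_chi <- d * (d + 1) / 2 - 1
  p <- stats::pchisq(chi, df_chi, lower.tail = FALSE)
  list(d = d, epsilon = epsilon, w = w, p = p)
}

#' Welch's two-sample t-test with Cohen's d
#'
#' The default between-group test: unequal-variance t with
#' Welch-Satterthwaite degrees of freedom, plus a pooled-SD Cohen's d.
#'
#' @param x,y numeric vectors (the two groups).
#' @param tails `"two.sided"` (default), `"greater"` or `"less"`.
#' @return data.frame with `t`, `df`, `p`, `cohens_d`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y, tails = "two.sided") {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = tails)
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, cohens_d = (mean(x) - mean(y)) / sp,
             mean_x = mean(x), mean_y = mean(y))
}

#' Paired t-test with Cohen's d
#'
#' Cohen's d for the paired design is the mean difference divided by the
#' standard deviation of the differences. A zero-variance difference vector
#' makes t undefined and is reported as an error rather than silently
#' returning infinity.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param tails `"two.sided"`, `"greater"` (mean(x) > mean(y)) or `"less"`.
#' @return data.frame with `t`, `df`, `p`, `cohens_d`, `mean_diff`.
#' @export
paired_t <- function(x, y, tails = "two.sided") {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (all(abs(d) < 1e-12)) {
      return(data.frame(t = 0, df = length(x) - 1,
                        p = if (tails == "two.sided") 1 else 0.5,
                        cohens_d = 0, mean_diff = 0))
    }
    stop("zero variance in paired differences: t undefined ",
         "(constant nonzero difference)")
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = tails)
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, cohens_d = mean(d) / stats::sd(d),
             mean_diff = mean(d))
}

#' Pearson correlation test
#'
#' @param x,y numeric vectors, length >= 3.
#' @return data.frame with `r`, `t`, `df` (= n - 2), `p`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  data.frame(r = unname(ht$estimate), t = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson-Filon z for two overlapping dependent correlations
#'
#' Tests whether two Pearson correlations that share one variable differ,
#' e.g. whether a behavioral memory score correlates more strongly with the
#' anterior than the posterior hippocampal response measured in the same
#' participants. This is the classical Pearson-Filon (1898) asymptotic test:
#' with \eqn{r_{12}} and \eqn{r_{13}} the two overlapping correlations and
#' \eqn{r_{23}} the correlation between the non-shared variables,
#' \deqn{z = \frac{(r_{12} - r_{13})\sqrt{n}}{\sqrt{(1-r_{12}^2)^2 +
#'   (1-r_{13}^2)^2 - 2k}}}
#' where \eqn{k} is the asymptotic covariance term
#' \eqn{k = r_{23}(1 - r_{12}^2 - r_{13}^2) - \tfrac{1}{2} r_{12} r_{13}
#' (1 - r_{12}^2 - r_{13}^2 - r_{23}^2)}.
#'
#' @param r12,r13 the two overlapping correlations (shared variable is 1).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (>= 4).
#' @return data.frame with `z` and two-tailed `p`.
#' @export
pearson_filon_z <- function(r12, r13, r23, n) {
  for (r in c(r12, r13, r23)) {
    if (!is.finite(r) || abs(r) > 1) stop("correlations must lie in [-1, 1]")
  }
  if (n < 4L) stop("n must be at least 4")
  R <- matrix(c(1, r12, r13,
                r12, 1, r23,
                r13, r23, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("correlation triple is not positive semidefinite")
  }
  k <- r23 * (1 - r12^2 - r13^2) -
    0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)
  denom <- (1 - r12^2)^2 + (1 - r13^2)^2 - 2 * k
  if (denom <= 0) stop("degenerate correlation configuration: ",
                       "variance estimate non-positive")
  z <- (r12 - r13) * sqrt(n) / sqrt(denom)
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard algorithm, with an explicit error for
#' constant input (W undefined).
#'
#' @param x numeric vector, 3 <= length <= 5000.
#' @return data.frame with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L) stop("need 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("constant input: W undefined")
  ht <- stats::shapiro.test(x)
  data.frame(W = unname(ht$statistic), p = ht$p.value)
}
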