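# Per-drug differential-expression calling over time: local quadratic fits
# with LOO-CV bandwidth selection per gene, tube-formula simultaneous bands
# against the fitted control (0 h) value, Bonferroni correction across
# genes, and the fold-change >= 1.2 rule.
#
# Because the equivalent-kernel matrices depend only on the design, fitting
# a whole matrix of genes reduces to a few matrix products per candidate
# bandwidth.

#' Assign response phase from the time of maximal response
#'
#' Immediate-Early, Middle, and Late phases cover (0, 2\], (2, 4\], and
#' (4, 8\] hours after exposure; boundary times fall in the earlier phase.
#'
#' @param t_max time(s) of maximal absolute log2 ratio, in hours.
#' @return character vector of `"IE"`, `"M"`, `"L"`.
#' @examples
#' assign_phase(c(1, 4, 8))  # "IE" "M" "L"
#' @export
assign_phase <- function(t_max) {
  if (any(t_max <= 0 | t_max > 8)) {
    stop("t_max must lie in (0, 8] hours; got ",
         paste(t_max[t_max <= 0 | t_max > 8], collapse = ", "))
  }
  as.character(cut(t_max, breaks = c(0, 2, 4, 8), labels = c("IE", "M", "L"),
                   right = TRUE))
}

#' Fit smoothed time courses for every gene of one drug
#'
#' For each gene: selects a bandwidth by leave-one-out cross validation over
#' candidate bandwidths (fractions of the time span; ties to the smallest),
#' fits the local quadratic curve on a dense evaluation grid, and computes
#' the smallest simultaneous level at which the band excludes the fitted
#' control (0 h) value, together with the signed fold change and the time of
#' the maximal response.
#'
#' @param dataset an [expression_dataset()].
#' @param drug drug name present in the dataset.
#' @param bandwidth_fractions candidate bandwidths as fractions of the
#'   observed time span.
#' @param grid_n number of equally spaced evaluation points (observed times
#'   are always added).
#' @param best optional per-gene candidate index (into the sorted
#'   bandwidths) pre-chosen externally, e.g. from the cross-drug
#'   cross-validation of [fit_all_drugs()]; default: per-gene LOO-CV on
#'   this drug alone.
#' @return an object of class `timecourse_fit_set`: per-gene fitted curves
#'   (`fitted`, genes x grid), standard errors (`se`), `bandwidth`, `sigma`,
#'   `df`, `kappa0`, `band_p`, `signed_fc`, `t_max`, plus `grid` and `times`.
#' @export
fit_timecourse <- function(dataset, drug,
                           bandwidth_fractions = c(0.4, 0.55, 0.7, 0.85, 1.0),
                           grid_n = 33, best = NULL) {
  dm <- drug_matrix(dataset, drug)
  tt <- dm$times
  Y <- dm$values
  if (min(tt) != 0) stop("drug ", drug, " has no time-0 reference")
  grid <- sort(unique(c(seq(0, max(tt), length.out = grid_n), tt)))
  cands <- sort(bandwidth_fractions * diff(range(tt)))
  n <- length(tt)
  i0g <- which(grid == 0)
  tpos <- grid[grid > 0]
  sm <- lapply(cands, function(h) {
    L <- .lp_smoother(tt, h, grid)
    H <- .lp_smoother(tt, h, tt)
    # equivalent kernel of the difference process fit(t) - fit(0): the DE
    # statistic studentizes this difference, so its standard error must
    # include the control-reference estimation noise and its covariance
    # with fit(t)
    Ld <- sweep(L, 2, L[i0g, ])
    pos <- which(grid > 0)
    list(L = L, H = H, P = .lp_loocv_matrix(tt, h),
         norms = sqrt(rowSums(L^2)),
         norms_diff = sqrt(rowSums(Ld[pos, , drop = FALSE]^2)),
         kappa0 = .lp_kappa0(L),
         kappa0_diff = .lp_kappa0_diff(tt, h, min(tpos), max(tpos)),
         df = max(n - sum(diag(H)), 1))
  })
  if (is.null(best)) {
    cv <- cv_matrix(dataset, drug, bandwidth_fractions)
    best <- max.col(-cv, ties.method = "first")
  }

  m <- length(grid)
  ng <- nrow(Y)
  pos <- which(grid > 0)
  Fitted <- matrix(NA_real_, ng, m, dimnames = list(rownames(Y), NULL))
  Norms <- Fitted
  NormsDiff <- matrix(NA_real_, ng, length(pos))
  rss <- df <- kappa0 <- kappa0_diff <- bandwidth <- numeric(ng)
  for (b in unique(best)) {
    g <- which(best == b)
    s <- sm[[b]]
    Fitted[g, ] <- Y[g, , drop = FALSE] %*% t(s$L)
    R <- Y[g, , drop = FALSE] - Y[g, , drop = FALSE] %*% t(s$H)
    rss[g] <- rowSums(R^2)
    Norms[g, ] <- rep(s$norms, each = length(g))
    NormsDiff[g, ] <- rep(s$norms_diff, each = length(g))
    df[g] <- s$df
    kappa0[g] <- s$kappa0
    kappa0_diff[g] <- s$kappa0_diff
    bandwidth[g] <- cands[b]
  }

  fit <- structure(list(
    drug = drug, genes = rownames(Y), times = tt, grid = grid,
    fitted = Fitted, norms = Norms, norms_diff = NormsDiff,
    bandwidth = bandwidth, rss = rss, df = df,
    kappa0 = kappa0, kappa0_diff = kappa0_diff
  ), class = "timecourse_fit_set")
  .band_stats(fit, sigma2 = rss / df, band_df = df)
}

# Fill in sigma, standard errors, band-exclusion p, fold change, and t_max
# for a fit set given a per-gene residual variance and its df (the variance
# may be pooled across drugs for the same gene).
.band_stats <- function(fit, sigma2, band_df) {
  grid <- fit$grid
  pos <- which(grid > 0)
  i0 <- which(grid == 0)
  ng <- length(fit$genes)
  sigma <- sqrt(sigma2)
  dev <- fit$fitted - fit$fitted[, i0]
  se_diff <- (sigma %o% rep(1, length(pos))) * fit$norms_diff
  z <- abs(dev[, pos, drop = FALSE]) / se_diff
  z[abs(dev[, pos, drop = FALSE]) == 0] <- 0    # flat + zero-residual case
  z[!is.finite(z)] <- Inf
  jz <- max.col(z, ties.method = "first")
  zmax <- z[cbind(seq_len(ng), jz)]
  band_p <- band_tail_p(zmax, fit$kappa0_diff, band_df)
  band_p[is.infinite(zmax)] <- 1e-300
  adev <- abs(dev[, pos, drop = FALSE])
  jmax <- max.col(adev, ties.method = "first")
  dmax <- dev[, pos, drop = FALSE][cbind(seq_len(ng), jmax)]

  fit$sigma <- sigma
  fit$band_df <- band_df
  fit$se <- (sigma %o% rep(1, ncol(fit$norms))) * fit$norms
  fit$band_p <- band_p
  fit$signed_fc <- ifelse(dmax >= 0, 1, -1) * 2^abs(dmax)
  fit$t_max <- grid[pos][jmax]
  fit$max_log2_ratio <- dmax
  fit
}

#' Pool per-gene residual variance across drugs
#'
#' For each gene, combines the residual sums of squares and degrees of
#' freedom of its per-drug fits into one variance estimate
#' (\eqn{\hat\sigma^2 = \sum_d RSS_d / \sum_d df_d}; each drug's own curve
#' absorbs that drug's trend, so residuals remain pure noise) and
#' recomputes every drug's standard errors and band-exclusion p-values with
#' the pooled variance and its larger df. Pooling is per gene only - no
#' information is shared between genes.
#'
#' @param fits named list of `timecourse_fit_set` objects over the same
#'   genes.
#' @return the list with updated `sigma`, `band_df`, `se`, `band_p`.
#' @export
pool_variance <- function(fits) {
  if (length(fits) < 2) return(fits)
  genes <- fits[[1]]$genes
  for (f in fits) stopifnot(identical(f$genes, genes))
  rss <- Reduce(`+`, lapply(fits, `[[`, "rss"))
  dfs <- Reduce(`+`, lapply(fits, `[[`, "df"))
  lapply(fits, function(f) .band_stats(f, sigma2 = rss / dfs, band_df = dfs))
}

#' @export
print.timecourse_fit_set <- function(x, ...) {
  cat("timecourse_fit_set:", length(x$genes), "genes,", x$drug, "\n")
  invisible(x)
}

#' Fit time courses for several drugs
#'
#' @param dataset an [expression_dataset()].
#' @param drugs drug names; default all non-control drugs.
#' @param pool_sigma pool each gene's residual variance across drugs
#'   (default TRUE; see [pool_variance()]).
#' @param joint_bandwidth choose each gene's bandwidth from the summed
#'   leave-one-out error across all drugs (default TRUE). A gene's response
#'   kinetics are shared across drug exposures, so the cross-drug criterion
#'   is better informed; it also decouples the choice from any single
#'   drug's noise, which keeps the per-drug band-exclusion p calibrated
#'   (per-drug selection chases that drug's own noise and inflates the
#'   far null tail).
#' @param bandwidth_fractions candidate bandwidths as fractions of the time
#'   span.
#' @param ... passed to [fit_timecourse()].
#' @return named list of `timecourse_fit_set` objects.
#' @export
fit_all_drugs <- function(dataset, drugs = NULL, pool_sigma = TRUE,
                          joint_bandwidth = TRUE,
                          bandwidth_fractions = c(0.4, 0.55, 0.7, 0.85, 1.0),
                          ...) {
  drugs <- drugs %||% dataset_drugs(dataset)
  best <- NULL
  if (joint_bandwidth && length(drugs) > 1) {
    cv <- Reduce(`+`, lapply(drugs, function(d) {
      cv_matrix(dataset, d, bandwidth_fractions)
    }))
    best <- max.col(-cv, ties.method = "first")
  }
  fits <- stats::setNames(
    lapply(drugs, function(d) {
      fit_timecourse(dataset, d, bandwidth_fractions = bandwidth_fractions,
                     best = best, ...)
    }), drugs)
  if (pool_sigma) fits <- pool_variance(fits)
  fits
}

#' Per-gene leave-one-out error matrix for one drug
#'
#' Mean squared leave-one-out prediction error of the local quadratic fit,
#' one row per gene, one column per candidate bandwidth (sorted ascending).
#'
#' @inheritParams fit_timecourse
#' @return numeric matrix, genes x candidates.
#' @export
cv_matrix <- function(dataset, drug,
                      bandwidth_fractions = c(0.4, 0.55, 0.7, 0.85, 1.0)) {
  dm <- drug_matrix(dataset, drug)
  tt <- dm$times
  Y <- dm$values
  cands <- sort(bandwidth_fractions * diff(range(tt)))
  cv <- vapply(cands, function(h) {
    P <- .lp_loocv_matrix(tt, h)
    rowMeans((Y - tcrossprod(Y, P))^2)
  }, numeric(nrow(Y)))
  if (is.null(dim(cv))) cv <- matrix(cv, nrow = 1)
  cv
}

# Smoothed log2 ratios (fitted(t) - fitted(0)) at requested grid times.
fitted_ratios <- function(fits, at_times) {
  stopifnot(inherits(fits, "timecourse_fit_set"))
  j <- vapply(at_times, function(t) {
    k <- which(abs(fits$grid - t) < 1e-8)
    if (length(k) != 1) stop("time ", t, " is not on the evaluation grid")
    k
  }, integer(1))
  i0 <- which(fits$grid == 0)
  out <- fits$fitted[, j, drop = FALSE] - fits$fitted[, i0]
  colnames(out) <- as.character(at_times)
  out
}

#' Call genes differentially expressed over time for one drug
#'
#' A gene is differentially expressed if (1) its Bonferroni-adjusted
#' band-exclusion p-value is below `alpha` and (2) its absolute linear-scale
#' fold change is at least `fc_threshold`. The band-exclusion p-value is the
#' smallest simultaneous level at which the confidence band around the
#' fitted curve excludes the fitted control (0 h) value at some time.
#'
#' @param dataset an [expression_dataset()]; ignored when `fits` is given.
#' @param drug drug name; ignored when `fits` is given.
#' @param alpha significance level on the adjusted p-value.
#' @param fc_threshold minimum absolute linear fold change (default 1.2).
#' @param fits optional precomputed [fit_timecourse()] result.
#' @param n_tested Bonferroni denominator; default the number of analyzed
#'   genes.
#' @return data.frame with columns `gene`, `drug`, `band_p`, `adj_p`,
#'   `signed_fc` (negative = down), `t_max`, `phase`, `direction`, `is_de`;
#'   the fit set is attached as attribute `"fits"`.
#' @export
call_degs <- function(dataset = NULL, drug = NULL, alpha = 0.05,
                      fc_threshold = 1.2, fits = NULL, n_tested = NULL) {
  if (is.null(fits)) {
    if (is.null(dataset) || is.null(drug)) {
      stop("either `fits` or both `dataset` and `drug` are required")
    }
    fits <- fit_timecourse(dataset, drug)
  }
  n_tested <- n_tested %||% length(fits$genes)
  adj_p <- pmin(1, fits$band_p * n_tested)
  out <- data.frame(
    gene = fits$genes,
    drug = fits$drug,
    band_p = fits$band_p,
    adj_p = adj_p,
    signed_fc = fits$signed_fc,
    t_max = fits$t_max,
    phase = assign_phase(fits$t_max),
    direction = ifelse(fits$signed_fc >= 0, "up", "down"),
    is_de = adj_p < alpha & abs(fits$signed_fc) >= fc_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
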