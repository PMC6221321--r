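# Temporal pattern discovery: Hartigan-Wong k-means on smoothed log2-ratio
# profiles (Euclidean distance, many random restarts), with the number of
# clusters chosen by average silhouette width and clusters labelled by the
# modal (direction, phase) of their members.

#' Average silhouette width of a partition
#'
#' Mean over all points of the silhouette \eqn{s(i) = (b_i - a_i)/\max(a_i,
#' b_i)}, with \eqn{a_i} the mean distance to the point's own cluster and
#' \eqn{b_i} the smallest mean distance to another cluster; singletons score
#' zero by convention.
#'
#' @param profiles numeric matrix, one row per profile.
#' @param assignments integer cluster labels, one per row.
#' @return scalar in \[-1, 1\].
#' @export
average_silhouette_width <- function(profiles, assignments) {
  n <- nrow(profiles)
  stopifnot(length(assignments) == n)
  if (length(unique(assignments)) < 2) stop("need at least two clusters")
  D <- as.matrix(stats::dist(profiles))
  cl <- as.integer(factor(assignments))
  K <- max(cl)
  Z <- matrix(0, n, K)
  Z[cbind(seq_len(n), cl)] <- 1
  sizes <- colSums(Z)
  M <- D %*% Z                      # total distance from i to each cluster
  own <- M[cbind(seq_len(n), cl)]
  a <- own / pmax(sizes[cl] - 1, 1)
  Mmean <- sweep(M, 2, sizes, "/")
  Mmean[cbind(seq_len(n), cl)] <- Inf
  b <- apply(Mmean, 1, min)
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s)] <- 0
  s[sizes[cl] == 1] <- 0
  mean(s)
}

#' Cluster temporal profiles with Hartigan-Wong k-means
#'
#' Best-of-`n_restarts` Hartigan-Wong solution by total within-cluster sum
#' of squares under Euclidean distance; deterministic given `seed`.
#'
#' @param profiles numeric matrix of profiles (genes x times); rownames are
#'   gene ids.
#' @param K number of clusters, `2 <= K <= nrow(profiles)`.
#' @param n_restarts random restarts (the "iterations" used to find an
#'   optimal partition); default 1000.
#' @param seed integer RNG seed.
#' @return object of class `clustering_result`: `K`, `assignments` (named
#'   integer vector), `centroids`, `tot_withinss`, `asw`.
#' @export
cluster_profiles <- function(profiles, K, n_restarts = 1000, seed = 1) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (K < 2 || K > n) stop("K must be in [2, ", n, "], got ", K)
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  ndistinct <- nrow(unique(profiles))
  if (K > ndistinct) stop("K exceeds the number of distinct profiles (",
                          ndistinct, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(
    profiles, centers = K, iter.max = 100, nstart = n_restarts,
    algorithm = "Hartigan-Wong"))
  asw <- if (K < n) average_silhouette_width(profiles, km$cluster) else {
    # every profile its own cluster: silhouettes undefined, report 0
    0
  }
  structure(list(
    K = K, assignments = stats::setNames(km$cluster, rownames(profiles)),
    centroids = km$centers, tot_withinss = km$tot.withinss, asw = asw
  ), class = "clustering_result")
}

#' Choose the number of temporal patterns by average silhouette width
#'
#' Runs [cluster_profiles()] for every K in `k_range` and returns the
#' solution maximizing the average silhouette width (ties to the smaller K);
#' the ASW profile over K is attached as `asw_by_k`.
#'
#' @inheritParams cluster_profiles
#' @param k_range candidate cluster numbers; values outside
#'   `[2, nrow(profiles) - 1]` are dropped.
#' @return the selected `clustering_result`, with elements `asw_by_k` and
#'   `results` (all per-K results) added.
#' @export
select_k_by_asw <- function(profiles, k_range = 2:10, n_restarts = 1000,
                            seed = 1) {
  profiles <- as.matrix(profiles)
  k_range <- sort(unique(k_range))
  k_range <- k_range[k_range >= 2 & k_range <= nrow(profiles) - 1]
  if (length(k_range) == 0) stop("k_range is empty after restriction to [2, n-1]")
  results <- lapply(seq_along(k_range), function(i) {
    cluster_profiles(profiles, k_range[i], n_restarts = n_restarts,
                     seed = seed + i)
  })
  asw <- vapply(results, `[[`, numeric(1), "asw")
  best <- results[[which.max(asw)]]
  best$asw_by_k <- stats::setNames(asw, k_range)
  best$results <- results
  best
}

#' Label clusters by the modal direction and phase of their members
#'
#' Each cluster is labelled `<direction>-<phase>` (e.g. `up-IE`) by majority
#' vote over its member DEG calls; ties go to the earlier phase, then to
#' `up`.
#'
#' @param result a `clustering_result`.
#' @param deg_calls data.frame from [call_degs()] covering every assigned
#'   gene.
#' @return named character vector, one label per cluster id.
#' @export
label_clusters <- function(result, deg_calls) {
  genes <- names(result$assignments)
  idx <- match(genes, deg_calls$gene)
  if (anyNA(idx)) {
    stop("no DEG call for gene(s): ",
         paste(utils::head(genes[is.na(idx)], 3), collapse = ", "))
  }
  phase <- factor(deg_calls$phase[idx], levels = c("IE", "M", "L"))
  direction <- factor(deg_calls$direction[idx], levels = c("up", "down"))
  ks <- sort(unique(result$assignments))
  stats::setNames(vapply(ks, function(k) {
    in_k <- result$assignments == k
    tab <- table(direction[in_k], phase[in_k])
    cnt <- as.vector(tab)
    cand <- expand.grid(direction = rownames(tab), phase = colnames(tab),
                        stringsAsFactors = FALSE)
    # order candidates: earlier phase first, then "up" before "down"
    ord <- order(match(cand$phase, c("IE", "M", "L")),
                 match(cand$direction, c("up", "down")))
    cand <- cand[ord, ]
    cnt <- cnt[ord]
    pick <- which.max(cnt)   # first max in the tie-break order
    paste0(cand$direction[pick], "-", cand$phase[pick])
  }, character(1)), as.character(ks))
}

#' Smoothed DEG profiles for clustering
#'
#' Profiles are the fitted log2 ratios (fitted(t) - fitted(0)) of the DE
#' genes at the observed post-exposure time points, not standardized, so
#' magnitude separates up from down patterns.
#'
#' @param fits a `timecourse_fit_set`.
#' @param deg_calls data.frame from [call_degs()]; only rows with `is_de`
#'   are used.
#' @param at_times profile time points; default the observed positive times.
#' @return numeric matrix (DE genes x times).
#' @export
deg_profiles <- function(fits, deg_calls, at_times = NULL) {
  at_times <- at_times %||% sort(unique(fits$times[fits$times > 0]))
  genes <- deg_calls$gene[deg_calls$is_de]
  prof <- fitted_ratios(fits, at_times)
  prof[match(genes, fits$genes), , drop = FALSE]
}
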