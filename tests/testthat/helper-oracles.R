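# Independent oracle implementations used to cross-check the package's
# computational paths. These deliberately use plain loops and base fitting
# functions, never the package internals they verify.

# Local quadratic fit at a single point via lm() with tricube weights,
# reproducing the >= 3-distinct-times bandwidth floor.
naive_local_fit <- function(times, values, h, t0) {
  du <- sort(abs(unique(times) - t0))
  h_eff <- max(h, du[3] * 1.2)
  d <- times - t0
  w <- (1 - pmin(abs(d) / h_eff, 1)^3)^3
  w[abs(d) >= h_eff] <- 0
  fit <- lm(values ~ d + I(d^2), weights = w)
  unname(coef(fit)[1])
}

# Leave-one-out CV error for one bandwidth, by explicit refitting.
naive_loocv <- function(times, values, h) {
  pred <- vapply(seq_along(times), function(i) {
    naive_local_fit(times[-i], values[-i], h, times[i])
  }, numeric(1))
  mean((values - pred)^2)
}

# Brute-force average silhouette width with explicit loops.
brute_asw <- function(profiles, cl) {
  D <- as.matrix(dist(profiles))
  n <- nrow(profiles)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(k) {
      mean(D[i, cl == k])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Hypergeometric upper tail by explicit combinatorial summation.
brute_hyper <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Hypergeometric upper tail by enumerating every draw of n from N.
enum_hyper_draws <- function(k, K, n, N) {
  draws <- combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# Brute-force per-base window overlap for target assignment
# (BED-convention coordinates).
brute_targets <- function(peaks, annotation, window = 1000) {
  targets <- character()
  for (i in seq_len(nrow(annotation))) {
    lo <- max(annotation$start[i] - window, 0)
    hi <- annotation$end[i] + window
    gene_bases <- seq(lo, hi - 1)
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != annotation$chrom[i]) next
      peak_bases <- seq(peaks$start[j], peaks$end[j] - 1)
      if (length(intersect(gene_bases, peak_bases)) > 0) {
        targets <- c(targets, annotation$gene[i])
        break
      }
    }
  }
  toupper(targets)
}

# All permutations of 1:n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# Small simulated dataset shared by several tests.
tiny_sim <- function(seed = 1, n_genes = 120, ...) {
  simulate_expression(simulation_config(n_genes = n_genes, seed = seed, ...))
}
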