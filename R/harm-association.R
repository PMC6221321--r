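# Association of opioid-induced DEGs with published drug-harm scores: each
# DEG's cross-drug smoothed expression vector at its strongest-response time
# is tested against every harm-effect score vector with both a Pearson
# correlation and a quadratic polynomial regression; a pair is significant
# if either test's p-value is below 0.05 (nominal, no multiplicity
# correction).

#' The twelve harm-effect names used by default
#'
#' Expert-panel harm dimensions: the three physical-harm subscales and their
#' mean, the three dependence subscales and their mean, the three
#' social-harm subscales and their mean, and conditioned place preference.
#'
#' @return character vector of length 12.
#' @export
harm_effects <- function() {
  c("dependence", "physical_dependence", "psychological_dependence",
    "pleasure", "physical_harm", "acute_physical_harm",
    "chronic_physical_harm", "social_harm", "intoxication",
    "other_social_harm", "health_care_cost", "cpp")
}

#' Effects counted as dependence-type
#' @return character vector.
#' @export
dependence_effects <- function() {
  c("dependence", "physical_dependence", "psychological_dependence")
}

#' Read a harm-score table
#'
#' CSV with one row per harm effect (first column `effect`) and one column
#' per drug.
#'
#' @param path CSV path.
#' @return data.frame of class `harm_score_table`; drugs in columns.
#' @export
read_harm_scores <- function(path) {
  df <- read_table_skip_comments(path, sep = ",")
  if (names(df)[1] != "effect") stop("first column must be `effect`")
  class(df) <- c("harm_score_table", class(df))
  df
}

#' Write a harm-score table
#' @param harm a `harm_score_table` data.frame.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_harm_scores <- function(harm, path) {
  utils::write.table(harm, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

harm_drugs <- function(harm) setdiff(names(harm), "effect")

#' Cross-drug expression vector for one gene at one time point
#'
#' The vector of smoothed log2 ratios (fitted(t) - fitted(0)) for a gene
#' across drugs, in the given drug order. The gene needs a fit for every
#' drug; the time must lie on the shared evaluation grid.
#'
#' @param fits named list of `timecourse_fit_set` objects (one per drug).
#' @param gene gene symbol.
#' @param time_point evaluation time in hours.
#' @param drugs drug order; default `names(fits)`.
#' @return named numeric vector, one value per drug.
#' @export
build_drug_vector <- function(fits, gene, time_point, drugs = NULL) {
  drugs <- drugs %||% names(fits)
  missing <- setdiff(drugs, names(fits))
  if (length(missing)) stop("no fit for drug: ", paste(missing, collapse = ", "))
  vapply(drugs, function(d) {
    f <- fits[[d]]
    i <- match(gene, f$genes)
    if (is.na(i)) stop("gene ", gene, " missing from fit for drug ", d)
    fitted_ratios(f, time_point)[i, 1]
  }, numeric(1))
}

#' Pearson correlation test
#'
#' Sample correlation with the two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} df. Degenerate input (zero
#' variance in either vector) returns `r = NA`, `p = 1` and a degenerate
#' flag instead of failing.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `degenerate`.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = 1, degenerate = TRUE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    return(list(r = r, p = .Machine$double.xmin, degenerate = FALSE))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2), degenerate = FALSE)
}

#' Quadratic polynomial regression test
#'
#' OLS fit of `y = b0 + b1 x + b2 x^2`; returns the p-value of the F test of
#' `(b1, b2) = 0` against the intercept-only model (df 2 and n - 3). Designs
#' with fewer than three distinct `x` values are degenerate and return
#' `p = 1`; an exact fit returns the machine floor.
#'
#' @param x predictor (harm scores).
#' @param y response (expression ratios).
#' @return list with `p`, `degenerate`.
#' @export
quadratic_regression_test <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 5) stop("need n >= 5 for the F test on (2, n-3) df")
  if (length(unique(x)) <= 2) return(list(p = 1, degenerate = TRUE))
  X <- cbind(1, x, x^2)
  fit <- stats::lm.fit(X, y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(list(p = 1, degenerate = TRUE))
  if (sse <= sst * 1e-14) return(list(p = .Machine$double.xmin, degenerate = FALSE))
  F <- ((sst - sse) / 2) / (sse / (n - 3))
  list(p = stats::pf(F, 2, n - 3, lower.tail = FALSE), degenerate = FALSE)
}

#' Associate opioid DEGs with harm-effect scores across drugs
#'
#' For every DE gene of the opioid drug(s) and every harm effect, tests the
#' gene's cross-drug expression vector at its strongest-response time
#' (`t_max`; optionally every observed time point) against the effect's
#' score vector with both tests; the pair is significant if either p-value
#' is below `alpha`. No multiple-testing correction is applied (nominal
#' significance).
#'
#' @param deg_calls data.frame from [call_degs()] (opioid drug); only
#'   `is_de` rows are tested.
#' @param fits named list of `timecourse_fit_set` objects covering every
#'   drug column of `harm`.
#' @param harm a `harm_score_table`.
#' @param alpha nominal level (default 0.05).
#' @param all_timepoints if TRUE, test at every observed positive time
#'   instead of only `t_max`.
#' @return data.frame: `gene`, `drug`, `effect`, `time`, `pearson_r`,
#'   `pearson_p`, `quad_p`, `degenerate`, `significant`.
#' @export
associate <- function(deg_calls, fits, harm, alpha = 0.05,
                      all_timepoints = FALSE) {
  drugs <- harm_drugs(harm)
  missing <- setdiff(drugs, names(fits))
  if (length(missing)) stop("no fit for drug: ", paste(missing, collapse = ", "))
  degs <- deg_calls[deg_calls$is_de, , drop = FALSE]
  if (nrow(degs) == 0) {
    return(data.frame(gene = character(), drug = character(),
                      effect = character(), time = numeric(),
                      pearson_r = numeric(), pearson_p = numeric(),
                      quad_p = numeric(), degenerate = logical(),
                      significant = logical()))
  }
  S <- as.matrix(harm[, drugs, drop = FALSE])
  rownames(S) <- harm$effect
  # smoothed ratios per drug at all needed times, computed matrix-wise
  rows <- list()
  for (i in seq_len(nrow(degs))) {
    g <- degs$gene[i]
    times <- if (all_timepoints) {
      sort(unique(fits[[degs$drug[i]]]$times[fits[[degs$drug[i]]]$times > 0]))
    } else degs$t_max[i]
    for (t in times) {
      G <- build_drug_vector(fits, g, t, drugs)
      for (e in rownames(S)) {
        pe <- pearson_test(S[e, ], G)
        qu <- quadratic_regression_test(S[e, ], G)
        degen <- pe$degenerate && qu$degenerate
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, drug = degs$drug[i], effect = e, time = t,
          pearson_r = pe$r, pearson_p = pe$p, quad_p = qu$p,
          degenerate = degen,
          significant = min(pe$p, qu$p) < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes significantly associated with dependence-type effects
#'
#' @param associations data.frame from [associate()].
#' @param effects effect names counted as dependence-type; default
#'   [dependence_effects()].
#' @return character vector of gene symbols.
#' @export
dependence_associated_genes <- function(associations,
                                        effects = dependence_effects()) {
  unique(associations$gene[associations$significant &
                             associations$effect %in% effects])
}
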