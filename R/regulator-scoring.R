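# Dependence and harm-association scores for enriched transcription
# regulators: the dependence score of a regulator in a phase is the sum of
# the maximum absolute fold changes (within that phase, relative to the
# control time point) of the dependence-associated DEGs it regulates; the
# per-effect association scores are the analogous sums over the regulated
# DEGs associated with each harm effect.

.phase_window <- function(phase) {
  switch(phase,
         IE = c(0, 2), M = c(2, 4), L = c(4, 8),
         stop("phase must be one of IE, M, L; got ", phase))
}

#' Maximum absolute fold change of genes within a phase window
#'
#' \eqn{FC = 2^{\max_t |fitted(t) - fitted(0)|}} over the evaluation-grid
#' times falling in the phase window ((0,2\], (2,4\], (4,8\] hours); always
#' >= 1.
#'
#' @param fits a `timecourse_fit_set`.
#' @param genes gene symbols (must be in the fit set).
#' @param phase `"IE"`, `"M"`, or `"L"`.
#' @return named numeric vector of linear fold-change magnitudes.
#' @export
max_abs_fc_in_phase <- function(fits, genes, phase) {
  w <- .phase_window(phase)
  j <- which(fits$grid > w[1] & fits$grid <= w[2])
  if (length(j) == 0) stop("no evaluation-grid points in phase ", phase)
  i <- match(genes, fits$genes)
  if (anyNA(i)) stop("gene(s) missing from fits: ",
                     paste(genes[is.na(i)], collapse = ", "))
  i0 <- which(fits$grid == 0)
  dev <- abs(fits$fitted[i, j, drop = FALSE] - fits$fitted[i, i0])
  stats::setNames(2^apply(dev, 1, max), genes)
}

#' Dependence score of one regulator in one phase
#'
#' `N` is the number of dependence-associated DEGs in the phase that the
#' regulator targets; the score is the sum of their maximum absolute fold
#' changes within the phase. The direction is the majority direction of the
#' regulated DEGs (ties to `"up"`), kept separate from the unsigned score so
#' the score stays non-negative; signed presentation is
#' `ifelse(direction == "down", -1, 1) * dependence_score`.
#'
#' @param regulator_set a `regulator_set` from [assign_targets()], or a
#'   character vector of target symbols.
#' @param dep_assoc_degs data.frame of DEG calls ([call_degs()] rows)
#'   restricted to dependence-associated genes.
#' @param fits the opioid's `timecourse_fit_set`.
#' @param phase `"IE"`, `"M"`, or `"L"`.
#' @return list: `regulator`, `phase`, `N`, `dependence_score`, `direction`,
#'   `genes`, `fc` (per-gene fold changes).
#' @export
dependence_score <- function(regulator_set, dep_assoc_degs, fits, phase) {
  targets <- if (inherits(regulator_set, "regulator_set")) {
    regulator_set$targets
  } else normalize_symbols(regulator_set)
  reg_name <- if (inherits(regulator_set, "regulator_set")) {
    regulator_set$regulator
  } else NA_character_
  in_phase <- dep_assoc_degs[dep_assoc_degs$phase == phase, , drop = FALSE]
  genes <- intersect(targets, in_phase$gene)
  if (length(genes) == 0) {
    return(list(regulator = reg_name, phase = phase, N = 0L,
                dependence_score = 0, direction = NA_character_,
                genes = character(), fc = numeric()))
  }
  fc <- max_abs_fc_in_phase(fits, genes, phase)
  dirs <- in_phase$direction[match(genes, in_phase$gene)]
  direction <- if (sum(dirs == "down") > length(dirs) / 2) "down" else "up"
  list(regulator = reg_name, phase = phase, N = length(genes),
       dependence_score = sum(fc), direction = direction,
       genes = genes, fc = fc)
}

#' Per-effect association scores of one regulator in one phase
#'
#' For each harm effect, the sum of the maximum absolute fold changes
#' (within the phase) of the regulated DEGs significantly associated with
#' that effect.
#'
#' @inheritParams dependence_score
#' @param associations data.frame from [associate()].
#' @param deg_calls DEG calls for the opioid (phase lookup).
#' @param effects effect names to score; default [harm_effects()].
#' @return named numeric vector of association scores, one per effect.
#' @export
association_scores <- function(regulator_set, associations, deg_calls, fits,
                               phase, effects = harm_effects()) {
  targets <- if (inherits(regulator_set, "regulator_set")) {
    regulator_set$targets
  } else normalize_symbols(regulator_set)
  in_phase <- deg_calls[deg_calls$is_de & deg_calls$phase == phase, ,
                        drop = FALSE]
  vapply(effects, function(e) {
    assoc_genes <- unique(associations$gene[associations$significant &
                                              associations$effect == e])
    genes <- intersect(targets, intersect(assoc_genes, in_phase$gene))
    if (length(genes) == 0) return(0)
    sum(max_abs_fc_in_phase(fits, genes, phase))
  }, numeric(1))
}

#' Score enriched regulators across phases
#'
#' Builds the full regulator report for one opioid: for every enriched
#' regulator and every phase in which it regulates at least one
#' dependence-associated DEG, the dependence score, direction, and the
#' twelve per-effect association scores.
#'
#' @param regulator_sets named list of target-gene vectors (e.g. from
#'   [regulator_sets_from_peaks()]), typically restricted to regulators
#'   enriched at FDR < 0.05.
#' @param deg_calls DEG calls for the opioid.
#' @param associations data.frame from [associate()].
#' @param fits the opioid's `timecourse_fit_set`.
#' @param effects effects to score; default [harm_effects()].
#' @return data.frame: `regulator`, `phase`, `direction`, `N`,
#'   `dependence_score`, `signed_score`, one column per effect.
#' @export
score_regulators <- function(regulator_sets, deg_calls, associations, fits,
                             effects = harm_effects()) {
  dep_genes <- dependence_associated_genes(associations)
  dep_degs <- deg_calls[deg_calls$is_de & deg_calls$gene %in% dep_genes, ,
                        drop = FALSE]
  rows <- list()
  for (r in names(regulator_sets)) {
    for (ph in c("IE", "M", "L")) {
      ds <- dependence_score(regulator_sets[[r]], dep_degs, fits, ph)
      if (ds$N == 0) next
      es <- association_scores(regulator_sets[[r]], associations, deg_calls,
                               fits, ph, effects)
      row <- data.frame(regulator = r, phase = ph, direction = ds$direction,
                        N = ds$N, dependence_score = ds$dependence_score,
                        signed_score = ifelse(identical(ds$direction, "down"),
                                              -1, 1) * ds$dependence_score,
                        stringsAsFactors = FALSE)
      for (e in effects) row[[e]] <- es[[e]]
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(regulator = character(), phase = character(),
                      direction = character(), N = integer(),
                      dependence_score = numeric(), signed_score = numeric())
    for (e in effects) out[[e]] <- numeric()
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$dependence_score, -out$N, out$regulator), ]
  rownames(out) <- NULL
  out
}
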