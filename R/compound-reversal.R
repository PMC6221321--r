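# Connectivity-map-style signature reversal: compounds are ranked by a
# weighted Kolmogorov-Smirnov running-sum statistic comparing each
# compound's signed expression signature with the opioid's
# dependence-associated query signature; negative scores mean the compound's
# ranking opposes the query (a candidate reverser). Significance comes from
# a gene-label permutation null.

#' Build the query signature from dependence-associated DEGs
#'
#' Each gene's weight is its signed maximum absolute fold change over the
#' measured post-exposure time points (linear scale; negative = down).
#'
#' @param deg_calls DEG calls for the opioid ([call_degs()]).
#' @param fits the opioid's `timecourse_fit_set`.
#' @param genes genes to include (typically
#'   [dependence_associated_genes()]); default all DE genes.
#' @return named numeric vector of signed weights (class `query_signature`).
#' @export
query_signature <- function(deg_calls, fits, genes = NULL) {
  de <- deg_calls[deg_calls$is_de, , drop = FALSE]
  genes <- genes %||% de$gene
  de <- de[de$gene %in% genes, , drop = FALSE]
  if (nrow(de) == 0) stop("no DE genes to build a query signature from")
  times <- sort(unique(fits$times[fits$times > 0]))
  ratios <- fitted_ratios(fits, times)[match(de$gene, fits$genes), ,
                                       drop = FALSE]
  jmax <- max.col(abs(ratios), ties.method = "first")
  dmax <- ratios[cbind(seq_len(nrow(ratios)), jmax)]
  w <- ifelse(dmax >= 0, 1, -1) * 2^abs(dmax)
  structure(stats::setNames(w, normalize_symbols(de$gene)),
            class = "query_signature")
}

#' Build a query signature from scored regulators
#'
#' Each regulator's weight is its signed dependence score (direction gives
#' the sign), so compound libraries profiled on regulator genes can be
#' searched for reversers of the regulator program.
#'
#' @param regulator_scores data.frame from [score_regulators()].
#' @return named numeric vector of signed weights (class `query_signature`).
#' @export
regulator_query_signature <- function(regulator_scores) {
  rs <- regulator_scores[regulator_scores$N > 0, , drop = FALSE]
  if (nrow(rs) == 0) stop("no scored regulators")
  # one entry per regulator: the phase with the largest dependence score
  rs <- rs[order(-rs$dependence_score), ]
  rs <- rs[!duplicated(rs$regulator), ]
  structure(stats::setNames(rs$signed_score, normalize_symbols(rs$regulator)),
            class = "query_signature")
}

#' Read and filter a compound signature library
#'
#' TSV with columns `compound_id`, `gene`, `signed_fc`, and optionally `p`.
#' Entries are kept only if `p < p_threshold` (when present) and
#' `|signed_fc| > fc_threshold`, the compound-DEG convention.
#'
#' @param path TSV path.
#' @param p_threshold compound DEG p-value cutoff (default 0.05).
#' @param fc_threshold absolute fold-change cutoff, strict (default 1.2).
#' @return named list of signed fold-change vectors, one per compound.
#' @export
read_compound_library <- function(path, p_threshold = 0.05,
                                  fc_threshold = 1.2) {
  df <- read_table_skip_comments(path)
  req <- c("compound_id", "gene", "signed_fc")
  if (!all(req %in% names(df))) {
    stop("compound library needs columns: ", paste(req, collapse = ", "))
  }
  keep <- abs(df$signed_fc) > fc_threshold
  if ("p" %in% names(df)) keep <- keep & df$p < p_threshold
  df <- df[keep, , drop = FALSE]
  df$gene <- normalize_symbols(df$gene)
  lapply(split(df, df$compound_id), function(d) {
    d <- d[!duplicated(d$gene), ]
    stats::setNames(d$signed_fc, d$gene)
  })
}

# Weighted-KS enrichment score of hit positions in a ranked list with
# weights w (absolute fold changes): the sum of the maximal positive and
# maximal negative excursions of the running-sum deviation. For a one-sided
# deviation this equals the classic signed extreme; unlike the extreme it
# is exactly antisymmetric under reversal of the ranked list (no tie
# ambiguity when the two excursions match in magnitude). 0 for an empty or
# full hit set.
.ks_es <- function(hits, w) {
  if (!any(hits)) return(0)
  N <- length(w)
  m <- sum(hits)
  if (m == N) return(0)
  p_hit <- cumsum(w * hits) / sum(w[hits])
  p_miss <- cumsum(!hits) / (N - m)
  dev <- p_hit - p_miss
  max(dev, 0) + min(dev, 0)
}

# Ranked order of a compound signature: decreasing signed fold change, ties
# broken by gene id for determinism.
.compound_order <- function(compound) {
  order(-compound, names(compound))
}

#' Connectivity score between a query and a compound signature
#'
#' Compound genes are ranked by signed fold change; a weighted
#' Kolmogorov-Smirnov enrichment score is computed for the query's
#' up-weighted genes (`ES_up`) and down-weighted genes (`ES_down`), and the
#' connectivity score is `(ES_up - ES_down) / 2`, in \[-1, 1\]. Negative
#' scores mean the compound regulates the query's genes in the opposite
#' direction (candidate reversal). The running-sum statistic uses the sum of
#' the maximal positive and negative excursions, so the score is exactly
#' antisymmetric under negating either signature (for distinct fold-change
#' values; ties in the compound ranking are broken by gene id).
#'
#' @param query named signed weight vector ([query_signature()]).
#' @param compound named signed fold-change vector.
#' @return list: `score`, `n_shared`, `comparable`, `opposite` (shared genes
#'   regulated in opposite directions).
#' @export
connectivity_score <- function(query, compound) {
  qn <- normalize_symbols(names(query))
  if (any(query == 0)) stop("query weights must be nonzero")
  ord <- .compound_order(compound)
  genes <- normalize_symbols(names(compound))[ord]
  w <- abs(compound[ord])
  shared <- intersect(qn, genes)
  if (length(shared) == 0) {
    return(list(score = NA_real_, n_shared = 0L, comparable = FALSE,
                opposite = character()))
  }
  up <- qn[query > 0]
  down <- qn[query < 0]
  es_up <- .ks_es(genes %in% up, w)
  es_down <- .ks_es(genes %in% down, w)
  score <- max(min((es_up - es_down) / 2, 1), -1)
  idx <- match(shared, normalize_symbols(names(compound)))
  opposite <- shared[sign(query[match(shared, qn)]) !=
                       sign(compound[idx])]
  list(score = score, n_shared = length(shared), comparable = TRUE,
       opposite = opposite)
}

#' Permutation p-value for reversal
#'
#' Null distribution: connectivity scores after shuffling the compound's
#' gene labels (equivalently, random placement of the query's hits in the
#' compound's ranked list). One-sided for reversal:
#' `p = (1 + #\{null <= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams connectivity_score
#' @param n_perm number of permutations (>= 1; 100+ recommended).
#' @param seed integer RNG seed.
#' @return list: `perm_p`, `observed`.
#' @export
permutation_p <- function(query, compound, n_perm = 999, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- connectivity_score(query, compound)
  if (!obs$comparable) return(list(perm_p = NA_real_, observed = NA_real_))
  ord <- .compound_order(compound)
  genes <- normalize_symbols(names(compound))[ord]
  w <- abs(compound[ord])
  N <- length(w)
  qn <- normalize_symbols(names(query))
  m_up <- sum(genes %in% qn[query > 0])
  m_down <- sum(genes %in% qn[query < 0])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    pos <- sample.int(N, m_up + m_down)
    hu <- hd <- logical(N)
    if (m_up > 0) hu[pos[seq_len(m_up)]] <- TRUE
    if (m_down > 0) hd[pos[m_up + seq_len(m_down)]] <- TRUE
    max(min((.ks_es(hu, w) - .ks_es(hd, w)) / 2, 1), -1)
  }, numeric(1))
  list(perm_p = (1 + sum(null <= obs$score)) / (n_perm + 1),
       observed = obs$score)
}

#' Rank a compound library by reversal of a query signature
#'
#' Scores every compound against the query, sorts ascending by connectivity
#' score (strongest reversal first; ties by shared-gene count, then
#' permutation p, then compound id), and reports the shared genes regulated
#' in opposite directions.
#' Compounds sharing no genes with the query are excluded (with a message).
#'
#' @inheritParams connectivity_score
#' @param library named list of compound signatures
#'   ([read_compound_library()]).
#' @param n_perm permutations per compound; `0` skips permutation p-values.
#' @param seed integer RNG seed.
#' @return data.frame: `compound`, `n_shared`, `score`, `perm_p`,
#'   `n_opposite`; per-compound opposite-direction gene lists attached as
#'   attribute `"opposite_genes"`.
#' @export
rank_compounds <- function(query, library, n_perm = 199, seed = 1) {
  if (length(library) == 0) stop("compound library is empty")
  scored <- lapply(library, connectivity_score, query = query)
  comparable <- vapply(scored, `[[`, logical(1), "comparable")
  if (any(!comparable)) {
    message(sum(!comparable),
            " compound(s) share no genes with the query; excluded")
  }
  ids <- names(library)[comparable]
  scored <- scored[comparable]
  pp <- rep(NA_real_, length(ids))
  if (n_perm > 0) {
    pp <- vapply(seq_along(ids), function(i) {
      permutation_p(query, library[[ids[i]]], n_perm = n_perm,
                    seed = seed + i)$perm_p
    }, numeric(1))
  }
  out <- data.frame(
    compound = ids,
    n_shared = vapply(scored, `[[`, integer(1), "n_shared"),
    score = vapply(scored, `[[`, numeric(1), "score"),
    perm_p = pp,
    n_opposite = vapply(scored, function(s) length(s$opposite), integer(1)),
    stringsAsFactors = FALSE)
  # ties on the score (e.g. several compounds at the clipped extreme) go to
  # the compound sharing more genes with the query - the stronger evidence -
  # then to the permutation p and the id
  ord <- order(out$score, -out$n_shared, out$perm_p, out$compound)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "opposite_genes") <- stats::setNames(
    lapply(scored, `[[`, "opposite")[ord], out$compound)
  out
}
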