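# Synthetic multi-drug time-course expression data with planted ground
# truth: DE genes following up/down x IE/M/L temporal templates, harm-score
# tables affinely tied to planted genes' cross-drug amplitudes, a toy genome
# with regulator binding peaks placed inside/outside the 1000-bp TSS/TTS
# windows of planted targets, functional gene sets, and a compound library
# containing an exact-negation reverser among random decoys.
#
# Structural choices (which genes are DE, their patterns and amplitudes,
# baselines, planted maps) are drawn from a fixed internal RNG stream so
# that the user seed changes measurement noise only, never the ground-truth
# structure.

.STRUCTURAL_SEED <- 20181107L

.profile_templates <- function() {
  # unit-amplitude response shapes on [0, 8] h; f(0) = 0, max |f| = 1,
  # peaking at 1 h (IE), 3 h (M), and 8 h (L)
  list(
    IE = function(t) t * exp(1 - t),
    M  = function(t) (t / 3)^3 * exp(3 * (1 - t / 3)),
    L  = function(t) (t / 8)^2
  )
}

.pattern_table <- function() {
  data.frame(
    pattern = c("up-IE", "up-M", "up-L", "down-IE", "down-M", "down-L"),
    phase = rep(c("IE", "M", "L"), 2),
    sign = rep(c(1, -1), each = 3),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the emulated study design: six drugs of abuse (two
#' opioids), samples at 0/1/2/4/8 h with three biological replicates, a
#' shared naive control at 0 h, log2-intensity noise, and planted DE genes
#' at linear fold change 2 following six temporal templates.
#'
#' @param n_genes number of genes.
#' @param drugs drug names.
#' @param opioids drugs flagged as opioids (DE genes are planted for these).
#' @param time_grid_hours sampling times; strictly increasing, starting at 0.
#' @param n_replicates biological replicates per (drug, time); >= 2.
#' @param noise_sd Gaussian noise SD in log2-intensity units; > 0.
#' @param de_fraction fraction of genes planted as DE per opioid, in \[0, 1).
#' @param fc_planted linear-scale fold change of planted DE genes.
#' @param seed integer seed driving the noise stream.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000,
                              drugs = c("morphine", "heroin", "cocaine",
                                        "methamphetamine", "ethanol",
                                        "nicotine"),
                              opioids = c("morphine", "heroin"),
                              time_grid_hours = c(0, 1, 2, 4, 8),
                              n_replicates = 3,
                              noise_sd = 0.2,
                              de_fraction = 0.1,
                              fc_planted = 2.0,
                              seed = 1) {
  if (n_genes < 1) stop("invalid field n_genes: must be >= 1")
  if (is.unsorted(time_grid_hours, strictly = TRUE) ||
      time_grid_hours[1] != 0) {
    stop("invalid field time_grid_hours: must be strictly increasing and start at 0")
  }
  if (n_replicates < 2) stop("invalid field n_replicates: must be >= 2")
  if (noise_sd <= 0) stop("invalid field noise_sd: must be > 0")
  if (de_fraction < 0 || de_fraction >= 1) {
    stop("invalid field de_fraction: must be in [0, 1)")
  }
  if (fc_planted < 1) stop("invalid field fc_planted: must be >= 1")
  if (!all(opioids %in% drugs)) {
    stop("invalid field opioids: ",
         paste(setdiff(opioids, drugs), collapse = ", "), " not in drugs")
  }
  structure(list(n_genes = n_genes, drugs = drugs, opioids = opioids,
                 time_grid_hours = time_grid_hours,
                 n_replicates = n_replicates, noise_sd = noise_sd,
                 de_fraction = de_fraction, fc_planted = fc_planted,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic structural layout: DE gene indices per opioid, pattern per
# responsive gene, per-drug amplitudes, baselines, harm-planted genes.
.simulate_structure <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.STRUCTURAL_SEED)

  n <- config$n_genes
  genes <- sprintf("G%06d", seq_len(n))
  n_de <- round(n * config$de_fraction)
  pt <- .pattern_table()

  de_idx <- list()
  offset <- 0
  for (op in config$opioids) {
    de_idx[[op]] <- if (n_de > 0) ((seq_len(n_de) - 1 + offset) %% n) + 1
                    else integer()
    offset <- offset + max(floor(n_de / 3), 1)   # partial overlap of opioids
  }
  responsive <- sort(unique(unlist(de_idx)))
  pattern <- stats::setNames(rep(NA_character_, n), genes)
  pattern[responsive] <- pt$pattern[((seq_along(responsive) - 1) %% 6) + 1]

  amp_log2 <- matrix(0, n, length(config$drugs),
                     dimnames = list(genes, config$drugs))
  a <- log2(config$fc_planted)
  for (g in responsive) {
    s <- pt$sign[match(pattern[g], pt$pattern)]
    amp_log2[g, ] <- s * stats::runif(length(config$drugs), 0.15, 0.85) * a
    for (op in config$opioids) {
      if (g %in% de_idx[[op]]) amp_log2[g, op] <- s * a
    }
  }

  # harm-planted genes: disjoint picks from the genes DE in EVERY flagged
  # opioid, so that all genes of one effect can share a single cross-drug
  # amplitude profile (full amplitude in the opioids); the effect's score
  # vector is then an affine image of every planted gene's own profile
  planted_effects <- c(dependence_effects(), "pleasure")
  pool <- Reduce(intersect, de_idx)
  effect_map <- list()
  for (e in planted_effects) {
    take <- utils::head(pool, 3)
    pool <- setdiff(pool, take)
    if (length(take) == 0) next
    profile <- stats::runif(length(config$drugs), 0.15, 1.0)
    profile[match(config$opioids, config$drugs)] <- 1
    for (g in take) {
      s <- pt$sign[match(pattern[g], pt$pattern)]
      amp_log2[g, ] <- s * profile * a
    }
    effect_map[[e]] <- genes[take]
  }

  list(genes = genes,
       de_idx = de_idx,
       pattern = pattern,
       amp_log2 = amp_log2,
       baseline = stats::runif(n, 4, 12),
       effect_map = effect_map)
}

#' Simulate a multi-drug time-course expression dataset
#'
#' Non-DE genes are flat (baseline plus Gaussian noise); planted DE genes
#' follow one of six unit-amplitude temporal templates (up/down x IE/M/L)
#' scaled to the configured fold change for the opioid(s) where they are
#' planted, with weaker same-shaped responses for the remaining drugs. The
#' time-0 control is a single naive group shared by all drugs. Identical
#' seeds give identical output; changing the seed changes the noise draw
#' only, never the planted structure.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (ground-truth list: `de_genes` data.frame, `amplitudes`, `patterns`,
#'   `effect_associated_genes`, later extended by the regulator/compound
#'   generator).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  st <- .simulate_structure(config)
  tmpl <- .profile_templates()
  pt <- .pattern_table()

  times_pos <- config$time_grid_hours[config$time_grid_hours > 0]
  samples <- rbind(
    data.frame(drug = "control", time_hours = 0,
               replicate = seq_len(config$n_replicates)),
    expand.grid(replicate = seq_len(config$n_replicates),
                time_hours = times_pos, drug = config$drugs,
                stringsAsFactors = FALSE)[, c("drug", "time_hours", "replicate")]
  )
  samples$sample <- sprintf("%s|t%g|r%d", samples$drug, samples$time_hours,
                            samples$replicate)

  mean_mat <- matrix(st$baseline, config$n_genes, nrow(samples),
                     dimnames = list(st$genes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    if (samples$time_hours[j] == 0) next
    d <- samples$drug[j]
    t <- samples$time_hours[j]
    resp <- which(!is.na(st$pattern))
    if (length(resp)) {
      ph <- pt$phase[match(st$pattern[resp], pt$pattern)]
      f <- vapply(ph, function(p) tmpl[[p]](t), numeric(1))
      mean_mat[resp, j] <- mean_mat[resp, j] + st$amp_log2[resp, d] * f
    }
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  values <- mean_mat + matrix(stats::rnorm(length(mean_mat),
                                           sd = config$noise_sd),
                              nrow(mean_mat))

  de_rows <- list()
  for (op in config$opioids) {
    idx <- st$de_idx[[op]]
    if (length(idx) == 0) next
    p <- st$pattern[idx]
    de_rows[[op]] <- data.frame(
      gene = st$genes[idx], drug = op, pattern = p,
      phase = pt$phase[match(p, pt$pattern)],
      direction = ifelse(pt$sign[match(p, pt$pattern)] > 0, "up", "down"),
      fc_linear = pt$sign[match(p, pt$pattern)] * config$fc_planted,
      stringsAsFactors = FALSE)
  }
  de_genes <- if (length(de_rows)) do.call(rbind, de_rows) else
    data.frame(gene = character(), drug = character(), pattern = character(),
               phase = character(), direction = character(),
               fc_linear = numeric())
  rownames(de_genes) <- NULL

  truth <- list(
    de_genes = de_genes,
    patterns = st$pattern[!is.na(st$pattern)],
    amplitudes = st$amp_log2,
    effect_associated_genes = st$effect_map,
    regulator_target_map = NULL,
    reversal_compound_ids = NULL
  )
  list(dataset = expression_dataset(values, samples), truth = truth)
}

#' Simulate a harm-score table
#'
#' Twelve-effect by drug score table on the expert-panel 0-3 scale. For each
#' effect with planted genes, the scores are an affine image of the planted
#' genes' shared cross-drug amplitude profile plus small Gaussian noise, so
#' the association stage can recover the planted (gene, effect) pairs;
#' effects without planted genes get scores independent of expression.
#'
#' @param drugs drug names (>= 4; cross-drug correlation is meaningless
#'   below that).
#' @param effects harm-effect names; default [harm_effects()].
#' @param planted named list: effect -> planted gene vector.
#' @param truth ground truth from [simulate_expression()] (supplies the
#'   amplitude profiles).
#' @param seed integer RNG seed.
#' @param score_noise_sd SD of the score noise (default 0.05).
#' @return a `harm_score_table` data.frame (`effect` column plus one column
#'   per drug).
#' @export
simulate_harm_scores <- function(drugs, effects = harm_effects(),
                                 planted = list(), truth, seed = 1,
                                 score_noise_sd = 0.05) {
  if (length(effects) == 0) stop("effect list is empty")
  if (length(drugs) < 4) stop("need >= 4 drugs for cross-drug association")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  S <- matrix(NA_real_, length(effects), length(drugs),
              dimnames = list(effects, drugs))
  for (e in effects) {
    genes <- planted[[e]]
    if (!is.null(genes) && length(genes) > 0) {
      prof <- abs(truth$amplitudes[genes[1], drugs])
      g <- prof / max(abs(prof))
      S[e, ] <- 1.5 + 1.2 * g + stats::rnorm(length(drugs),
                                             sd = score_noise_sd)
    } else {
      S[e, ] <- stats::runif(length(drugs), 0.5, 3.0)
    }
  }
  out <- data.frame(effect = effects, S, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("harm_score_table", class(out))
  out
}

#' Simulate functional gene sets
#'
#' A handful of "planted" sets drawn from the responsive genes (so that
#' functional enrichment of DEG clusters has signal) plus random decoy sets.
#'
#' @param truth ground truth from [simulate_expression()].
#' @param universe all gene symbols.
#' @param n_sets total number of sets (default 40).
#' @param seed integer RNG seed.
#' @return named list of gene-symbol vectors.
#' @export
simulate_gene_sets <- function(truth, universe, n_sets = 40, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sets <- list()
  resp <- names(truth$patterns)
  for (p in unique(truth$patterns)) {
    members <- resp[truth$patterns == p]
    if (length(members) < 3) next
    extra <- sample(setdiff(universe, members),
                    min(10, length(universe) - length(members)))
    sets[[sprintf("PLANTED_%s", toupper(gsub("-", "_", p)))]] <-
      c(members, extra)
  }
  i <- 0
  while (length(sets) < n_sets) {
    i <- i + 1
    sets[[sprintf("RANDOM_%03d", i)]] <-
      sample(universe, min(length(universe), sample(10:50, 1)))
  }
  lapply(sets, normalize_symbols)
}

#' Simulate a toy genome, regulator peaks, and a compound library
#'
#' Emits (i) a single-chromosome annotation (one transcript per gene,
#' 10-kb spacing, alternating strands), (ii) binding peaks for a panel of
#' regulators placed 500 bp upstream of each planted target's TSS (well
#' inside the 1000-bp window) and nowhere near non-targets, with the first
#' regulators preferentially targeting dependence-associated planted genes,
#' and (iii) a compound signature library containing one exact-negation
#' reverser of the planted dependence signature among random decoys (plus
#' entries failing the p/fold-change filters, to exercise loading).
#'
#' @param truth ground truth from [simulate_expression()]; returned updated.
#' @param config the [simulation_config()].
#' @param n_regulators regulator panel size (default 20).
#' @param n_planted_regulators regulators enriched for planted
#'   dependence-associated genes (default 5).
#' @param n_compounds library size (default 200).
#' @param seed integer RNG seed (structure of this stage).
#' @return list: `annotation` (BED-convention data.frame), `peaks`
#'   (BED-convention data.frame with `name` = regulator), `compounds`
#'   (data.frame `compound_id`, `gene`, `signed_fc`, `p`), `truth` (updated
#'   with `regulator_target_map` and `reversal_compound_ids`).
#' @export
simulate_regulators_and_compounds <- function(truth, config,
                                              n_regulators = 20,
                                              n_planted_regulators = 5,
                                              n_compounds = 200,
                                              seed = 1) {
  if (is.null(truth$de_genes) || nrow(truth$de_genes) == 0) {
    stop("truth has no planted DE genes; run simulate_expression first")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  genes <- rownames(truth$amplitudes)
  n <- length(genes)
  starts <- 10000 * seq_len(n)
  annotation <- data.frame(
    gene = genes, chrom = "chr1", start = starts, end = starts + 2000,
    strand = rep(c("+", "-"), length.out = n), stringsAsFactors = FALSE)

  dep_genes <- unique(unlist(
    truth$effect_associated_genes[dependence_effects()]))
  dep_genes <- dep_genes[!is.null(dep_genes)]
  regs <- sprintf("REG%02d", seq_len(n_regulators))
  target_map <- list()
  for (i in seq_len(n_regulators)) {
    if (i <= n_planted_regulators && length(dep_genes) > 0) {
      core <- sample(dep_genes, min(length(dep_genes), 6))
      extra <- sample(setdiff(genes, core), min(n - length(core), 4))
      target_map[[regs[i]]] <- sort(unique(c(core, extra)))
    } else {
      target_map[[regs[i]]] <- sort(sample(genes, min(n, 10)))
    }
  }

  peak_rows <- list()
  for (r in regs) {
    tg <- target_map[[r]]
    a <- annotation[match(tg, annotation$gene), ]
    mid <- ifelse(a$strand == "+", a$start - 500, a$end + 500)
    peak_rows[[r]] <- data.frame(
      chrom = a$chrom, start = pmax(mid - 100, 0), end = mid + 100,
      name = r, stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peak_rows)
  rownames(peaks) <- NULL

  # planted dependence signature: signed true fold changes of the
  # dependence-associated planted genes (opioid rows of the DE table)
  sig_genes <- intersect(dep_genes, truth$de_genes$gene)
  sig <- truth$de_genes[match(sig_genes, truth$de_genes$gene), ]
  reverser_id <- "CMP_R001"
  comp_rows <- list(data.frame(
    compound_id = reverser_id, gene = sig$gene,
    signed_fc = -sig$fc_linear, p = 0.001, stringsAsFactors = FALSE))
  sig_size <- min(n, 40)
  for (i in seq_len(n_compounds - 1)) {
    id <- sprintf("CMP%04d", i)
    gset <- sample(genes, sig_size)
    comp_rows[[length(comp_rows) + 1]] <- data.frame(
      compound_id = id, gene = gset,
      signed_fc = sample(c(-1, 1), sig_size, replace = TRUE) *
        stats::runif(sig_size, 1.25, 3),
      p = stats::runif(sig_size, 0.0005, 0.04), stringsAsFactors = FALSE)
    # a few entries that must be dropped by the loader's DEG filter
    comp_rows[[length(comp_rows) + 1]] <- data.frame(
      compound_id = id, gene = sample(genes, 2),
      signed_fc = c(1.1, -2), p = c(0.01, 0.5), stringsAsFactors = FALSE)
  }
  compounds <- do.call(rbind, comp_rows)
  rownames(compounds) <- NULL

  truth$regulator_target_map <- target_map
  truth$reversal_compound_ids <- reverser_id
  list(annotation = annotation, peaks = peaks, compounds = compounds,
       truth = truth)
}

#' Write the full synthetic input bundle to a directory
#'
#' Generates and writes every pipeline input: expression TSV + sample sheet
#' CSV, harm-score CSV, functional gene sets GMT, annotation GFF3, peaks
#' BED, compound signature TSV, and the ground truth as JSON.
#'
#' @param dir output directory (created if needed).
#' @param config a [simulation_config()].
#' @param ... passed to [simulate_regulators_and_compounds()].
#' @return invisible list: `files` (paths to everything written) plus the
#'   in-memory `dataset`, `ground_truth`, `harm`, `gene_sets`, `annotation`,
#'   `peaks`, `compounds`.
#' @export
write_synthetic_bundle <- function(dir, config = simulation_config(), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(config)
  harm <- simulate_harm_scores(config$drugs,
                               planted = sim$truth$effect_associated_genes,
                               truth = sim$truth, seed = config$seed + 1)
  sets <- simulate_gene_sets(sim$truth, sim$dataset$gene_ids,
                             seed = config$seed + 2)
  rc <- simulate_regulators_and_compounds(sim$truth, config,
                                          seed = config$seed + 3, ...)
  truth <- rc$truth

  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.csv"),
    harm = file.path(dir, "harm_scores.csv"),
    gmt = file.path(dir, "genesets.gmt"),
    annotation = file.path(dir, "annotation.gff3"),
    peaks = file.path(dir, "peaks.bed"),
    compounds = file.path(dir, "compounds.tsv"),
    truth = file.path(dir, "truth.json"))

  write_expression(sim$dataset, paths$expression, paths$samples)
  write_harm_scores(harm, paths$harm)
  write_gmt(sets, paths$gmt)

  ann_gr <- GenomicRanges::GRanges(
    seqnames = rc$annotation$chrom,
    ranges = IRanges::IRanges(start = rc$annotation$start + 1,
                              end = rc$annotation$end),
    strand = rc$annotation$strand,
    type = "gene", ID = rc$annotation$gene, Name = rc$annotation$gene)
  rtracklayer::export(ann_gr, paths$annotation, format = "GFF3")

  pk_gr <- GenomicRanges::GRanges(
    seqnames = rc$peaks$chrom,
    ranges = IRanges::IRanges(start = rc$peaks$start + 1, end = rc$peaks$end),
    name = rc$peaks$name)
  rtracklayer::export(pk_gr, paths$peaks, format = "BED")

  utils::write.table(rc$compounds, paths$compounds, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(de_genes = truth$de_genes,
         patterns = as.list(truth$patterns),
         effect_associated_genes = truth$effect_associated_genes,
         regulator_target_map = truth$regulator_target_map,
         reversal_compound_ids = truth$reversal_compound_ids),
    paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(list(files = paths, dataset = sim$dataset, ground_truth = truth,
                 harm = harm, gene_sets = sets, annotation = rc$annotation,
                 peaks = rc$peaks, compounds = rc$compounds))
}
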