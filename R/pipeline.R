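# End-to-end orchestration: de -> cluster -> enrich(functional) ->
# associate -> enrich(regulator) -> score-regulators -> reverse, with
# deterministic seeding, provenance headers on every output table, and
# input validation.

#' Pipeline configuration
#'
#' @param expression,samples,harm,gmt,annotation,peaks,compounds input file
#'   paths (the layout written by [write_synthetic_bundle()]).
#' @param out_dir output directory for stage tables.
#' @param opioids drugs to analyze for DE (the rest only complete the
#'   cross-drug harm vectors).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param fc_threshold DE fold-change threshold (default 1.2).
#' @param k_range candidate cluster numbers (default 2:10).
#' @param n_restarts k-means restarts (default 1000).
#' @param n_perm reversal permutations (default 199).
#' @param window_bp regulator target window (default 1000).
#' @param seed master integer seed; per-stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, samples = NULL, harm, gmt,
                            annotation, peaks, compounds, out_dir,
                            opioids = c("morphine", "heroin"),
                            alpha = 0.05, fc_threshold = 1.2,
                            k_range = 2:10, n_restarts = 1000,
                            n_perm = 199, window_bp = 1000, seed = 1) {
  if (alpha <= 0 || fc_threshold <= 0) stop("thresholds must be positive")
  structure(list(expression = expression, samples = samples, harm = harm,
                 gmt = gmt, annotation = annotation, peaks = peaks,
                 compounds = compounds, out_dir = out_dir, opioids = opioids,
                 alpha = alpha, fc_threshold = fc_threshold,
                 k_range = k_range, n_restarts = n_restarts, n_perm = n_perm,
                 window_bp = window_bp, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Config from a bundle directory
#'
#' Convenience constructor pointing at the standard file names of a
#' [write_synthetic_bundle()] directory.
#'
#' @param dir bundle directory.
#' @param out_dir output directory (default `file.path(dir, "results")`).
#' @param ... passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
bundle_config <- function(dir, out_dir = file.path(dir, "results"), ...) {
  pipeline_config(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.csv"),
    harm = file.path(dir, "harm_scores.csv"),
    gmt = file.path(dir, "genesets.gmt"),
    annotation = file.path(dir, "annotation.gff3"),
    peaks = file.path(dir, "peaks.bed"),
    compounds = file.path(dir, "compounds.tsv"),
    out_dir = out_dir, ...)
}

#' Validate pipeline inputs
#'
#' Checks file existence and dialects (TSV/CSV/GMT/BED/GFF3), the time
#' grid, replicate counts, drug consistency between the expression matrix
#' and the harm table, and the symbol-namespace overlap between the
#' expression genes and the gene-set universe (warning below 80%). Errors
#' and warnings are distinguished by level.
#'
#' @param config a `pipeline_config`.
#' @return data.frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows means a clean bundle.
#' @export
validate_inputs <- function(config) {
  probs <- list()
  add <- function(level, msg) {
    probs[[length(probs) + 1]] <<- data.frame(level = level, message = msg,
                                              stringsAsFactors = FALSE)
  }
  for (f in c("expression", "harm", "gmt", "annotation", "peaks",
              "compounds")) {
    if (!file.exists(config[[f]])) add("error", paste0("missing file: ",
                                                       config[[f]]))
  }
  if (length(probs)) return(do.call(rbind, probs))

  ds <- tryCatch(read_expression(config$expression, config$samples),
                 error = function(e) {
                   add("error", paste("expression:", conditionMessage(e)))
                   NULL
                 })
  if (!is.null(ds)) {
    tg <- sort(unique(ds$samples$time_hours))
    if (tg[1] != 0) add("error", "time grid does not start at 0")
    reps <- table(ds$samples$drug, ds$samples$time_hours)
    if (any(reps[reps > 0] < 2)) {
      add("warning", "some (drug, time) groups have < 2 replicates")
    }
  }

  gmt_lines <- readLines(config$gmt)
  nf <- lengths(strsplit(gmt_lines, "\t", fixed = TRUE))
  bad <- which(nf < 3)
  if (length(bad)) {
    add("error", paste0("GMT line ", bad[1], " has ", nf[bad[1]],
                        " fields (< 3)"))
  }

  bed_lines <- strsplit(readLines(config$peaks), "\t", fixed = TRUE)
  for (i in seq_along(bed_lines)) {
    f <- bed_lines[[i]]
    if (length(f) >= 3 && !is.na(suppressWarnings(as.numeric(f[2]))) &&
        as.numeric(f[2]) >= as.numeric(f[3])) {
      add("error", paste0("BED line ", i, ": start >= end"))
    }
  }

  harm <- tryCatch(read_harm_scores(config$harm), error = function(e) {
    add("error", paste("harm table:", conditionMessage(e)))
    NULL
  })
  if (!is.null(harm) && !is.null(ds)) {
    missing <- setdiff(harm_drugs(harm), dataset_drugs(ds))
    if (length(missing)) {
      add("error", paste0("harm-table drug(s) missing from expression data: ",
                          paste(missing, collapse = ", ")))
    }
    missing_op <- setdiff(config$opioids, harm_drugs(harm))
    if (length(missing_op)) {
      add("error", paste0("configured opioid(s) missing from harm table: ",
                          paste(missing_op, collapse = ", ")))
    }
  }
  if (length(probs) == 0 && !is.null(ds)) {
    sets <- read_gmt(config$gmt)
    setg <- unique(unlist(sets))
    overlap <- mean(setg %in% ds$gene_ids)
    if (overlap < 0.8) {
      add("warning", sprintf(
        "gene-set universe overlap with expression genes is %.0f%% (< 80%%)",
        100 * overlap))
    }
  }
  if (length(probs) == 0) {
    return(data.frame(level = character(), message = character()))
  }
  do.call(rbind, probs)
}

#' Run the full pipeline
#'
#' Executes the seven stages for every configured opioid and writes one
#' provenance-headed TSV per stage into `config$out_dir`: DEG calls,
#' cluster assignments (+ ASW by K), functional enrichment per cluster,
#' harm associations, regulator enrichment, regulator scores, and the
#' ranked compound-reversal table. Re-running with an identical config
#' reproduces byte-identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return invisible named list of all stage results.
#' @export
run_pipeline <- function(config) {
  val <- validate_inputs(config)
  if (any(val$level == "error")) {
    stop("input validation failed:\n  ",
         paste(val$message[val$level == "error"], collapse = "\n  "))
  }
  for (w in val$message[val$level == "warning"]) warning(w, call. = FALSE)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = paste0("odmap ", as.character(utils::packageVersion("odmap"))),
               config_md5 = config_hash(unclass(config)),
               seed = config$seed)
  out <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ds <- read_expression(config$expression, config$samples)
  harm <- read_harm_scores(config$harm)
  sets <- read_gmt(config$gmt)
  annotation <- read_annotation(config$annotation)
  peaks <- read_peaks(config$peaks)
  library_ <- read_compound_library(config$compounds,
                                    fc_threshold = config$fc_threshold)

  fits <- stage("de", fit_all_drugs(ds, harm_drugs(harm)))
  degs <- stage("de", do.call(rbind, lapply(config$opioids, function(op) {
    call_degs(fits = fits[[op]], alpha = config$alpha,
              fc_threshold = config$fc_threshold)
  })))
  message("[de] ", sum(degs$is_de), " DE calls across ",
          length(config$opioids), " opioid(s) from ",
          length(ds$gene_ids), " genes")
  write_table_provenance(degs, out("degs.tsv"), meta)

  clusters <- asw_tabs <- list()
  enr_fun <- list()
  for (op in config$opioids) {
    opdeg <- degs[degs$drug == op, ]
    prof <- deg_profiles(fits[[op]], opdeg)
    if (nrow(prof) >= 3) {
      cl <- stage("cluster",
                  select_k_by_asw(prof, config$k_range,
                                  n_restarts = config$n_restarts,
                                  seed = config$seed))
      labels <- label_clusters(cl, opdeg)
      clusters[[op]] <- data.frame(
        gene = names(cl$assignments), drug = op, cluster = cl$assignments,
        label = labels[as.character(cl$assignments)],
        stringsAsFactors = FALSE)
      asw_tabs[[op]] <- data.frame(drug = op,
                                   K = as.integer(names(cl$asw_by_k)),
                                   asw = unname(cl$asw_by_k))
      message("[cluster] ", op, ": K = ", cl$K, " (ASW = ",
              signif(cl$asw, 3), ")")
      for (k in sort(unique(cl$assignments))) {
        q <- names(cl$assignments)[cl$assignments == k]
        e <- suppressMessages(enrich(q, sets, ds$gene_ids, "functional"))
        if (nrow(e)) {
          e <- data.frame(drug = op, cluster = k,
                          label = labels[[as.character(k)]], e)
          enr_fun[[length(enr_fun) + 1]] <- e
        }
      }
    }
  }
  cl_tab <- do.call(rbind, clusters)
  rownames(cl_tab) <- NULL
  write_table_provenance(cl_tab, out("clusters.tsv"), meta)
  write_table_provenance(do.call(rbind, asw_tabs), out("asw_by_k.tsv"), meta)
  write_table_provenance(do.call(rbind, enr_fun),
                         out("enrichment_functional.tsv"), meta)

  assoc <- stage("associate", do.call(rbind, lapply(config$opioids,
    function(op) associate(degs[degs$drug == op, ], fits, harm,
                           alpha = config$alpha))))
  message("[associate] ", sum(assoc$significant), " significant (gene, effect) pairs")
  write_table_provenance(assoc, out("associations.tsv"), meta)

  reg_sets <- stage("enrich-regulator",
                    regulator_sets_from_peaks(peaks, annotation,
                                              config$window_bp))
  reg_enr <- reg_scores <- reversal <- list()
  for (op in config$opioids) {
    op_assoc <- assoc[assoc$drug == op, ]
    dep_genes <- dependence_associated_genes(op_assoc)
    if (length(dep_genes) == 0) next
    e <- suppressMessages(enrich(dep_genes, reg_sets, annotation$gene,
                                 "regulator"))
    reg_enr[[op]] <- data.frame(drug = op, e)
    keep <- e$set[e$significant]
    message("[enrich-regulator] ", op, ": ", length(keep),
            " enriched regulator(s)")
    if (length(keep)) {
      sc <- stage("score-regulators",
                  score_regulators(reg_sets[keep], degs[degs$drug == op, ],
                                   op_assoc, fits[[op]]))
      if (nrow(sc)) reg_scores[[op]] <- data.frame(drug = op, sc)
    }
    q <- query_signature(degs[degs$drug == op, ], fits[[op]],
                         genes = dep_genes)
    rk <- stage("reverse",
                suppressMessages(rank_compounds(q, library_,
                                                n_perm = config$n_perm,
                                                seed = config$seed)))
    reversal[[op]] <- data.frame(drug = op, rk)
    message("[reverse] ", op, ": top compound ", rk$compound[1],
            " (score = ", signif(rk$score[1], 3), ")")
  }
  write_table_provenance(do.call(rbind, reg_enr),
                         out("enrichment_regulators.tsv"), meta)
  if (length(reg_scores)) {
    write_table_provenance(do.call(rbind, reg_scores),
                           out("regulator_scores.tsv"), meta)
  }
  write_table_provenance(do.call(rbind, reversal), out("reversal.tsv"), meta)

  invisible(list(dataset = ds, fits = fits, degs = degs,
                 clusters = cl_tab, functional_enrichment = enr_fun,
                 associations = assoc, regulator_enrichment = reg_enr,
                 regulator_scores = reg_scores, reversal = reversal))
}
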