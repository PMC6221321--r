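# Container for a gene x sample log2 expression matrix with (drug, time,
# replicate) sample metadata, following the single-dose multi-drug striatum
# design: each drug measured at 1, 2, 4, 8 h with replicates, and a shared
# naive control group providing the 0 h reference for every drug.

#' Construct an expression dataset
#'
#' @param values numeric matrix of log2 intensities, genes in rows, samples
#'   in columns; rownames are gene symbols.
#' @param samples data.frame with columns `sample`, `drug`, `time_hours`,
#'   `replicate`; one row per column of `values`, in column order.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, samples) {
  values <- as.matrix(values)
  req <- c("sample", "drug", "time_hours", "replicate")
  if (!all(req %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (ncol(values) != nrow(samples)) {
    stop("values has ", ncol(values), " columns but sample sheet has ",
         nrow(samples), " rows")
  }
  if (is.null(rownames(values))) stop("values must carry gene ids as rownames")
  if (!any(samples$time_hours == 0)) {
    stop("no time-0 samples: a control reference at 0 h is required")
  }
  rownames(values) <- normalize_symbols(rownames(values))
  samples$drug <- as.character(samples$drug)
  structure(list(values = values, samples = samples,
                 gene_ids = rownames(values)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  drugs:", paste(setdiff(unique(x$samples$drug), "control"),
                        collapse = ", "), "\n")
  cat("  times (h):", paste(sort(unique(x$samples$time_hours)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Drugs present in a dataset
#' @param dataset an `expression_dataset`.
#' @param include_control also list the shared control group.
#' @return character vector of drug names.
#' @export
dataset_drugs <- function(dataset, include_control = FALSE) {
  d <- unique(dataset$samples$drug)
  if (!include_control) d <- setdiff(d, c("control", "naive", "saline"))
  d
}

# Columns for one drug's time course: the drug's own samples plus the shared
# time-0 controls (drug-labelled 0 h samples also qualify).
.drug_columns <- function(dataset, drug) {
  s <- dataset$samples
  ctrl <- which(s$time_hours == 0 &
                  s$drug %in% c(drug, "control", "naive", "saline"))
  trt <- which(s$drug == drug & s$time_hours > 0)
  if (length(trt) == 0) stop("drug not present in dataset: ", drug)
  if (length(ctrl) == 0) stop("no time-0 control samples for drug: ", drug)
  idx <- c(ctrl, trt)
  idx[order(s$time_hours[idx], s$replicate[idx])]
}

#' Extract one drug's time-course matrix
#'
#' @param dataset an `expression_dataset`.
#' @param drug drug name.
#' @return list with `values` (genes x observations) and `times` (hours).
#' @export
drug_matrix <- function(dataset, drug) {
  idx <- .drug_columns(dataset, drug)
  list(values = dataset$values[, idx, drop = FALSE],
       times = dataset$samples$time_hours[idx])
}

#' Read an expression matrix and sample sheet from disk
#'
#' The expression TSV has genes in rows (first column `gene`) and one column
#' per sample named `drug|t<hours>|r<replicate>`; the optional sample sheet
#' CSV (columns `sample`, `drug`, `time_hours`, `replicate`) overrides the
#' header encoding.
#'
#' @param expression_tsv path to the expression TSV.
#' @param sample_csv optional path to the sample sheet CSV.
#' @return an `expression_dataset`.
#' @export
read_expression <- function(expression_tsv, sample_csv = NULL) {
  tab <- read_table_skip_comments(expression_tsv)
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- genes
  if (!is.null(sample_csv)) {
    samples <- read_table_skip_comments(sample_csv, sep = ",")
    samples <- samples[match(colnames(values), samples$sample), ]
  } else {
    parts <- strsplit(colnames(values), "|", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad)) {
      stop("sample column name not in drug|t<h>|r<i> form: ",
           colnames(values)[bad[1]])
    }
    samples <- data.frame(
      sample = colnames(values),
      drug = vapply(parts, `[`, "", 1),
      time_hours = as.numeric(sub("^t", "", vapply(parts, `[`, "", 2))),
      replicate = as.integer(sub("^r", "", vapply(parts, `[`, "", 3))),
      stringsAsFactors = FALSE
    )
  }
  expression_dataset(values, samples)
}

#' Write an expression dataset to disk
#'
#' @param dataset an `expression_dataset`.
#' @param expression_tsv output TSV path.
#' @param sample_csv optional output path for the sample sheet CSV.
#' @return invisibly, the expression TSV path.
#' @export
write_expression <- function(dataset, expression_tsv, sample_csv = NULL) {
  df <- data.frame(gene = rownames(dataset$values),
                   dataset$values, check.names = FALSE)
  utils::write.table(df, expression_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sample_csv)) {
    utils::write.table(dataset$samples, sample_csv, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(expression_tsv)
}
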