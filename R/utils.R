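#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tricube kernel weights
#'
#' Standard tricube weight \eqn{(1-|u|^3)^3} for \eqn{|u| < 1}, zero outside.
#'
#' @param u numeric vector of scaled distances.
#' @return numeric vector of weights in \[0, 1\].
#' @keywords internal
tricube <- function(u) {
  a <- abs(u)
  w <- (1 - pmin(a, 1)^3)^3
  w[a >= 1] <- 0
  w
}

#' Normalize gene symbols
#'
#' Uppercases and trims gene identifiers. Symbol matching across the
#' expression matrix, gene sets, annotation, and compound signatures is done
#' on uppercased symbols throughout the package (the cross-namespace
#' convention when mouse genes are matched to human regulator targets and
#' compound profiles).
#'
#' @param x character vector of gene identifiers.
#' @return uppercased, trimmed character vector.
#' @export
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

#' Adjusted Rand index between two partitions
#'
#' Permutation-model-corrected agreement between two labelings of the same
#' items; 1 means identical partitions, 0 is the chance level.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Write a data.frame as TSV with '# key: value' provenance header lines.
write_table_provenance <- function(df, path, meta = list()) {
  con <- file(path, open = "wb")  # binary mode: byte-identical across runs
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_skip_comments <- function(path, sep = "\t", header = TRUE) {
  utils::read.table(path, sep = sep, header = header, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# md5 of an R object via its canonical JSON serialization (for provenance).
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
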