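# Hypergeometric over-representation of (a) functional gene sets among
# per-cluster DEGs and (b) regulator target sets among dependence-associated
# DEGs, with targets assigned from binding peaks and a 1000-bp window around
# the gene (upstream of the TSS and downstream of the TTS).

#' Hypergeometric upper-tail probability
#'
#' Exact \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(`N`, `K`, `n`):
#' drawing `n` genes from a universe of `N` containing `K` set members and
#' seeing at least `k` members.
#'
#' @param k observed overlap.
#' @param K set size in the universe.
#' @param n query size.
#' @param N universe size.
#' @return probability in (0, 1\].
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10)  # 66/252
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > min(K, n) || K > N || n > N) {
    stop("require 0 <= k <= min(K, n) and K, n <= N; got k=", k, " K=", K,
         " n=", n, " N=", N)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes. Symbols are
#' uppercased.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, normalize_symbols)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation test of a query gene list against gene sets
#'
#' One hypergeometric upper-tail test per set, on the given universe. Query
#' genes outside the universe are dropped (with a message); each set is
#' restricted to the universe before counting. In `"regulator"` mode a
#' Benjamini-Hochberg FDR column is added and significance is called on it;
#' in `"functional"` mode significance is called on the raw p-value,
#' following the two stages' respective conventions.
#'
#' @param query character vector of gene symbols.
#' @param sets named list of character vectors (e.g. from [read_gmt()] or
#'   [regulator_sets_from_peaks()]).
#' @param universe character vector of all eligible gene symbols.
#' @param mode `"functional"` or `"regulator"`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame sorted by p with columns `set`, `k`, `K`, `n`, `N`,
#'   `p`, `significant`, and `fdr_p` in regulator mode.
#' @export
enrich <- function(query, sets, universe, mode = c("functional", "regulator"),
                   alpha = 0.05) {
  mode <- match.arg(mode)
  universe <- unique(normalize_symbols(universe))
  query <- unique(normalize_symbols(query))
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(length(dropped), " query gene(s) outside the universe dropped")
  }
  query <- intersect(query, universe)
  if (length(query) == 0) {
    warning("empty query after restriction to the universe")
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      significant = logical()))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(normalize_symbols(sets[[nm]])), universe)
    k <- length(intersect(members, query))
    data.frame(set = nm, k = k, K = length(members), n = n, N = N,
               p = hypergeom_upper_tail(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (mode == "regulator") {
    out$fdr_p <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$fdr_p < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}

# Coerce peak/gene tables in BED convention (0-based half-open) to GRanges.
.bed_df_to_granges <- function(df, extra = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  if (!is.null(extra)) {
    for (col in extra) S4Vectors::mcols(gr)[[col]] <- df[[col]]
  }
  gr
}

#' Assign target genes to a regulator from binding peaks
#'
#' A gene is a target if any peak overlaps the window extending from 1000 bp
#' upstream of the transcription start site to 1000 bp downstream of the
#' transcription termination site (gene body included; the window is clipped
#' at the chromosome origin). Coordinates in data.frame inputs follow the
#' BED convention (0-based half-open); `GRanges` inputs are used as-is.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (BED convention) or
#'   a `GRanges`.
#' @param annotation data.frame with `gene`, `chrom`, `start`, `end`,
#'   `strand` (BED convention: for `+` genes the TSS is at `start`, for `-`
#'   genes at `end`).
#' @param window_bp flank size in bp (default 1000).
#' @param regulator optional regulator name stored on the result.
#' @return list of class `regulator_set`: `regulator`, `targets` (symbols),
#'   `peak_counts` (named, peaks overlapping each target's window).
#' @export
assign_targets <- function(peaks, annotation, window_bp = 1000,
                           regulator = NA_character_) {
  if (!inherits(peaks, "GRanges")) {
    peaks <- .bed_df_to_granges(peaks)
  }
  known <- as.character(unique(annotation$chrom))
  pk_chrom <- as.character(GenomicRanges::seqnames(peaks))
  bad <- !(pk_chrom %in% known)
  if (any(bad)) {
    message(sum(bad), " peak(s) on unknown chromosome(s) skipped")
    peaks <- peaks[!bad]
  }
  genes <- GenomicRanges::GRanges(
    seqnames = as.character(annotation$chrom),
    ranges = IRanges::IRanges(
      start = pmax(annotation$start + 1 - window_bp, 1),
      end = annotation$end + window_bp))
  # disjoint seqlevel sets (e.g. every peak filtered out) warn harmlessly
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(genes, peaks, ignore.strand = TRUE))
  targets <- normalize_symbols(annotation$gene[hits > 0])
  structure(list(regulator = regulator, targets = targets,
                 peak_counts = stats::setNames(hits[hits > 0], targets)),
            class = "regulator_set")
}

#' Build regulator target sets from a multi-regulator peak table
#'
#' Splits peaks by their `name` field (one regulator per name) and runs
#' [assign_targets()] for each.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `name` (BED
#'   convention) or a `GRanges` with a `name` metadata column.
#' @inheritParams assign_targets
#' @return named list of target-gene character vectors, one per regulator;
#'   full `regulator_set` objects attached as attribute `"sets"`.
#' @export
regulator_sets_from_peaks <- function(peaks, annotation, window_bp = 1000) {
  if (inherits(peaks, "GRanges")) {
    nm <- S4Vectors::mcols(peaks)$name
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                     start = GenomicRanges::start(peaks) - 1,
                     end = GenomicRanges::end(peaks),
                     name = nm, stringsAsFactors = FALSE)
  } else {
    df <- peaks
  }
  if (is.null(df$name)) stop("peaks need a `name` column naming the regulator")
  by_reg <- split(df, df$name)
  sets <- lapply(names(by_reg), function(r) {
    assign_targets(by_reg[[r]], annotation, window_bp, regulator = r)
  })
  names(sets) <- names(by_reg)
  out <- lapply(sets, `[[`, "targets")
  attr(out, "sets") <- sets
  out
}

#' Read a BED peak file
#'
#' @param path BED file (0-based half-open on disk).
#' @return data.frame `chrom`, `start`, `end`, `name` in BED convention.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Read gene annotation from GFF3 or BED12
#'
#' GFF3 `gene` records (or all records if none are typed `gene`) or BED
#' entries are converted to the package's BED-convention annotation table.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED file.
#' @return data.frame `gene`, `chrom`, `start`, `end`, `strand` (BED
#'   convention, 0-based half-open).
#' @export
read_annotation <- function(path) {
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "GFF3" else "BED"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "GFF3" && "type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  }
  nm <- S4Vectors::mcols(gr)
  gene <- if (!is.null(nm$Name)) nm$Name else if (!is.null(nm$ID)) nm$ID
          else if (!is.null(nm$name)) nm$name else stop("no gene names in ", path)
  data.frame(gene = normalize_symbols(as.character(gene)),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
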