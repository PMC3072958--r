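# Readers and writers for the flat-file formats the package exchanges:
# TSV matrices (probe rows x sample columns), MatrixMarket with id sidecars,
# TSV annotations, TSV Cq tables (long replicate or wide averaged), and the
# candidate report. UTF-8, '.' decimal point, no thousands separators.

#' Read a probe-by-sample expression matrix
#'
#' Reads either a tab-separated file (header row of sample ids, first column
#' of probe ids) or a MatrixMarket `.mtx` file with two id sidecar files
#' (one id per line). Every cell must be present and numeric; duplicate ids
#' are rejected. The caller states the scale of the stored signal.
#'
#' @param path Path to the `.tsv`/`.txt` or `.mtx` file.
#' @param scale Scale of the stored values, `"linear"` or `"log2"`.
#' @param probe_id_path,sample_id_path Sidecar id files for MatrixMarket
#'   input; default `<path>.rows` and `<path>.cols`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2"),
                                   probe_id_path = paste0(path, ".rows"),
                                   sample_id_path = paste0(path, ".cols")) {
  scale <- match.arg(scale)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(probe_id_path)
    cn <- readLines(sample_id_path)
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("sidecar id files do not match the MatrixMarket dimensions",
           call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
    return(expression_matrix(m, scale))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("expected probe id column plus >= 1 sample column",
                          call. = FALSE)
  ids <- raw[[1]]
  check_axis_ids(ids, "probe")
  samples <- colnames(raw)[-1]
  check_axis_ids(samples, "sample")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  empty <- which(is.na(vals) | !nzchar(trimws(vals)), arr.ind = TRUE)
  if (nrow(empty) > 0) {
    stop(sprintf("empty cell at probe '%s', sample '%s'",
                 ids[empty[1, 1]], samples[empty[1, 2]]), call. = FALSE)
  }
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value '%s' at probe '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 samples[bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, samples)
  expression_matrix(num, scale)
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that a write-then-read
#' round trip reproduces the doubles bit-exactly.
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  v <- matrix$values
  txt <- array(sprintf("%.17g", v), dim = dim(v))
  lines <- c(paste(c("probe_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), apply(txt, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated, header row of axis names, first column `sample_id`, one row
#' per sample. Unknown extra columns are preserved as free annotation axes.
#'
#' @param path Path to the TSV file.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  annotation_table(df)
}

#' Write a sample annotation table as TSV
#'
#' @param annotations An [annotation_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_table"))
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an RT-qPCR Cq table
#'
#' Two layouts are accepted:
#' \describe{
#'   \item{long}{columns `gene_id`, `sample_id`, `cq` (case-insensitive), one
#'     row per technical replicate. Replicates are averaged by arithmetic
#'     mean per (gene, sample); failed wells (empty or `NA` Cq) are dropped
#'     before averaging, and a (gene, sample) pair with no surviving
#'     replicate is an error.}
#'   \item{wide}{first column of gene ids, header of sample ids,
#'     already-averaged values, which pass through unchanged.}
#' }
#'
#' @param path Path to the TSV file.
#' @return A [cq_table()]; `replicate_counts` records how many replicates
#'   went into each cell (1 for wide input).
#' @export
read_cq_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  lc <- tolower(names(df))
  if (all(c("gene_id", "sample_id", "cq") %in% lc)) {
    gene <- df[[which(lc == "gene_id")[1]]]
    sample <- df[[which(lc == "sample_id")[1]]]
    cqv <- suppressWarnings(as.numeric(df[[which(lc == "cq")[1]]]))
    keep <- is.finite(cqv)
    genes <- unique(gene)
    samples <- unique(sample)
    if (length(genes) < 2 || length(samples) < 2) {
      stop("a Cq table needs at least 2 genes and 2 samples", call. = FALSE)
    }
    cq <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
    counts <- matrix(0L, length(genes), length(samples),
                     dimnames = list(genes, samples))
    gi <- match(gene, genes)[keep]
    si <- match(sample, samples)[keep]
    sums <- matrix(0, length(genes), length(samples))
    for (r in seq_along(gi)) {
      sums[gi[r], si[r]] <- sums[gi[r], si[r]] + cqv[keep][r]
      counts[gi[r], si[r]] <- counts[gi[r], si[r]] + 1L
    }
    if (any(counts == 0L)) {
      bad <- which(counts == 0L, arr.ind = TRUE)
      stop(sprintf(
        "no surviving Cq replicate for gene '%s', sample '%s'",
        genes[bad[1, 1]], samples[bad[1, 2]]), call. = FALSE)
    }
    cq[] <- sums / counts
    return(cq_table(cq, counts))
  }
  # wide, already averaged
  genes <- df[[1]]
  check_axis_ids(genes, "gene")
  vals <- suppressWarnings(
    array(as.numeric(as.matrix(df[, -1, drop = FALSE])),
          dim = c(nrow(df), ncol(df) - 1)))
  dimnames(vals) <- list(genes, names(df)[-1])
  counts <- array(1L, dim = dim(vals), dimnames = dimnames(vals))
  cq_table(vals, counts)
}

#' Write a candidate reference-gene report
#'
#' Tab-separated report with columns `probe_id`, `median`, `mean`, `sd`,
#' `rank`, `present_fraction`, sorted ascending by SD (the order of the
#' candidate list itself).
#'
#' @param candidates A `candidate_list` from [find_reference_genes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidate_report <- function(candidates, path) {
  stopifnot(inherits(candidates, "candidate_list"))
  if (nrow(candidates) == 0) stop("empty candidate list", call. = FALSE)
  out <- data.frame(
    probe_id = candidates$probe_id,
    median = sprintf("%.17g", candidates$median),
    mean = sprintf("%.17g", candidates$mean),
    sd = sprintf("%.17g", candidates$sd),
    rank = candidates$rank,
    present_fraction = ifelse(is.na(candidates$present_fraction), "NA",
                              sprintf("%.17g", candidates$present_fraction)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
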