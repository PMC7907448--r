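# Ingest: count matrices, sample designs, biotype maps, CPM normalization,
# coding/non-coding split, low-expression filtering.

#' Construct a validated counts matrix
#'
#' @param counts numeric matrix of non-negative counts, genes in rows and
#'   samples in columns.
#' @param gene_ids,sample_ids character vectors of unique identifiers; default
#'   to the dimnames of `counts`.
#' @return A `counts_matrix`: an integer-valued matrix with row and column
#'   names, carrying class `"counts_matrix"`.
#' @export
counts_matrix <- function(counts, gene_ids = rownames(counts),
                          sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop_ft("counts matrix requires gene and sample identifiers")
  if (anyDuplicated(gene_ids))
    stop_ft("duplicate gene identifier(s): ",
            paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_ft("duplicate sample identifier(s): ",
            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.numeric(counts)) stop_ft("non-numeric count entries")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop_ft("negative count at row ", neg[1, 1], " (", gene_ids[neg[1, 1]],
            "), column ", neg[1, 2], " (", sample_ids[neg[1, 2]], ")")
  if (any(!is.finite(counts)))
    stop_ft("non-finite count entries")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(counts, class = c("counts_matrix", "matrix", "array"))
}

#' Read a gene-level count matrix
#'
#' Two on-disk layouts are supported: a TSV with a header row of sample ids and
#' gene ids in the first column, or a MatrixMarket triplet file with sidecar
#' row/column label files (one id per line). Omitted MatrixMarket cells are
#' zeros.
#'
#' @param path file path (the `.mtx` file for MatrixMarket input).
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_path,samples_path label sidecars for `format = "mtx"`; default
#'   to `<path without .mtx>.genes.tsv` / `.samples.tsv`.
#' @return A [counts_matrix()].
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        genes_path = NULL, samples_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ft("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                     !is.na(m), arr.ind = TRUE)
      if (nrow(bad) > 0)
        stop_ft("non-numeric count at row ", bad[1, 1], ", column ", bad[1, 2])
      stop_ft("non-numeric count entries in ", path)
    }
    counts_matrix(m, gene_ids = gene_ids, sample_ids = colnames(df)[-1])
  } else {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(genes_path)) genes_path <- paste0(stem, ".genes.tsv")
    if (is.null(samples_path)) samples_path <- paste0(stem, ".samples.tsv")
    for (p in c(genes_path, samples_path))
      if (!file.exists(p)) stop_ft("label file not found: ", p)
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_path)
    sample_ids <- readLines(samples_path)
    if (length(gene_ids) != nrow(m))
      stop_ft("gene label count (", length(gene_ids),
              ") does not match matrix rows (", nrow(m), ")")
    if (length(sample_ids) != ncol(m))
      stop_ft("sample label count (", length(sample_ids),
              ") does not match matrix columns (", ncol(m), ")")
    counts_matrix(m, gene_ids = gene_ids, sample_ids = sample_ids)
  }
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()] for the TSV layout; integer counts round-trip
#' exactly.
#'
#' @param m a [counts_matrix()] (or plain matrix with dimnames).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE],
                                                        check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Expects a TSV with header columns `sample_id`, `condition`, `time_h`,
#' `replicate`, `dataset`.
#'
#' @param path file path.
#' @return A `sample_design` data.frame with those five columns, `time_h`
#'   numeric.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_ft("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_design(df)
}

#' Construct/validate a sample design
#'
#' @param df data.frame with columns `sample_id`, `condition`, `time_h`,
#'   `replicate`, `dataset`.
#' @return The validated design with class `"sample_design"`.
#' @export
sample_design <- function(df) {
  required <- c("sample_id", "condition", "time_h", "replicate", "dataset")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_ft("design is missing required column(s): ",
            paste(missing, collapse = ", "))
  df <- df[required]
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.character(df$replicate)
  df$dataset <- as.character(df$dataset)
  time_h <- suppressWarnings(as.numeric(df$time_h))
  if (anyNA(time_h) & !anyNA(df$time_h))
    stop_ft("non-numeric time_h value(s): ",
            paste(utils::head(df$time_h[is.na(time_h)], 3), collapse = ", "))
  if (anyNA(time_h)) stop_ft("missing time_h value(s)")
  if (any(time_h < 0)) stop_ft("negative time_h value(s)")
  df$time_h <- time_h
  if (anyDuplicated(df$sample_id))
    stop_ft("duplicate sample_id(s) in design: ",
            paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Read a gene-to-biotype map
#'
#' Accepts a two-column TSV (`gene_id`, `biotype`; a header row is detected and
#' skipped) or a GENCODE-style GTF, from which `gene_id` and
#' `gene_type`/`gene_biotype` attributes of `gene` features are taken. Only the
#' attributes are used; coordinates are ignored.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gtf"`.
#' @return A named character vector mapping gene_id to biotype, with class
#'   `"biotype_map"`.
#' @export
read_biotypes <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ft("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop_ft("biotype TSV must have two columns")
    if (identical(tolower(as.character(df[1, 1])), "gene_id"))
      df <- df[-1, , drop = FALSE]
    biotype_map(gene_ids = as.character(df[[1]]),
                biotypes = as.character(df[[2]]))
  } else {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(path)
      md <- as.data.frame(gr)
      md <- md[is.na(md$type) | md$type == "gene", , drop = FALSE]
      bt_col <- intersect(c("gene_type", "gene_biotype"), names(md))
      if (length(bt_col) == 0)
        stop_ft("GTF has no gene_type/gene_biotype attribute")
      keep <- !is.na(md$gene_id) & !is.na(md[[bt_col[1]]])
      biotype_map(gene_ids = md$gene_id[keep], biotypes = md[[bt_col[1]]][keep])
    } else {
      parse_gtf_biotypes(path)
    }
  }
}

# Plain-text GTF attribute scan (gene features only); used when rtracklayer is
# unavailable.
parse_gtf_biotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene", logical(1))
  attrs <- vapply(fields[keep], `[[`, character(1), 9)
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]+)"'), a))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  gid <- vapply(attrs, get_attr, character(1), key = "gene_id")
  bt <- vapply(attrs, get_attr, character(1), key = "gene_type")
  miss <- is.na(bt)
  if (any(miss))
    bt[miss] <- vapply(attrs[miss], get_attr, character(1), key = "gene_biotype")
  ok <- !is.na(gid) & !is.na(bt)
  biotype_map(gene_ids = gid[ok], biotypes = bt[ok])
}

#' Construct/validate a biotype map
#'
#' @param gene_ids character vector of gene identifiers.
#' @param biotypes character vector of biotype labels, same length.
#' @return Named character vector (`gene_id -> biotype`), class
#'   `"biotype_map"`. A gene listed twice with conflicting biotypes is an
#'   error; consistent duplicates are collapsed.
#' @export
biotype_map <- function(gene_ids, biotypes) {
  stopifnot(length(gene_ids) == length(biotypes))
  dup <- duplicated(gene_ids)
  if (any(dup)) {
    for (g in unique(gene_ids[dup])) {
      bts <- unique(biotypes[gene_ids == g])
      if (length(bts) > 1)
        stop_ft("gene ", g, " mapped to conflicting biotypes: ",
                paste(bts, collapse = ", "))
    }
    biotypes <- biotypes[!dup]
    gene_ids <- gene_ids[!dup]
  }
  structure(stats::setNames(biotypes, gene_ids), class = "biotype_map")
}

#' Normalize counts to log2 counts-per-million
#'
#' Each cell becomes `log2(1e6 * count / library_size + pseudocount)` where the
#' library size is the column sum. The pseudocount and library sizes are kept
#' in the result so the transform is invertible and so downstream CPM
#' thresholds convert exactly to value thresholds.
#'
#' @param m a [counts_matrix()].
#' @param pseudocount positive real added to CPM before log2 (default 1).
#' @return A `log_expr` object: the genes x samples value matrix plus
#'   `pseudocount`, `lib_sizes` and a `provenance` string as attributes.
#' @export
cpm_log2 <- function(m, pseudocount = 1) {
  if (!is_scalar_number(pseudocount) || pseudocount <= 0)
    stop_ft("pseudocount must be a positive number")
  lib <- colSums(m)
  if (any(lib == 0))
    stop_ft("zero library size for sample(s): ",
            paste(colnames(m)[lib == 0], collapse = ", "))
  values <- log2(sweep(unclass(m), 2, lib, "/") * 1e6 + pseudocount)
  log_expr(values, pseudocount = pseudocount, lib_sizes = lib,
           provenance = sprintf("log2(CPM + %g)", pseudocount))
}

#' Construct a log-expression matrix
#'
#' @param values numeric genes x samples matrix of log2(CPM + pseudocount).
#' @param pseudocount the pseudocount used.
#' @param lib_sizes optional named library sizes.
#' @param provenance free-text normalization description.
#' @return A `log_expr` matrix.
#' @export
log_expr <- function(values, pseudocount, lib_sizes = NULL,
                     provenance = sprintf("log2(CPM + %g)", pseudocount)) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop_ft("log-expression values must be finite")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop_ft("log-expression matrix requires gene and sample names")
  structure(values, class = c("log_expr", "matrix", "array"),
            pseudocount = pseudocount, lib_sizes = lib_sizes,
            provenance = provenance)
}

# Rebuild a log_expr after subsetting rows, preserving provenance.
subset_log_expr <- function(m, rows) {
  log_expr(unclass(m)[rows, , drop = FALSE],
           pseudocount = attr(m, "pseudocount"),
           lib_sizes = attr(m, "lib_sizes"),
           provenance = attr(m, "provenance"))
}

#' Split an expression matrix into coding and non-coding submatrices
#'
#' @param m a `log_expr` matrix.
#' @param biotypes a [biotype_map()].
#' @param pcg_labels biotype labels treated as protein-coding.
#' @param ncg_labels biotype labels treated as non-coding; `NULL` (default)
#'   means every annotated biotype other than `pcg_labels`. Use
#'   `ncg_labels = "lincRNA"` for a lincRNA-only non-coding set.
#' @param unannotated `"error"` (default) or `"drop"` for genes absent from the
#'   map.
#' @return `list(pcg = , ncg = )` of `log_expr` matrices with disjoint gene
#'   sets. Annotated genes matching neither label set are dropped with a
#'   warning.
#' @export
split_by_biotype <- function(m, biotypes, pcg_labels = "protein_coding",
                             ncg_labels = NULL,
                             unannotated = c("error", "drop")) {
  unannotated <- match.arg(unannotated)
  genes <- rownames(m)
  known <- genes %in% names(biotypes)
  if (!all(known)) {
    if (unannotated == "error")
      stop_ft("gene(s) missing from biotype map: ",
              paste(utils::head(genes[!known], 5), collapse = ", "),
              if (sum(!known) > 5) sprintf(" (and %d more)", sum(!known) - 5))
    m <- subset_log_expr(m, known)
    genes <- rownames(m)
  }
  bt <- unname(unclass(biotypes)[genes])
  if (is.null(ncg_labels)) ncg_labels <- setdiff(unique(bt), pcg_labels)
  is_pcg <- bt %in% pcg_labels
  is_ncg <- bt %in% ncg_labels & !is_pcg
  dropped <- sum(!is_pcg & !is_ncg)
  if (dropped > 0)
    warning(dropped, " annotated gene(s) match neither label set and were dropped",
            call. = FALSE)
  list(pcg = subset_log_expr(m, is_pcg), ncg = subset_log_expr(m, is_ncg))
}

#' Filter genes by minimum expression
#'
#' Retains genes with CPM at or above `min_cpm` in at least `min_fraction` of
#' samples. The CPM cutoff is converted to a value cutoff through the stored
#' pseudocount, so the rule is exact on the log scale.
#'
#' @param m a `log_expr` matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction minimum fraction of samples at or above threshold
#'   (default 0.5).
#' @return The filtered `log_expr`, gene order preserved.
#' @export
filter_low_expression <- function(m, min_cpm = 1, min_fraction = 0.5) {
  stopifnot(min_fraction >= 0, min_fraction <= 1, min_cpm >= 0)
  cutoff <- log2(min_cpm + attr(m, "pseudocount"))
  frac <- rowMeans(unclass(m) >= cutoff)
  keep <- frac >= min_fraction
  if (!any(keep))
    warning("expression filter removed every gene", call. = FALSE)
  subset_log_expr(m, keep)
}
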