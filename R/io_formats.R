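#' Read an expression matrix from a tab-separated file
#'
#' Expression matrices are plain numeric matrices (log2 scale) with feature
#' identifiers as row names and sample identifiers as column names, the
#' convention used throughout limma/DESeq2-style workflows.  The file must
#' have a header row of sample ids and feature ids in the first column.
#'
#' @param path Path to a TSV file.
#' @param rows_are_features If `FALSE` the parsed table is transposed so that
#'   features end up on rows.
#' @return A numeric matrix, features x samples.
#' @export
read_expression_table <- function(path, rows_are_features = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("expression table '", path, "': need a header row and at least one data row")
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids)) {
    stop("expression table '", path, "': duplicate sample id '",
         col_ids[duplicated(col_ids)][1L], "' in header")
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(row_ids)) {
    stop("expression table '", path, "': duplicate feature id '",
         row_ids[duplicated(row_ids)][1L], "'")
  }
  n <- length(col_ids)
  values <- matrix(NA_real_, nrow = length(body), ncol = n,
                   dimnames = list(row_ids, col_ids))
  for (i in seq_along(body)) {
    fields <- body[[i]][-1L]
    if (length(fields) != n) {
      stop("expression table '", path, "': row '", row_ids[i], "' has ",
           length(fields), " values, expected ", n)
    }
    v <- suppressWarnings(as.numeric(fields))
    bad <- which(is.na(v) & !(fields %in% c("NA", "NaN")))
    if (length(bad)) {
      stop("expression table '", path, "': non-numeric value '",
           fields[bad[1L]], "' at row '", row_ids[i], "', column '",
           col_ids[bad[1L]], "'")
    }
    values[i, ] <- v
  }
  if (!rows_are_features) values <- t(values)
  values
}

#' Read a sample design table
#'
#' The design table maps samples to experimental factors.  Required columns:
#' `sample_id`, `replicate`, `is_control`; every other column is treated as a
#' design factor (finite label set).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with factor columns as character, `replicate` integer
#'   and `is_control` logical; attribute `"factors"` names the factor columns.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "replicate", "is_control")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("design table '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("design table '", path, "': duplicate sample_id")
  }
  df$is_control <- as.logical(df$is_control)
  df$replicate <- as.integer(df$replicate)
  attr(df, "factors") <- setdiff(names(df), required)
  df
}

check_design_matches <- function(mat, design) {
  if (!setequal(colnames(mat), design$sample_id) ||
      anyDuplicated(design$sample_id)) {
    stop("design does not cover the matrix sample columns exactly; offenders: ",
         paste(union(setdiff(colnames(mat), design$sample_id),
                     setdiff(design$sample_id, colnames(mat))), collapse = ", "))
  }
  invisible(TRUE)
}

#' Convert log2 expression values to log2-ratios against the control mean
#'
#' Each non-control column becomes `value - mean(control columns)` row-wise;
#' control columns are dropped from the output.  Input values must already be
#' on the log2 scale (RMA-style summaries), so the ratio is a subtraction.
#' Rows containing missing values are dropped with a message, since the
#' downstream decomposition requires a complete matrix.
#'
#' @param raw Numeric matrix, features x samples, log2 scale.
#' @param design Design data.frame as from [read_design()]; at least one
#'   sample must be flagged `is_control`.
#' @return Numeric matrix of log2-ratios with control columns removed.
#' @export
compute_log_ratios <- function(raw, design) {
  check_design_matches(raw, design)
  ctrl <- design$sample_id[design$is_control]
  if (length(ctrl) == 0L) {
    stop("compute_log_ratios: no sample is flagged is_control in the design")
  }
  keep <- !apply(raw, 1L, anyNA)
  if (any(!keep)) {
    message("compute_log_ratios: dropping ", sum(!keep),
            " row(s) with missing values")
    raw <- raw[keep, , drop = FALSE]
  }
  ctrl_mean <- rowMeans(raw[, ctrl, drop = FALSE])
  non_ctrl <- setdiff(colnames(raw), ctrl)
  raw[, non_ctrl, drop = FALSE] - ctrl_mean
}

#' Median-normalize each column of a (log-scale) matrix
#'
#' Shifts every column so that its median is zero, the normalization used for
#' single-colour miRNA arrays.
#'
#' @param raw Numeric matrix.
#' @return Matrix of the same shape with column medians 0.
#' @export
median_normalize <- function(raw) {
  if (nrow(raw) < 1L) stop("median_normalize: empty matrix")
  sweep(raw, 2L, apply(raw, 2L, stats::median, na.rm = TRUE))
}

#' Read sequences from a FASTA file
#'
#' Parses with Biostrings and post-processes: ids are the first
#' whitespace-delimited token of each header, sequences are uppercased and
#' transliterated (U/T) to the requested alphabet.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"rna"` or `"dna"`.
#' @return Named character vector id -> sequence.
#' @export
read_fasta <- function(path, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1L), 1L)
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    stop("read_fasta '", path, "': empty sequence for record '",
         ids[!nzchar(seqs)][1L], "'")
  }
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) {
    stop("read_fasta '", path, "': record '", ids[bad][1L],
         "' contains characters outside {A,C,G,T,U,N}")
  }
  if (alphabet == "rna") chartr("T", "U", seqs) else chartr("U", "T", seqs)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: `name TAB description TAB gene TAB gene ...`.
#' Duplicate genes within a set are deduplicated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (gene ids); attribute
#'   `"descriptions"` holds the per-set description strings.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT file '", path, "': line ", short[1L], " has fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("GMT file '", path, "': duplicate set name '", nm[duplicated(nm)][1L], "'")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1L), 2L), nm)
  sets
}

#' Write a result table as TSV with a JSON provenance sidecar
#'
#' Columns are written in their data.frame order, numeric values at full
#' precision (15 significant digits).  A sidecar `<path>.json` records run
#' metadata (seed, parameters, package version, timestamp-free so re-runs are
#' bit-identical).
#'
#' @param results A data.frame.
#' @param path Output TSV path.
#' @param metadata Named list of run metadata for the sidecar.
#' @export
write_results <- function(results, path, metadata = list()) {
  stopifnot(is.data.frame(results))
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- function(x) {
    # 17 significant digits: lossless double round trip
    if (is.numeric(x)) formatC(x, digits = 17, format = "g") else as.character(x)
  }
  writeLines(paste(names(results), collapse = "\t"), con)
  if (nrow(results)) {
    cols <- lapply(results, fmt)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  meta <- c(list(package = "icamir",
                 version = as.character(utils::packageVersion("icamir")),
                 n_rows = nrow(results)),
            metadata)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression matrix as TSV
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Header label for the feature-id column.
#' @export
write_expression_table <- function(mat, path, id_column = "feature_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- cbind(df[[1L]], formatC(as.matrix(mat), digits = 15, format = "g"))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
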