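# Alias table mapping external feature-table headers to canonical names.
# Matching is case-insensitive; extend here when ingesting a deposited
# table whose headers differ.
FEATURE_ALIASES <- c(
  "e_ref" = "e_ref", "eref" = "e_ref", "e(ref)" = "e_ref", "epsilon_r" = "e_ref",
  "q_theta5_seq" = "q_theta5_seq", "qtheta5(seq)" = "q_theta5_seq",
  "q_theta0_org" = "q_theta0_org", "qtheta0(org)" = "q_theta0_org",
  "q_theta0_tech" = "q_theta0_tech", "qtheta0(tech)" = "q_theta0_tech",
  "d_theta5_seq" = "d_theta5_seq", "dtheta5(seq)" = "d_theta5_seq",
  "d_theta0_host" = "d_theta0_host", "dtheta0(host)" = "d_theta0_host",
  "d_theta0_adju" = "d_theta0_adju", "dtheta0(adju)" = "d_theta0_adju",
  "d_theta0_proc" = "d_theta0_proc", "dtheta0(proc)" = "d_theta0_proc",
  "d_theta0_org" = "d_theta0_org", "dtheta0(org)" = "d_theta0_org",
  "d_theta0_tech" = "d_theta0_tech", "dtheta0(tech)" = "d_theta0_tech",
  "label" = "label", "class" = "label", "e_query" = "label", "epsilon_q" = "label"
)

.delim_for <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an assay-pair table
#'
#' Reads a CSV/TSV with columns `query_seq`, `ref_seq`, `ref_activity`,
#' `query_activity`, `org`, `host`, `proc`, `tech`, `adju` (order-insensitive
#' by name; header required) and validates every row. Malformed rows are
#' rejected with the row number named, never coerced.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) infers from the extension
#'   (`.tsv` means tab, anything else comma).
#' @return Validated assay-record data.frame, input row order preserved.
#' @export
read_pairs_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path, sep),
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  validate_records(df)
}

#' Write an assay-pair table
#'
#' @param records assay-record data.frame.
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_pairs_table <- function(records, path) {
  cols <- c("query_seq", "ref_seq", "ref_activity", "query_activity",
            CONDITION_FACTORS)
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a model feature table
#'
#' Ingests a feature table (10 features + label) written by this package
#' or deposited elsewhere: headers are matched case-insensitively through
#' an alias table and the columns are normalized to the canonical order of
#' [feature_names()]. Non-finite values are rejected with row and column
#' named.
#'
#' @inheritParams read_pairs_table
#' @return data.frame with columns [feature_names()] plus `label`.
#' @export
read_feature_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path, sep),
                          quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  canon <- unname(FEATURE_ALIASES[tolower(names(df))])
  if (anyNA(canon)) {
    stop("unrecognized feature column(s): ",
         paste(names(df)[is.na(canon)], collapse = ", "), call. = FALSE)
  }
  names(df) <- canon
  needed <- c(FEATURE_COLUMNS, "label")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (ncol(df) != 11L) {
    stop(sprintf("feature table must have exactly 11 columns (10 features + label), found %d",
                 ncol(df)), call. = FALSE)
  }
  df <- df[, needed]
  for (col in needed) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      stop(sprintf("column '%s' is not numeric", col), call. = FALSE)
    }
    bad <- which(!is.finite(x))
    if (length(bad) > 0L) {
      stop(sprintf("non-finite value in column '%s' at row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  bad_label <- which(!(df$label %in% c(0, 1)))
  if (length(bad_label) > 0L) {
    stop(sprintf("column 'label' must be 0 or 1; bad value at row %d", bad_label[1]),
         call. = FALSE)
  }
  df$label <- as.integer(df$label)
  df$e_ref <- as.numeric(df$e_ref)
  df
}

#' Write a model feature table
#'
#' Writes RFC-4180-style CSV with the canonical header and real-valued
#' features at 6 decimal places, so that re-runs are byte-identical.
#'
#' @param features feature data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- features[, c(FEATURE_COLUMNS, "label")]
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.6f", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Character vector of uppercase sequences, named by FASTA header.
#' @export
read_peptides_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- toupper(vapply(seqs, function(s) as.character(s)[1], character(1)))
  names(out) <- names(seqs)
  out
}

#' Write an entropy descriptor table as CSV
#'
#' Columns `sequence, theta0, ..., theta<k_max>`, floats at 6 decimals.
#'
#' @param theta matrix from [descriptor_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(theta, path) {
  fmt <- matrix(sprintf("%.6f", theta), nrow = nrow(theta),
                dimnames = dimnames(theta))
  df <- data.frame(sequence = rownames(theta), fmt, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
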