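# Condition factors carried by every assay record, in canonical order.
# The sixth factor, Seq, is implicit: the set of all sequences, whose
# "category mean" is the grand mean over all records.
CONDITION_FACTORS <- c("org", "host", "proc", "tech", "adju")

# Feature columns of the final model table, in canonical order.
FEATURE_COLUMNS <- c("e_ref",
                     "q_theta5_seq", "q_theta0_org", "q_theta0_tech",
                     "d_theta5_seq", "d_theta0_host", "d_theta0_adju",
                     "d_theta0_proc", "d_theta0_org", "d_theta0_tech")

#' Canonical feature column names
#'
#' The ten model inputs, in order: the observed reference activity class,
#' three query perturbations (theta5 under Seq, theta0 under Org and Tech),
#' and six query-minus-reference perturbation differences (theta5 under
#' Seq; theta0 under Host, Adju, Proc, Org, Tech).
#'
#' @return Character vector of the 10 feature names.
#' @export
feature_names <- function() FEATURE_COLUMNS

#' Validate a table of assay records
#'
#' An assay-pair table has one row per query/reference assay pair with
#' columns `query_seq`, `ref_seq`, `ref_activity`, `query_activity` (both
#' activities binary: 1 = positive-high, 0 = positive-intermediate) and the
#' five categorical condition columns `org`, `host`, `proc`, `tech`,
#' `adju`.
#'
#' @param records data.frame of assay records.
#' @return The validated data.frame (activities as integers), invisibly.
#' @export
validate_records <- function(records) {
  needed <- c("query_seq", "ref_seq", "ref_activity", "query_activity",
              CONDITION_FACTORS)
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop("assay table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("assay table is empty", call. = FALSE)
  check_class_column <- function(x, col) {
    bad <- which(!(as.character(x) %in% c("0", "1")))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s' must be 0 or 1; bad value '%s' at row %d",
                   col, as.character(x)[bad[1]], bad[1]), call. = FALSE)
    }
    as.integer(as.character(x))
  }
  records$ref_activity <- check_class_column(records$ref_activity, "ref_activity")
  records$query_activity <- check_class_column(records$query_activity, "query_activity")
  for (col in c("query_seq", "ref_seq")) {
    bad <- which(!grepl("^[A-Z]+$", records[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s' has an invalid peptide sequence '%s' at row %d",
                   col, records[[col]][bad[1]], bad[1]), call. = FALSE)
    }
  }
  for (col in CONDITION_FACTORS) {
    bad <- which(is.na(records[[col]]) | !nzchar(as.character(records[[col]])))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s' has an empty category at row %d", col, bad[1]),
           call. = FALSE)
    }
    records[[col]] <- as.character(records[[col]])
  }
  invisible(records)
}

#' Per-condition category means of the entropy descriptors
#'
#' For each condition factor and each category observed in the records, the
#' arithmetic mean of the query-sequence entropy vectors over the records
#' carrying that category. The implicit `seq` factor yields the single
#' grand mean over all records. These means are the expectations the
#' perturbation features deviate from.
#'
#' @param records validated assay-record data.frame.
#' @param theta descriptor matrix from [descriptor_table()]; must cover
#'   every query and reference sequence in `records`.
#' @return A list of class `condition_means`: per factor, a matrix of
#'   category means (rownames are categories); `$seq` is the grand-mean
#'   vector.
#' @export
compute_condition_means <- function(records, theta) {
  records <- validate_records(records)
  miss <- setdiff(unique(c(records$query_seq, records$ref_seq)), rownames(theta))
  if (length(miss) > 0L) {
    stop("descriptor table is missing sequence(s): ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  q_theta <- theta[records$query_seq, , drop = FALSE]
  means <- lapply(CONDITION_FACTORS, function(f) {
    g <- factor(records[[f]])
    m <- apply(q_theta, 2, function(col) tapply(col, g, mean))
    if (nlevels(g) == 1L) m <- matrix(m, nrow = 1, dimnames = list(levels(g), colnames(q_theta)))
    m
  })
  names(means) <- CONDITION_FACTORS
  means$seq <- colMeans(q_theta)
  structure(means, class = "condition_means")
}

#' Perturbation of a descriptor against a condition expectation
#'
#' The perturbation of a descriptor value under a condition factor is its
#' deviation from the category mean of that factor: `theta_k - mean_k`.
#'
#' @param theta_k descriptor value(s).
#' @param mean_k matching category mean(s).
#' @return `theta_k - mean_k`.
#' @export
perturbation <- function(theta_k, mean_k) {
  stopifnot(is.numeric(theta_k), is.numeric(mean_k),
            all(is.finite(theta_k)), all(is.finite(mean_k)))
  theta_k - mean_k
}

# Look up the per-record category mean for one factor and one descriptor,
# optionally falling back to the grand mean for unseen categories.
.category_mean <- function(means, factor_name, categories, k_col, unseen) {
  m <- means[[factor_name]]
  hit <- match(categories, rownames(m))
  out <- m[hit, k_col]
  if (anyNA(hit)) {
    if (unseen == "error") {
      stop(sprintf("unseen category '%s' for factor '%s'; no mean available",
                   categories[which(is.na(hit))[1]], factor_name), call. = FALSE)
    }
    out[is.na(hit)] <- means$seq[k_col]
  }
  unname(out)
}

#' Assemble the perturbation-theory feature table
#'
#' Builds one row of model inputs per assay record: the observed reference
#' activity, three query perturbations, and six query-minus-reference
#' perturbation differences, each difference taken under the identical
#' condition category of that record. In reproduction mode the means come
#' from the full table; a leakage-safe caller passes means computed on a
#' training subset instead and chooses how unseen categories are handled.
#'
#' @param records validated assay-record data.frame.
#' @param theta descriptor matrix from [descriptor_table()].
#' @param means [compute_condition_means()] result; defaults to means over
#'   `records` themselves (reproduction mode).
#' @param unseen `"error"` (default) or `"grand_mean"`: what to do when a
#'   record's category has no entry in `means`.
#' @return data.frame with the 10 feature columns of [feature_names()]
#'   plus `label` (the query activity class).
#' @export
assemble_features <- function(records, theta,
                              means = compute_condition_means(records, theta),
                              unseen = c("error", "grand_mean")) {
  unseen <- match.arg(unseen)
  records <- validate_records(records)
  miss <- setdiff(unique(c(records$query_seq, records$ref_seq)), rownames(theta))
  if (length(miss) > 0L) {
    stop("descriptor table is missing sequence(s): ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  q <- theta[records$query_seq, , drop = FALSE]
  r <- theta[records$ref_seq, , drop = FALSE]

  pert_q <- function(k_col, fac) {
    if (fac == "seq") return(unname(q[, k_col] - means$seq[k_col]))
    q[, k_col] - .category_mean(means, fac, records[[fac]], k_col, unseen)
  }
  pert_r <- function(k_col, fac) {
    if (fac == "seq") return(unname(r[, k_col] - means$seq[k_col]))
    r[, k_col] - .category_mean(means, fac, records[[fac]], k_col, unseen)
  }
  d <- function(k_col, fac) pert_q(k_col, fac) - pert_r(k_col, fac)

  out <- data.frame(
    e_ref        = records$ref_activity,
    q_theta5_seq = pert_q("theta5", "seq"),
    q_theta0_org = pert_q("theta0", "org"),
    q_theta0_tech = pert_q("theta0", "tech"),
    d_theta5_seq = d("theta5", "seq"),
    d_theta0_host = d("theta0", "host"),
    d_theta0_adju = d("theta0", "adju"),
    d_theta0_proc = d("theta0", "proc"),
    d_theta0_org = d("theta0", "org"),
    d_theta0_tech = d("theta0", "tech"),
    label        = records$query_activity,
    row.names = NULL
  )
  stopifnot(identical(names(out), c(FEATURE_COLUMNS, "label")))
  out
}

#' Remove duplicate feature rows
#'
#' Rows identical in all 10 features and the label collapse to their first
#' occurrence; other rows keep their order. Equality is taken after
#' rounding features to 6 decimal places, which makes the comparison
#' robust to float noise and reproducible across platforms.
#'
#' @param rows feature data.frame from [assemble_features()] or
#'   [read_feature_table()].
#' @return The deduplicated data.frame.
#' @export
deduplicate <- function(rows) {
  if (nrow(rows) == 0L) return(rows)
  keys <- do.call(paste, c(lapply(rows, function(col) {
    if (is.double(col)) sprintf("%.6f", col) else as.character(col)
  }), sep = "\r"))
  out <- rows[!duplicated(keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}
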