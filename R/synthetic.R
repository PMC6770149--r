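# Standard 20-residue alphabet used by the generator.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a synthetic assay-pair dataset
#'
#' Describes an epitope-assay pair table with known ground truth, emulating
#' the shape of curated immune-epitope assay data at desk scale: short
#' peptides, heavy-tailed (Zipf-skewed) condition-category frequencies,
#' and a roughly 1.84:1 class imbalance. The query activity label is
#' generated by a logistic rule over the reference activity and the
#' perturbation features (standardized internally), plus a product
#' interaction term that plants non-linear structure, then flipped at the
#' label-noise rate.
#'
#' @param n_records number of assay pairs.
#' @param len_range sequence length range, inclusive (default 5-30).
#' @param vocab named category vocabulary sizes for the five condition
#'   factors (defaults: org 50, host 20, proc 15, tech 28, adju 30 — the
#'   real database's 1448/323/15/28/505 factor structure at reduced scale).
#' @param zipf Zipf exponent of category frequencies (default 1.1).
#' @param imbalance target majority:minority class ratio `n_0:n_1`
#'   (default 1.84).
#' @param coefs named logistic coefficients on the feature columns;
#'   continuous features are standardized before entering the linear
#'   predictor, `e_ref` enters as the raw 0/1 class. Default: 2 on
#'   `e_ref`, 1 on `d_theta5_seq`.
#' @param interaction list with `features` (two continuous feature names)
#'   and `weight`: adds `weight * z1 * z2` to the linear predictor
#'   (default: weight 2.5 on `d_theta5_seq` x `d_theta0_org`).
#' @param noise_rate label flip probability in `[0, 0.5)` (default 0.05).
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records = 1000L,
                           len_range = c(5L, 30L),
                           vocab = c(org = 50L, host = 20L, proc = 15L,
                                     tech = 28L, adju = 30L),
                           zipf = 1.1,
                           imbalance = 1.84,
                           coefs = c(e_ref = 2, d_theta5_seq = 1),
                           interaction = list(features = c("d_theta5_seq", "d_theta0_org"),
                                              weight = 2.5),
                           noise_rate = 0.05,
                           seed = 42L) {
  stopifnot(n_records >= 1L, length(len_range) == 2L, len_range[1] >= 1L,
            len_range[1] <= len_range[2],
            all(vocab >= 1L), zipf >= 0, imbalance > 0,
            noise_rate >= 0, noise_rate < 0.5)
  if (!all(names(vocab) == CONDITION_FACTORS)) {
    stop("vocab must be named org, host, proc, tech, adju", call. = FALSE)
  }
  bad <- setdiff(names(coefs), FEATURE_COLUMNS)
  if (length(bad) > 0L) stop("unknown coefficient(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(interaction)) {
    stopifnot(length(interaction$features) == 2L,
              all(interaction$features %in% setdiff(FEATURE_COLUMNS, "e_ref")),
              is.numeric(interaction$weight))
  }
  structure(list(n_records = as.integer(n_records),
                 len_range = as.integer(len_range),
                 vocab = vocab, zipf = zipf, imbalance = imbalance,
                 coefs = coefs, interaction = interaction,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Random peptide sequence
#'
#' Uniform i.i.d. residues over the standard 20-letter alphabet, drawn
#' from the current RNG state.
#'
#' @param length sequence length (>= 1).
#' @return A peptide string.
#' @export
random_peptide <- function(length) {
  if (!is.numeric(length) || length < 1) stop("length must be >= 1", call. = FALSE)
  paste(sample(AA_ALPHABET, as.integer(length), replace = TRUE), collapse = "")
}

# Zipf-skewed category draw: P(category i) proportional to i^-s.
.zipf_sample <- function(n, n_categories, s, prefix) {
  p <- (seq_len(n_categories))^(-s)
  sprintf("%s%03d", prefix, sample.int(n_categories, n, replace = TRUE, prob = p / sum(p)))
}

#' Generate a synthetic assay-pair dataset with known ground truth
#'
#' Draws query and reference peptides, reference activity classes, and
#' Zipf-skewed condition categories; computes the perturbation features
#' through the real descriptor path ([descriptor_table()] +
#' [assemble_features()]); and assigns the query activity by the logistic
#' rule of the spec, with the intercept calibrated so the expected class
#' ratio matches the imbalance target, before flipping labels at the noise
#' rate. Deterministic given the spec (including its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `records` (assay-pair data.frame), `features`
#'   (the feature table the labels were generated from, including the
#'   final labels), and `truth` (all generative parameters, the calibrated
#'   intercept, and the indices of noise-flipped labels).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng())
  n <- spec$n_records
  lens_q <- sample(seq(spec$len_range[1], spec$len_range[2]), n, replace = TRUE)
  lens_r <- sample(seq(spec$len_range[1], spec$len_range[2]), n, replace = TRUE)
  p1 <- 1 / (1 + spec$imbalance)
  records <- data.frame(
    query_seq = vapply(lens_q, random_peptide, character(1)),
    ref_seq = vapply(lens_r, random_peptide, character(1)),
    ref_activity = stats::rbinom(n, 1L, p1),
    query_activity = 0L,  # placeholder; assigned from the features below
    org  = .zipf_sample(n, spec$vocab[["org"]],  spec$zipf, "ORG"),
    host = .zipf_sample(n, spec$vocab[["host"]], spec$zipf, "HOST"),
    proc = .zipf_sample(n, spec$vocab[["proc"]], spec$zipf, "PROC"),
    tech = .zipf_sample(n, spec$vocab[["tech"]], spec$zipf, "TECH"),
    adju = .zipf_sample(n, spec$vocab[["adju"]], spec$zipf, "ADJU"),
    stringsAsFactors = FALSE
  )
  # both activity classes must be representable
  if (n >= 10L && length(unique(records$ref_activity)) < 2L) {
    stop("infeasible imbalance: reference classes degenerate", call. = FALSE)
  }
  theta <- descriptor_table(unique(c(records$query_seq, records$ref_seq)))
  features <- assemble_features(records, theta)

  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  lp <- rep(0, n)
  for (nm in names(spec$coefs)) {
    v <- if (nm == "e_ref") features$e_ref else zscore(features[[nm]])
    lp <- lp + spec$coefs[[nm]] * v
  }
  if (!is.null(spec$interaction)) {
    z1 <- zscore(features[[spec$interaction$features[1]]])
    z2 <- zscore(features[[spec$interaction$features[2]]])
    lp <- lp + spec$interaction$weight * z1 * z2
  }
  # calibrate the intercept so the post-noise class ratio hits the target:
  # flipping at rate rho maps a mean p to p(1 - 2 rho) + rho
  p_star <- (p1 - spec$noise_rate) / (1 - 2 * spec$noise_rate)
  if (p_star <= 0 || p_star >= 1) {
    stop("infeasible imbalance/noise combination: required pre-noise class rate ",
         "falls outside (0, 1)", call. = FALSE)
  }
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) - p_star,
                       interval = c(-50, 50), tol = 1e-10)$root
  y <- stats::rbinom(n, 1L, stats::plogis(b0 + lp))
  flip <- which(stats::runif(n) < spec$noise_rate)
  y[flip] <- 1L - y[flip]
  records$query_activity <- y
  features$label <- y
  list(records = records,
       features = features,
       truth = list(spec = unclass(spec), intercept = b0,
                    p1_target = p1, flipped = flip))
}
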