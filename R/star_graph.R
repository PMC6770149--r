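#' Validate a peptide sequence
#'
#' A valid peptide is a non-empty string of uppercase letters `A`-`Z`.
#' Nonstandard residue codes (B, J, O, U, X, Z) are accepted as residue
#' types in their own right: immune-epitope databases contain them, and
#' rejecting them would silently shrink datasets.
#'
#' @param sequence character scalar to validate.
#' @return The sequence, invisibly, if valid; otherwise an error.
#' @export
validate_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("peptide must be a single character string", call. = FALSE)
  }
  if (nchar(sequence) == 0L) {
    stop("peptide sequence is empty", call. = FALSE)
  }
  if (!grepl("^[A-Z]+$", sequence)) {
    stop(sprintf("invalid peptide sequence '%s': only uppercase letters A-Z are allowed",
                 sequence), call. = FALSE)
  }
  invisible(sequence)
}

#' Build the star-graph recurrence network of a peptide
#'
#' The star graph embeds a sequence of length L as L + 1 nodes: a center
#' node plus one node per residue position. Each distinct residue letter
#' forms a branch: its occurrences are chained in order of appearance, and
#' the first occurrence is joined to the center. The embedded variant
#' additionally connects consecutive sequence positions, retaining the
#' linear backbone on top of the recurrence branches.
#'
#' @param sequence peptide sequence (uppercase letters).
#' @param embedded logical; add consecutive-position backbone edges
#'   (default `FALSE`, the plain non-embedded star graph).
#' @return An object of class `star_graph`: a list with `sequence`,
#'   `n_nodes`, `edges` (2-column integer matrix, node 1 is the center,
#'   node i+1 is sequence position i), `branch_of` (residue letter per
#'   node, `"*"` for the center), and `embedded`.
#' @examples
#' g <- build_star_graph("ACA")
#' g$edges
#' @export
build_star_graph <- function(sequence, embedded = FALSE) {
  validate_peptide(sequence)
  letters_seq <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(letters_seq)
  # node 1 = center; node i + 1 = position i
  prev <- integer(26)  # last node seen per letter, 0 = none yet
  from <- integer(L)
  idx <- match(letters_seq, LETTERS)
  for (i in seq_len(L)) {
    a <- idx[i]
    from[i] <- if (prev[a] == 0L) 1L else prev[a]
    prev[a] <- i + 1L
  }
  edges <- cbind(from, seq_len(L) + 1L)
  if (embedded && L > 1L) {
    backbone <- cbind(2:L, 3:(L + 1L))
    edges <- rbind(edges, backbone)
    # drop duplicates (a repeated letter at consecutive positions is already chained)
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  dimnames(edges) <- NULL
  structure(
    list(sequence = sequence,
         n_nodes = L + 1L,
         edges = edges,
         branch_of = c("*", letters_seq),
         embedded = embedded),
    class = "star_graph"
  )
}

#' @export
print.star_graph <- function(x, ...) {
  cat(sprintf("Star graph of '%s'%s: %d nodes, %d edges, %d branches\n",
              x$sequence, if (x$embedded) " (embedded)" else "",
              x$n_nodes, nrow(x$edges),
              length(unique(x$branch_of)) - 1L))
  invisible(x)
}

#' Markov chain of a star graph
#'
#' The transition matrix is the degree-normalized adjacency matrix of the
#' graph (each adjacency row divided by the node degree), and the initial
#' distribution is uniform over all nodes, center included. Star graphs
#' are connected, so every row is well defined and row-stochastic.
#'
#' @param graph a [build_star_graph()] result.
#' @return A list of class `markov_chain` with `transition` (row-stochastic
#'   matrix) and `initial` (uniform probability vector).
#' @export
markov_chain <- function(graph) {
  stopifnot(inherits(graph, "star_graph"))
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  A[graph$edges] <- 1
  A[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  structure(
    list(transition = A / rowSums(A),
         initial = rep(1 / n, n)),
    class = "markov_chain"
  )
}

#' Shannon-entropy descriptor series of a peptide's Markov chain
#'
#' Propagates the initial node distribution through natural powers of the
#' transition matrix, p(k) = p0 %*% Pi^k, and returns the Shannon entropy
#' theta_k = -sum(p_i(k) * log(p_i(k))) in nats for k = 0..k_max, with the
#' convention 0 * log(0) = 0. theta_0 depends only on p0, and every theta_k
#' lies in [0, log(n_nodes)].
#'
#' @param mc a [markov_chain()] result.
#' @param k_max largest Markov power (default 5).
#' @return Named numeric vector `theta0` .. `theta<k_max>`.
#' @export
shannon_entropy_series <- function(mc, k_max = 5L) {
  stopifnot(inherits(mc, "markov_chain"))
  if (!is.numeric(k_max) || length(k_max) != 1L || is.na(k_max) || k_max < 0) {
    stop("k_max must be a non-negative integer", call. = FALSE)
  }
  k_max <- as.integer(k_max)
  p <- mc$initial
  theta <- numeric(k_max + 1L)
  theta[1L] <- shannon_entropy(p)
  if (k_max > 0L) {
    for (k in seq_len(k_max)) {
      p <- as.numeric(p %*% mc$transition)
      theta[k + 1L] <- shannon_entropy(p)
    }
  }
  names(theta) <- paste0("theta", 0:k_max)
  theta
}

# Shannon entropy in nats with 0 log 0 = 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy descriptors for one peptide
#'
#' Convenience wrapper chaining [build_star_graph()], [markov_chain()] and
#' [shannon_entropy_series()].
#'
#' @inheritParams build_star_graph
#' @inheritParams shannon_entropy_series
#' @return Named numeric vector of entropies `theta0` .. `theta<k_max>`.
#' @export
peptide_entropy <- function(sequence, k_max = 5L, embedded = FALSE) {
  shannon_entropy_series(markov_chain(build_star_graph(sequence, embedded = embedded)),
                         k_max = k_max)
}

#' Entropy descriptor table for a set of peptides
#'
#' Computes each distinct sequence exactly once; the result is independent
#' of input order and duplication. Errors are reported with the offending
#' sequence named.
#'
#' @param sequences character vector of peptide sequences.
#' @inheritParams peptide_entropy
#' @return Numeric matrix, one row per distinct sequence (rownames are the
#'   sequences), columns `theta0` .. `theta<k_max>`.
#' @export
descriptor_table <- function(sequences, k_max = 5L, embedded = FALSE) {
  if (length(sequences) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = k_max + 1L,
                dimnames = list(NULL, paste0("theta", 0:k_max)))
    return(m)
  }
  uniq <- unique(sequences)
  uniq <- uniq[order(uniq)]  # deterministic, order-independent
  rows <- lapply(uniq, function(s) {
    tryCatch(peptide_entropy(s, k_max = k_max, embedded = embedded),
             error = function(e) {
               stop(sprintf("descriptor computation failed for sequence '%s': %s",
                            s, conditionMessage(e)), call. = FALSE)
             })
  })
  m <- do.call(rbind, rows)
  rownames(m) <- uniq
  m
}
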