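# Independent brute-force oracles used to cross-check the implementation.

# Entropy oracle: builds the adjacency from per-letter occurrence lists and
# takes explicit matrix powers, sharing no code with the package path.
oracle_entropy <- function(sequence, k_max = 5L) {
  letters_seq <- strsplit(sequence, "")[[1]]
  n <- length(letters_seq) + 1L
  A <- matrix(0, n, n)
  for (a in unique(letters_seq)) {
    pos <- which(letters_seq == a) + 1L  # node 1 is the center
    A[1, pos[1]] <- A[pos[1], 1] <- 1
    if (length(pos) > 1L) {
      for (i in seq_len(length(pos) - 1L)) {
        A[pos[i], pos[i + 1L]] <- A[pos[i + 1L], pos[i]] <- 1
      }
    }
  }
  Pi <- A / rowSums(A)
  p0 <- rep(1 / n, n)
  ent <- function(p) { p <- p[p > 1e-300]; -sum(p * log(p)) }
  out <- numeric(k_max + 1L)
  Mk <- diag(n)
  out[1] <- ent(p0)
  for (k in seq_len(k_max)) {
    Mk <- Mk %*% Pi                    # explicit repeated multiplication
    out[k + 1L] <- ent(as.numeric(p0 %*% Mk))
  }
  out
}

# AUROC oracle: all-pairs concordance counting with half credit for ties.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small hand-built assay table for feature tests.
toy_records <- function() {
  data.frame(
    query_seq = c("ACA", "AAC", "CCA", "GAG"),
    ref_seq = c("AAC", "ACA", "GAG", "CCA"),
    ref_activity = c(1L, 0L, 1L, 0L),
    query_activity = c(1L, 1L, 0L, 0L),
    org = c("X", "X", "Y", "Y"),
    host = c("H1", "H2", "H1", "H2"),
    proc = c("P", "P", "P", "P"),
    tech = c("T1", "T1", "T2", "T2"),
    adju = c("AD1", "AD2", "AD1", "AD2"),
    stringsAsFactors = FALSE
  )
}

random_sequences <- function(n, min_len = 1, max_len = 30) {
  vapply(sample(seq(min_len, max_len), n, replace = TRUE), function(L) {
    paste(sample(LETTERS[1:20], L, replace = TRUE), collapse = "")
  }, character(1))
}
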