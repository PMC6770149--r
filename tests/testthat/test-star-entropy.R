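test_that("star-graph construction chains recurrences per residue branch", {
  g <- build_star_graph("AA")
  expect_equal(g$n_nodes, 3L)
  expect_equal(g$edges, cbind(c(1L, 2L), c(2L, 3L)))

  # "ACA": center-A1, center-C, A1-A3 (nodes: 1 center, 2..4 positions)
  g2 <- build_star_graph("ACA")
  expect_equal(g2$n_nodes, 4L)
  key <- function(e) sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_equal(key(g2$edges), key(cbind(c(1, 1, 2), c(2, 3, 4))))
  expect_equal(g2$branch_of, c("*", "A", "C", "A"))

  expect_error(build_star_graph(""), "empty")
  expect_error(build_star_graph("A*C"), "invalid")
  expect_error(build_star_graph("acd"), "invalid")
})

test_that("star graphs are connected trees without duplicate or self edges", {
  set.seed(101)
  for (s in random_sequences(25)) {
    for (emb in c(FALSE, TRUE)) {
      g <- build_star_graph(s, embedded = emb)
      expect_equal(g$n_nodes, nchar(s) + 1L)
      expect_true(all(g$edges[, 1] != g$edges[, 2]))
      key <- paste(pmin(g$edges[, 1], g$edges[, 2]), pmax(g$edges[, 1], g$edges[, 2]))
      expect_false(any(duplicated(key)))
      # connectivity by breadth-first expansion from the center
      adj <- lapply(seq_len(g$n_nodes), function(i) {
        c(g$edges[g$edges[, 1] == i, 2], g$edges[g$edges[, 2] == i, 1])
      })
      seen <- 1L; frontier <- 1L
      while (length(frontier) > 0L) {
        nxt <- setdiff(unique(unlist(adj[frontier])), seen)
        seen <- c(seen, nxt); frontier <- nxt
      }
      expect_equal(sort(seen), seq_len(g$n_nodes))
      if (!emb) expect_equal(nrow(g$edges), nchar(s))  # a tree
    }
  }
})

test_that("Markov chain is the degree-normalized adjacency with uniform start", {
  mc1 <- markov_chain(build_star_graph("A"))
  expect_equal(mc1$transition, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(mc1$initial, c(0.5, 0.5))

  mc2 <- markov_chain(build_star_graph("AA"))
  expect_equal(mc2$transition,
               matrix(c(0, 0.5, 0, 1, 0, 1, 0, 0.5, 0), 3, 3))

  # row-stochasticity of every power up to 5, random sequences
  set.seed(7)
  for (s in random_sequences(10)) {
    Pi <- markov_chain(build_star_graph(s))$transition
    Mk <- diag(nrow(Pi))
    for (k in 1:5) {
      Mk <- Mk %*% Pi
      expect_true(all(abs(rowSums(Mk) - 1) < 1e-10))
    }
  }
})

test_that("entropy series matches hand-derived values and stays in bounds", {
  th <- peptide_entropy("AA")
  expect_equal(unname(th["theta0"]), log(3), tolerance = 1e-12)
  expect_equal(unname(th["theta1"]), 0.867563, tolerance = 1e-6)
  # theta0 depends only on p0: uniform over n nodes
  set.seed(11)
  for (s in random_sequences(20)) {
    th <- peptide_entropy(s)
    n <- nchar(s) + 1L
    expect_equal(unname(th["theta0"]), log(n), tolerance = 1e-12)
    expect_true(all(th >= 0 & th <= log(n) + 1e-12))
  }
  expect_error(shannon_entropy_series(markov_chain(build_star_graph("AA")), -1),
               "k_max")
})

test_that("entropy is invariant under residue relabeling", {
  expect_equal(peptide_entropy("AC"), peptide_entropy("CA"))
  set.seed(23)
  for (i in 1:10) {
    s <- random_sequences(1)
    perm <- sample(LETTERS)
    relab <- chartr(paste(LETTERS, collapse = ""), paste(perm, collapse = ""), s)
    expect_equal(peptide_entropy(s), peptide_entropy(relab), tolerance = 1e-12)
  }
})

test_that("entropy series agrees with the brute-force matrix-power oracle", {
  set.seed(31)
  for (s in random_sequences(40)) {
    expect_equal(unname(peptide_entropy(s)), oracle_entropy(s), tolerance = 1e-9)
  }
})

test_that("embedded variant adds backbone edges and changes the descriptors", {
  g <- build_star_graph("ACD", embedded = TRUE)
  key <- paste(pmin(g$edges[, 1], g$edges[, 2]), pmax(g$edges[, 1], g$edges[, 2]))
  expect_true(all(c("2 3", "3 4") %in% key))  # consecutive positions joined
  th_plain <- peptide_entropy("ACDA")
  th_emb <- peptide_entropy("ACDA", embedded = TRUE)
  expect_false(isTRUE(all.equal(th_plain, th_emb)))
  # repeated consecutive letters already chained: no duplicate edges
  g2 <- build_star_graph("AAB", embedded = TRUE)
  key2 <- paste(pmin(g2$edges[, 1], g2$edges[, 2]), pmax(g2$edges[, 1], g2$edges[, 2]))
  expect_false(any(duplicated(key2)))
})

test_that("descriptor table dedupes, is order-independent, and names bad input", {
  m <- descriptor_table(c("AA", "AA", "ACA"))
  expect_equal(nrow(m), 2L)
  expect_setequal(rownames(m), c("AA", "ACA"))
  expect_equal(descriptor_table(c("ACA", "AA")), descriptor_table(c("AA", "ACA")))
  expect_error(descriptor_table(c("AA", "A*")), "A\\*")
  expect_equal(m["AA", ], peptide_entropy("AA"))
})
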