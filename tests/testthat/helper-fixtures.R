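# Shared fixture builders and independent oracles.

# Small quant table built in code.
toy_table <- function(n = 3, nf = 4, ids = sprintf("P%02d", seq_len(n)),
                      intensity = NULL, ibaq = NULL, ...) {
  if (is.null(intensity)) {
    intensity <- matrix(seq_len(n * nf), nrow = n)
  }
  if (is.null(ibaq)) ibaq <- intensity / 10
  quant_table(protein_id = ids, gene_name = toupper(ids),
              intensity = intensity, ibaq = ibaq, ...)
}

# Random normalized profile matrix (rows sum to 1).
random_profiles <- function(n, nf) {
  m <- matrix(stats::runif(n * nf), nrow = n,
              dimnames = list(sprintf("P%02d", seq_len(n)), NULL))
  m / rowSums(m)
}

# Brute-force Manhattan distance, element-wise double loop.
brute_manhattan <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (f in seq_len(ncol(m))) s <- s + abs(m[i, f] - m[j, f])
    d[i, j] <- s
  }
  d
}

# Naive UPGMA oracle: recomputes every inter-cluster mean from the original
# matrix at each step (no Lance-Williams update), same lexicographic
# tie-break contract as average_linkage().
naive_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))     # cluster id -> leaf members
  active <- seq_len(n)
  merges <- NULL
  for (step in seq_len(n - 1L)) {
    best <- NULL; best_h <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq.int(ii + 1L, length(active))) {
        a <- active[ii]; b <- active[jj]
        h <- mean(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) { best_h <- h; best <- c(a, b) }
      }
    }
    new_id <- n + step
    clusters[[new_id]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active <- sort(c(setdiff(active, best), new_id))
    merges <- rbind(merges, data.frame(step = step, a = best[1], b = best[2],
                                       height = best_h))
  }
  merges
}

# Protein ids by ground-truth role.
truth_ids <- function(truth, roles) {
  vapply(Filter(function(s) s$role %in% roles, truth$subunits),
         function(s) s$protein_id, character(1))
}

expect_quant_tables_equal <- function(a, b) {
  expect_equal(a$proteins, b$proteins)
  expect_equal(a$n_fractions, b$n_fractions)
  expect_equal(a$fraction_labels, b$fraction_labels)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  expect_equal(a$ibaq, b$ibaq, tolerance = 1e-12)
}
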