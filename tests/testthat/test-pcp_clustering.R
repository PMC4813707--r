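pcp_dist_from_matrix <- function(d) {
  structure(list(ids = rownames(d), d = d), class = "pcp_dist")
}

test_that("Manhattan distances match closed forms and the brute-force oracle", {
  d <- manhattan_matrix(rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0)))
  expect_equal(d$d["a", "b"], 2)
  expect_equal(d$d["a", "c"], 0)

  withr::local_seed(5)
  m <- random_profiles(5, 6)
  expect_equal(manhattan_matrix(m)$d, brute_manhattan(m), tolerance = 1e-12)
})

test_that("Manhattan distance satisfies the metric axioms on random inputs", {
  withr::local_seed(6)
  for (rep in 1:10) {
    m <- random_profiles(6, 8)
    d <- manhattan_matrix(m)$d
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d[upper.tri(d)] >= 0))
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("zero-total profiles are excluded from clustering", {
  tab <- toy_table(n = 3, nf = 3,
                   intensity = rbind(c(1, 1, 0), c(0, 0, 0), c(0, 1, 1)))
  d <- manhattan_matrix(build_profiles(tab))
  expect_identical(d$ids, c("P01", "P03"))
})

test_that("average linkage reproduces hand-computed UPGMA", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- average_linkage(pcp_dist_from_matrix(d))
  expect_equal(tree$merges$height, c(1, 10))
  expect_identical(c(tree$merges$a[1], tree$merges$b[1]), c(1L, 2L))

  d2 <- matrix(c(0, 3, 3, 0), nrow = 2, dimnames = list(c("x", "y"), c("x", "y")))
  tree2 <- average_linkage(pcp_dist_from_matrix(d2))
  expect_equal(tree2$merges$height, 3)
})

test_that("average linkage agrees with the naive recompute oracle, ties included", {
  withr::local_seed(7)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    # integer distances force exact ties regularly
    v <- sample(1:5, n * (n - 1) / 2, replace = TRUE)
    d <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
    d[lower.tri(d)] <- v
    d <- d + t(d)
    tree <- average_linkage(pcp_dist_from_matrix(d))
    oracle <- naive_upgma(d)
    expect_equal(tree$merges$a, oracle$a)
    expect_equal(tree$merges$b, oracle$b)
    expect_equal(tree$merges$height, oracle$height, tolerance = 1e-12)
  }
})

test_that("the dendrogram matches stats::hclust cophenetic structure", {
  withr::local_seed(8)
  m <- random_profiles(9, 12)
  dm <- manhattan_matrix(m)
  mine <- stats::cophenetic(as.hclust(average_linkage(dm)))
  ref <- stats::cophenetic(stats::hclust(stats::as.dist(dm$d), method = "average"))
  expect_equal(as.matrix(mine), as.matrix(ref), tolerance = 1e-10)
})

test_that("co_cluster cuts behave at the extremes and are monotone in height", {
  withr::local_seed(9)
  m <- random_profiles(7, 10)
  dm <- manhattan_matrix(m)
  tree <- average_linkage(dm)
  expect_identical(co_cluster(tree, "P03", 0), "P03")
  expect_setequal(co_cluster(tree, "P03", max(tree$merges$height)), dm$ids)
  heights <- sort(c(0, tree$merges$height, max(tree$merges$height) + 1))
  prev <- character(0)
  for (h in heights) {
    cur <- co_cluster(tree, "P01", h)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_error(co_cluster(tree, "nope", 1), class = "bnpcp_value_error")
})

test_that("heatmap order is a permutation consistent with the dendrogram", {
  withr::local_seed(10)
  m <- random_profiles(6, 9)
  dm <- manhattan_matrix(m)
  tree <- average_linkage(dm)
  hm <- heatmap_order(tree, dm)
  expect_setequal(hm$ids, dm$ids)
  expect_equal(sort(as.vector(hm$d)), sort(as.vector(dm$d)))
  expect_identical(hm$ids, tree$labels[leaf_order(tree)])
})

test_that("the default cut recovers the synthetic complex without contaminants", {
  tr <- default_truth(noise_cv = 0, dropout_rate = 0)
  pr <- build_profiles(simulate_table(tr, 1L))
  tree <- average_linkage(manhattan_matrix(pr))
  roi <- bait_region_of_interest(tree, "P_MTA2")
  expect_true(all(truth_ids(tr, c("bait", "core", "enriched")) %in% roi$members))
  expect_false(any(truth_ids(tr, "contaminant") %in% roi$members))
})

test_that("newick and merge-table exports are well formed", {
  withr::local_seed(11)
  m <- random_profiles(5, 6)
  tree <- average_linkage(manhattan_matrix(m))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  s <- readLines(nwk)
  expect_match(s, ";$")
  expect_identical(lengths(regmatches(s, gregexpr("\\(", s))),
                   lengths(regmatches(s, gregexpr("\\)", s))))
  for (id in rownames(m)) expect_match(s, id, fixed = TRUE)

  mt <- withr::local_tempfile(fileext = ".tsv")
  write_merge_table(tree, mt)
  df <- utils::read.delim(mt)
  expect_identical(nrow(df), nrow(m) - 1L)
  expect_true(all(diff(df$height) >= -1e-12))
})
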