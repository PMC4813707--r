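test_that("gene sets normalize case and deduplicate", {
  gs <- gene_set("test", c("sox2", "SOX2", "Nanog", " pou5f1 ", ""))
  expect_setequal(gs$genes, c("SOX2", "NANOG", "POU5F1"))

  path <- withr::local_tempfile()
  writeLines(c("# targets", "sox2", "", "SOX2", "Nanog"), path)
  gs2 <- read_gene_set(path, "targets")
  expect_identical(length(gs2$genes), 2L)

  empty <- withr::local_tempfile()
  writeLines(c("# only a comment"), empty)
  expect_warning(read_gene_set(empty), "empty")
})

test_that("proxy set is the intersection, brute-force checked", {
  a <- gene_set("a", c("A", "B"))
  b <- gene_set("b", c("B", "C"))
  c_ <- gene_set("c", "B")
  expect_identical(proxy_set(list(a, b, c_), "p")$genes, "B")
  expect_length(proxy_set(list(a, gene_set("e", character(0))), "p")$genes, 0L)
  expect_error(proxy_set(list(a), "p"), class = "bnpcp_input_error")

  withr::local_seed(13)
  syms <- sprintf("G%04d", 1:400)
  sets <- lapply(1:3, function(i) gene_set(paste0("s", i), sample(syms, 100)))
  got <- proxy_set(sets, "p")$genes
  brute <- character(0)
  for (g in sets[[1]]$genes) {
    inner <- FALSE
    for (h in sets[[2]]$genes) if (g == h) inner <- TRUE
    if (!inner) next
    inner2 <- FALSE
    for (h in sets[[3]]$genes) if (g == h) inner2 <- TRUE
    if (inner2) brute <- c(brute, g)
  }
  expect_setequal(got, brute)
})

test_that("overlap percentages reproduce the worked example and edge cases", {
  ref <- gene_set("nurd", sprintf("N%04d", 1:1604))
  other <- gene_set("wdr5", c(sprintf("N%04d", 1:1162), sprintf("W%04d", 1:500)))
  ov <- overlap_percent(ref, other)
  expect_identical(ov$count_shared, 1162L)
  expect_identical(ov$count_reference, 1604L)
  expect_identical(ov$percent, 72L)

  expect_identical(overlap_percent(ref, gene_set("x", "Z1"))$percent, 0L)
  sub <- gene_set("sub", sprintf("N%04d", 1:10))
  expect_identical(overlap_percent(sub, ref)$percent, 100L)
  expect_identical(overlap_percent(ref, ref)$percent, 100L)
  expect_error(overlap_percent(gene_set("e", character(0)), ref),
               class = "bnpcp_value_error")
})

test_that("percent rounding is half-up", {
  ref <- gene_set("r", sprintf("A%02d", 1:8))
  other <- gene_set("o", sprintf("A%02d", 1:1))  # 12.5% -> 13
  expect_identical(overlap_percent(ref, other)$percent, 13L)
})

test_that("venn3 partitions match hand enumeration and brute force", {
  p <- venn3(gene_set("A", c("1", "2")), gene_set("B", c("2", "3")),
             gene_set("C", "3"))
  expect_identical(unname(p$counts[c("A", "B", "C", "AB", "AC", "BC", "ABC")]),
                   c(1L, 0L, 0L, 1L, 0L, 1L, 0L))

  same <- gene_set("s", c("X", "Y"))
  p2 <- venn3(same, same, same)
  expect_identical(unname(p2$counts["ABC"]), 2L)
  expect_identical(sum(p2$counts), 2L)

  withr::local_seed(14)
  syms <- sprintf("G%03d", 1:120)
  a <- gene_set("a", sample(syms, 60))
  b <- gene_set("b", sample(syms, 60))
  c_ <- gene_set("c", sample(syms, 60))
  p3 <- venn3(a, b, c_)
  # brute-force per-element classification
  uni <- union(union(a$genes, b$genes), c_$genes)
  counts <- integer(7)
  names(counts) <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  for (g in uni) {
    key <- paste0(if (g %in% a$genes) "A" else "",
                  if (g %in% b$genes) "B" else "",
                  if (g %in% c_$genes) "C" else "")
    counts[key] <- counts[key] + 1L
  }
  expect_identical(p3$counts, counts)
  # conservation: regions sum to the union, per-set totals recoverable
  expect_identical(sum(p3$counts), length(uni))
  expect_identical(unname(sum(p3$counts[c("A", "AB", "AC", "ABC")])),
                   length(a$genes))
})

test_that("shared fraction of partner-bound loci reproduces the printed 7%", {
  p <- venn3_from_counts(c(A = 1123, AB = 105, AC = 342, ABC = 34),
                         set_names = c(A = "NuRD", B = "Suz12", C = "Sall4"))
  expect_identical(shared_fraction_of_partners(p), 7L)
  expect_identical(shared_fraction_of_partners(venn3_from_counts(c(AB = 5, AC = 5))),
                   0L)
  expect_identical(shared_fraction_of_partners(venn3_from_counts(c(ABC = 9))), 100L)
  expect_error(shared_fraction_of_partners(venn3_from_counts(c(A = 3))),
               class = "bnpcp_value_error")
})

test_that("the partition -> filter chain computes retention", {
  part <- gene_set("part", c("A", "B", "C", "D"))
  expect_identical(partition_filter_chain(part, part)$percent_retained, 100L)
  expect_identical(
    partition_filter_chain(part, gene_set("x", c("Z")))$percent_retained, 0L)
  expect_error(partition_filter_chain(gene_set("e", character(0)), part),
               class = "bnpcp_value_error")

  withr::local_seed(15)
  syms <- sprintf("G%03d", 1:200)
  pg <- gene_set("pg", sample(syms, 80))
  fs <- gene_set("fs", sample(syms, 90))
  chain <- partition_filter_chain(pg, fs)
  brute <- sum(vapply(pg$genes, function(g) any(fs$genes == g), logical(1)))
  expect_identical(length(chain$filtered$genes), as.integer(brute))
  expect_identical(chain$percent_retained,
                   as.integer(floor(100 * brute / 80 + 0.5)))

  p <- venn3(gene_set("A", c("1", "2", "3")), gene_set("B", c("2", "3")),
             gene_set("C", c("3", "4")))
  pooled <- partition_genes(p, c("AB", "AC", "ABC"))
  expect_setequal(pooled$genes, c("2", "3"))
  expect_error(partition_genes(p, "XY"), class = "bnpcp_input_error")
})

test_that("set operations are order- and duplication-invariant", {
  a1 <- gene_set("a", c("X", "Y", "Z"))
  a2 <- gene_set("a", c("z", "Y", "X", "x", "y"))
  b <- gene_set("b", c("Y", "W"))
  expect_identical(overlap_percent(a1, b), overlap_percent(a2, b))
  expect_identical(venn3(a1, b, a1)$counts, venn3(a2, b, a2)$counts)
})
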