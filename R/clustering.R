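# Protein correlation profiling: Manhattan distances between migration
# profiles, average-linkage (UPGMA) agglomeration, the bait's co-cluster
# ("region of interest"), and heatmap ordering.

#' Pairwise Manhattan distance matrix between migration profiles
#'
#' `d[i, j] = sum_f |v_i[f] - v_j[f]|` on the normalized profile vectors.
#' Zero-total proteins are excluded: their profile is undefined under
#' total-intensity normalization, so no distance is meaningful for them.
#'
#' @param profiles A `migration_profiles` object (or a numeric matrix with
#'   row names, rows = proteins).
#' @return A `pcp_dist`: list with `ids` and the symmetric matrix `d`.
#' @export
manhattan_matrix <- function(profiles) {
  if (inherits(profiles, "migration_profiles")) {
    keep <- profiles$total_intensity > 0
    m <- profiles$values[keep, , drop = FALSE]
    ids <- profiles$ids[keep]
  } else if (is.matrix(profiles)) {
    m <- profiles
    ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  } else {
    abort_input("expected migration_profiles or a matrix")
  }
  if (nrow(m) < 2L) abort_input("need at least 2 nonzero profiles")
  d <- as.matrix(stats::dist(m, method = "manhattan"))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "pcp_dist")
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates the pair of clusters with minimal mean inter-cluster
#' distance at each step, recording that mean as the merge height.
#' Inter-cluster means are maintained with the exact Lance-Williams update
#' for average linkage. Ties are broken deterministically by the
#' lexicographically lowest (i, j) cluster-index pair, with leaves numbered
#' 1..n in input order and merged clusters n+1, n+2, ... in creation order.
#'
#' @param dist A `pcp_dist` from [manhattan_matrix()] (or any symmetric
#'   matrix wrapped the same way).
#' @return A `pcp_dendrogram`: merge table (step, a, b, height; a and b are
#'   cluster indices), labels, and n.
#' @export
average_linkage <- function(dist) {
  if (!inherits(dist, "pcp_dist")) abort_input("expected a pcp_dist")
  d <- dist$d
  n <- nrow(d)
  if (n < 2L) abort_input("need at least 2 items")
  # Active-cluster bookkeeping; dm holds mean inter-cluster distances.
  active <- seq_len(n)
  sizes <- rep(1L, n)
  dm <- matrix(NA_real_, nrow = 2L * n - 1L, ncol = 2L * n - 1L)
  dm[seq_len(n), seq_len(n)] <- d
  merges <- data.frame(step = integer(n - 1L), a = integer(n - 1L),
                       b = integer(n - 1L), height = numeric(n - 1L))
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_)
    best_h <- Inf
    for (ii in seq_len(length(active) - 1L)) {
      for (jj in seq.int(ii + 1L, length(active))) {
        i <- active[ii]; j <- active[jj]
        h <- dm[i, j]
        if (h < best_h) { best_h <- h; best <- c(i, j) }
        # strict < keeps the earliest (lowest-index) pair on ties because
        # `active` is maintained in increasing cluster-index order
      }
    }
    a <- best[1]; b <- best[2]
    new_id <- n + step
    # Lance-Williams update for average linkage
    rest <- setdiff(active, c(a, b))
    for (cl in rest) {
      dm[new_id, cl] <- dm[cl, new_id] <-
        (sizes[a] * dm[a, cl] + sizes[b] * dm[b, cl]) / (sizes[a] + sizes[b])
    }
    sizes[new_id] <- sizes[a] + sizes[b]
    active <- c(rest[rest < new_id], new_id)
    active <- sort(active)
    merges[step, ] <- list(step, a, b, best_h)
  }
  structure(
    list(merges = merges, labels = dist$ids, n = n),
    class = "pcp_dendrogram"
  )
}

#' @export
print.pcp_dendrogram <- function(x, ...) {
  cat(sprintf("<pcp_dendrogram> %d leaves, %d merges, height range [%.4g, %.4g]\n",
              x$n, nrow(x$merges), min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

# Leaf ids (1..n) under a cluster index.
cluster_leaves <- function(tree, cluster) {
  n <- tree$n
  if (cluster <= n) return(cluster)
  row <- tree$merges[cluster - n, ]
  c(cluster_leaves(tree, row$a), cluster_leaves(tree, row$b))
}

#' Dendrogram leaf order for display
#'
#' Left subtree = earlier-created (lower-index) cluster; purely cosmetic but
#' deterministic.
#'
#' @param tree A `pcp_dendrogram`.
#' @return Integer vector of leaf indices in display order.
#' @export
leaf_order <- function(tree) {
  cluster_leaves(tree, tree$n + nrow(tree$merges))
}

#' Members of the bait's cluster at a height cut
#'
#' Applies merges with height <= `height` (average linkage on a metric is
#' reducible, so heights are non-decreasing) and returns the members of the
#' cluster containing the bait.
#'
#' @param tree A `pcp_dendrogram`.
#' @param bait_id Label of the bait leaf.
#' @param height Nonnegative cut height.
#' @return Character vector of member labels (always includes the bait).
#' @export
co_cluster <- function(tree, bait_id, height) {
  bait <- match(bait_id, tree$labels)
  if (is.na(bait)) abort_value(sprintf("unknown bait: %s", bait_id))
  if (height < 0) abort_input("height must be >= 0")
  membership <- seq_len(tree$n)
  for (k in seq_len(nrow(tree$merges))) {
    row <- tree$merges[k, ]
    if (row$height > height) break
    la <- cluster_leaves(tree, row$a)
    lb <- cluster_leaves(tree, row$b)
    membership[membership %in% membership[c(la, lb)]] <- min(membership[c(la, lb)])
  }
  tree$labels[membership == membership[bait]]
}

#' Bait region of interest by the default cut rule
#'
#' Follows the bait's cluster through the merge history and stops at the
#' first merge that brings its size to at least `k` members; the cut height
#' is that merge's height. `k` defaults to 15, the size of the default
#' synthetic region of interest: bait, 7 flat core subunits, 3
#' entity-II-enriched subunits, and 4 entity-specific or shared partners --
#' mirroring how a bait's heatmap cluster contains the complex together
#' with its specific interactors.
#'
#' @param tree A `pcp_dendrogram`.
#' @param bait_id Label of the bait leaf.
#' @param k Minimum member count of the returned cluster.
#' @return List with `members` (labels), `height` (the cut height used).
#' @export
bait_region_of_interest <- function(tree, bait_id, k = 15L) {
  bait <- match(bait_id, tree$labels)
  if (is.na(bait)) abort_value(sprintf("unknown bait: %s", bait_id))
  members <- bait
  for (step in seq_len(nrow(tree$merges))) {
    row <- tree$merges[step, ]
    la <- cluster_leaves(tree, row$a)
    lb <- cluster_leaves(tree, row$b)
    if (any(members %in% c(la, lb))) members <- union(members, c(la, lb))
    if (length(members) >= k) {
      return(list(members = tree$labels[sort(members)], height = row$height))
    }
  }
  list(members = tree$labels, height = max(tree$merges$height))
}

#' Heatmap ordering of a distance matrix
#'
#' @param tree A `pcp_dendrogram` over the same ids as `dist`.
#' @param dist The `pcp_dist` the tree was built from.
#' @return List with `ids` (dendrogram leaf order) and `d` (matrix
#'   reordered accordingly).
#' @export
heatmap_order <- function(tree, dist) {
  if (!identical(sort(tree$labels), sort(dist$ids))) {
    abort_input("tree and distance matrix ids differ")
  }
  ord <- tree$labels[leaf_order(tree)]
  idx <- match(ord, dist$ids)
  list(ids = ord, d = dist$d[idx, idx, drop = FALSE])
}

#' Convert to a stats::hclust object
#'
#' Enables base-R plotting and interoperability (e.g. `ape::as.phylo`).
#'
#' @param x A `pcp_dendrogram`.
#' @param ... Unused.
#' @return An `hclust` object with method `"average"`.
#' @export
as.hclust.pcp_dendrogram <- function(x, ...) {
  n <- x$n
  merge <- cbind(
    ifelse(x$merges$a <= n, -x$merges$a, x$merges$a - n),
    ifelse(x$merges$b <= n, -x$merges$b, x$merges$b - n)
  )
  structure(
    list(merge = merge, height = x$merges$height, order = leaf_order(x),
         labels = x$labels, method = "average",
         dist.method = "manhattan", call = match.call()),
    class = "hclust"
  )
}

#' Export the dendrogram in Newick format
#'
#' Ultrametric branch lengths: each internal node sits at its merge height,
#' leaves at height 0.
#'
#' @param tree A `pcp_dendrogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  n <- tree$n
  node_height <- function(cl) if (cl <= n) 0 else tree$merges$height[cl - n]
  build <- function(cl, parent_h) {
    bl <- parent_h - node_height(cl)
    if (cl <= n) {
      sprintf("%s:%.10g", gsub("[ ,():;]", "_", tree$labels[cl]), bl)
    } else {
      row <- tree$merges[cl - n, ]
      h <- row$height
      sprintf("(%s,%s):%.10g", build(row$a, h), build(row$b, h), bl)
    }
  }
  root <- n + nrow(tree$merges)
  row <- tree$merges[root - n, ]
  h <- row$height
  writeLines(sprintf("(%s,%s);", build(row$a, h), build(row$b, h)), path)
  invisible(path)
}

#' Write the merge history as TSV
#'
#' Columns: step, members_a, members_b (semicolon-joined labels), height.
#'
#' @param tree A `pcp_dendrogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_merge_table <- function(tree, path) {
  lab <- function(cl) paste(tree$labels[cluster_leaves(tree, cl)], collapse = ";")
  df <- data.frame(
    step = tree$merges$step,
    members_a = vapply(tree$merges$a, lab, character(1)),
    members_b = vapply(tree$merges$b, lab, character(1)),
    height = tree$merges$height
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
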