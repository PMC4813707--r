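# Target-gene co-occupancy: gene sets, the intersection-based complex proxy,
# pairwise overlap percentages, 3-way Venn partitions, and the
# partition -> filter chain.
#
# Gene identity is uppercased symbol string match; published target lists
# are compared as given, with no alias or ortholog resolution and no
# peak-to-gene reassignment.

#' Construct a named gene set
#'
#' Symbols are uppercased and deduplicated; empty strings are dropped.
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols.
#' @return A `gene_set`: list(name, genes).
#' @export
gene_set <- function(name, genes) {
  g <- unique(toupper(trimws(as.character(genes))))
  g <- g[nzchar(g)]
  structure(list(name = as.character(name), genes = g), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d symbols\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read a gene list file
#'
#' One symbol per line; blank lines and lines starting with `#` are
#' skipped; symbols are case-normalized and deduplicated. An empty result
#' is a warning, not an error.
#'
#' @param path Text file path.
#' @param name Name for the set (default: file base name).
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  gs <- gene_set(name %||% sub("\\.[^.]*$", "", basename(path)), x)
  if (length(gs$genes) == 0L) {
    warning(sprintf("gene set %s is empty", gs$name), call. = FALSE)
  }
  gs
}

#' Intersection-based complex proxy set
#'
#' Because individual subunits also occur in other complexes, the
#' intersection of several subunits' target-gene sets approximates the
#' binding of the intact complex (e.g. Chd4 n Hdac1 n Hdac2 for NuRD).
#'
#' @param sets List of >= 2 [gene_set()] objects.
#' @param name Name for the proxy set.
#' @return A [gene_set()] containing the intersection.
#' @export
proxy_set <- function(sets, name) {
  if (length(sets) < 2L) abort_input("need >= 2 sets for a proxy")
  genes <- Reduce(intersect, lapply(sets, `[[`, "genes"))
  gene_set(name, genes)
}

#' Percent of a reference set shared with another set
#'
#' `percent = round(100 * |reference n other| / |reference|)`, rounded
#' half-up to an integer (the reporting convention for overlaps like
#' "72% (1162 of 1604)").
#'
#' @param reference Non-empty [gene_set()] whose size is the denominator.
#' @param other [gene_set()] to intersect with.
#' @return List: `count_shared`, `count_reference`, `percent`.
#' @export
overlap_percent <- function(reference, other) {
  n_ref <- length(reference$genes)
  if (n_ref == 0L) abort_value("reference set is empty")
  shared <- length(intersect(reference$genes, other$genes))
  list(
    count_shared = shared,
    count_reference = n_ref,
    percent = as.integer(round_half_up(100 * shared / n_ref))
  )
}

#' Three-way Venn partition
#'
#' Counts (and members) of the 7 exclusive regions of sets A, B, C.
#' Region names use the set roles: `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC`
#' (each region excludes the others, so `AB` means "in A and B but not C").
#'
#' @param a,b,c Three [gene_set()] objects.
#' @return A `venn3_partition`: `counts` (named integer vector), `regions`
#'   (named list of member vectors), `set_names`.
#' @export
venn3 <- function(a, b, c) {
  universe <- union(union(a$genes, b$genes), c$genes)
  in_a <- universe %in% a$genes
  in_b <- universe %in% b$genes
  in_c <- universe %in% c$genes
  key <- paste0(ifelse(in_a, "A", ""), ifelse(in_b, "B", ""), ifelse(in_c, "C", ""))
  region_names <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  regions <- lapply(region_names, function(r) universe[key == r])
  names(regions) <- region_names
  counts <- vapply(regions, length, integer(1))
  structure(
    list(counts = counts, regions = regions,
         set_names = c(A = a$name, B = b$name, C = c$name)),
    class = "venn3_partition"
  )
}

#' @export
print.venn3_partition <- function(x, ...) {
  cat(sprintf("<venn3_partition> A=%s B=%s C=%s\n",
              x$set_names["A"], x$set_names["B"], x$set_names["C"]))
  print(x$counts)
  invisible(x)
}

#' Construct a venn3_partition directly from region counts
#'
#' For worked examples where only the printed partition counts are known;
#' synthetic placeholder symbols are generated for each region.
#'
#' @param counts Named vector with entries among A, B, C, AB, AC, BC, ABC
#'   (missing regions default to 0).
#' @param set_names Optional names for the three sets.
#' @return A `venn3_partition` realizing those counts.
#' @export
venn3_from_counts <- function(counts, set_names = c(A = "A", B = "B", C = "C")) {
  region_names <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  full <- stats::setNames(integer(7), region_names)
  full[names(counts)] <- as.integer(counts)
  regions <- lapply(region_names, function(r) {
    if (full[r] == 0L) character(0)
    else sprintf("%s_%05d", r, seq_len(full[r]))
  })
  names(regions) <- region_names
  structure(
    list(counts = full, regions = regions, set_names = set_names),
    class = "venn3_partition"
  )
}

#' Members of one or more partition regions as a gene set
#'
#' @param partition A `venn3_partition`.
#' @param region_names Regions to pool, e.g. `c("AB", "AC", "ABC")`.
#' @param name Name for the pooled set.
#' @return A [gene_set()].
#' @export
partition_genes <- function(partition, region_names, name = NULL) {
  bad <- setdiff(region_names, names(partition$regions))
  if (length(bad)) abort_input(sprintf("unknown region(s): %s", paste(bad, collapse = ", ")))
  gene_set(name %||% paste(region_names, collapse = "+"),
           unlist(partition$regions[region_names], use.names = FALSE))
}

#' Shared fraction of the complex's partner-bound loci
#'
#' With A the complex proxy and B, C two partners, computes
#' `round(100 * ABC / (AB + AC + ABC))`: of the complex loci bound by
#' either partner, the percent bound by both (e.g. "only 7% were common
#' targets" from counts 105, 342, 34).
#'
#' @param partition A `venn3_partition` with the complex proxy in role A.
#' @return Integer percent (half-up).
#' @export
shared_fraction_of_partners <- function(partition) {
  counts <- partition$counts
  denom <- counts["AB"] + counts["AC"] + counts["ABC"]
  if (denom == 0) abort_value("no complex loci bound by either partner")
  as.integer(round_half_up(100 * counts["ABC"] / denom))
}

#' Partition -> filter chain
#'
#' Pools previously identified partition genes into one set and reduces it
#' to the genes also present in `filter_set` (e.g. shared NuRD/Sall4,
#' NuRD/Suz12 and triple loci filtered for Wdr5 co-localization).
#'
#' @param partition_genes_set Non-empty [gene_set()] of pooled partition
#'   members.
#' @param filter_set [gene_set()] to intersect with.
#' @return List: `filtered` ([gene_set()]), `percent_retained` (half-up
#'   integer).
#' @export
partition_filter_chain <- function(partition_genes_set, filter_set) {
  n <- length(partition_genes_set$genes)
  if (n == 0L) abort_value("empty partition gene set")
  filtered <- gene_set(
    paste0(partition_genes_set$name, "&", filter_set$name),
    intersect(partition_genes_set$genes, filter_set$genes)
  )
  list(
    filtered = filtered,
    percent_retained = as.integer(round_half_up(100 * length(filtered$genes) / n))
  )
}

#' Write a venn3 partition as TSV
#' @param partition A `venn3_partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_venn3 <- function(partition, path) {
  df <- data.frame(
    region = names(partition$counts),
    count = unname(partition$counts),
    genes = vapply(partition$regions, function(g) paste(g, collapse = ";"),
                   character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
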