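# Synthetic two-assembly BN-PAGE AP-MS data generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a bait whose migration profile has two partially overlapping
# Gaussian peaks in the high-mass region of a 48-fraction gel, subunits that
# co-migrate with both peaks at fixed or entity-biased stoichiometry, partner
# proteins confined to one peak, nonspecific contaminants with unstructured
# profiles, multiplicative log-normal noise, Bernoulli dropout, and an integer
# fraction shift between replicates (gel-cutting differences).

.INTENSITY_SCALE <- 1e9

#' Describe one complex entity (one bait peak)
#'
#' An entity is a distinct assembly of the bait complex, visible as one peak
#' in the bait's migration profile. The signal model places a Gaussian of the
#' given width (in fraction units) at `apex_fraction`, scaled by
#' `bait_amount`.
#'
#' @param label Entity label, e.g. `"I"` or `"II"`.
#' @param apex_fraction Integer fraction index of the peak apex (1 = gel
#'   bottom = low mass).
#' @param width Gaussian standard deviation in fraction units; must be > 0.
#' @param bait_amount Nonnegative abundance scalar for the bait in this
#'   entity.
#' @return An `entity_spec` list.
#' @export
entity_spec <- function(label, apex_fraction, width, bait_amount) {
  if (width <= 0) abort_input("entity width must be > 0")
  if (bait_amount < 0) abort_input("bait_amount must be nonnegative")
  structure(
    list(
      label = as.character(label),
      apex_fraction = as.integer(apex_fraction),
      width = as.numeric(width),
      bait_amount = as.numeric(bait_amount)
    ),
    class = "entity_spec"
  )
}

#' Describe one simulated protein
#'
#' `per_entity_ratio` gives the protein's abundance relative to the bait in
#' each entity; a flat-ratio subunit has equal entries, an entity-biased
#' subunit unequal entries, and a single-entity partner a zero entry.
#' Contaminants must have all-zero ratios; they receive unstructured
#' background intensities instead of entity signal.
#'
#' @param protein_id Unique protein identifier.
#' @param gene_name Gene symbol.
#' @param per_entity_ratio Nonnegative numeric vector, one value per entity.
#' @param is_bait Logical; exactly one subunit per truth may be the bait.
#' @param is_contaminant Logical; nonspecific background protein.
#' @param role Free-text bookkeeping label (`"bait"`, `"core"`, `"enriched"`,
#'   `"partner"`, `"contaminant"`); used by tests to compare against truth and
#'   not part of the simulated tables.
#' @return A `subunit_spec` list.
#' @export
subunit_spec <- function(protein_id, gene_name, per_entity_ratio,
                         is_bait = FALSE, is_contaminant = FALSE,
                         role = NULL) {
  if (any(per_entity_ratio < 0)) abort_input("per_entity_ratio must be nonnegative")
  if (is_contaminant && any(per_entity_ratio != 0)) {
    abort_input("contaminants must have all per_entity_ratio = 0")
  }
  structure(
    list(
      protein_id = as.character(protein_id),
      gene_name = as.character(gene_name),
      per_entity_ratio = as.numeric(per_entity_ratio),
      is_bait = isTRUE(is_bait),
      is_contaminant = isTRUE(is_contaminant),
      role = role %||% if (isTRUE(is_bait)) "bait" else if (isTRUE(is_contaminant)) "contaminant" else "subunit"
    ),
    class = "subunit_spec"
  )
}

#' Assemble a synthetic ground truth
#'
#' @param n_fractions Number of gel fractions (>= 2).
#' @param entities List of [entity_spec()] objects.
#' @param subunits List of [subunit_spec()] objects; exactly one bait.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise (>= 0; 0 disables noise).
#' @param dropout_rate Probability that a true-nonzero cell is reported as 0
#'   (in `[0, 1)`).
#' @param replicate_shift Integer fraction offset added to every entity apex
#'   in replicate 2, emulating gel-cutting differences.
#' @param seed Integer seed; all randomness in [simulate_table()] derives
#'   deterministically from it.
#' @return A validated `synthetic_truth` object.
#' @export
synthetic_truth <- function(n_fractions, entities, subunits,
                            noise_cv = 0.1, dropout_rate = 0.1,
                            replicate_shift = 1L, seed = 42L) {
  truth <- structure(
    list(
      n_fractions = as.integer(n_fractions),
      entities = entities,
      subunits = subunits,
      noise_cv = as.numeric(noise_cv),
      dropout_rate = as.numeric(dropout_rate),
      replicate_shift = as.integer(replicate_shift),
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
  validate_truth(truth)
}

#' Validate a synthetic truth against its invariants
#'
#' @param truth A `synthetic_truth` object.
#' @return The truth, invisibly unchanged, or an input error.
#' @export
validate_truth <- function(truth) {
  if (!inherits(truth, "synthetic_truth")) abort_input("not a synthetic_truth")
  if (truth$n_fractions < 2L) abort_input("n_fractions must be >= 2")
  if (truth$noise_cv < 0) abort_input("noise_cv must be >= 0")
  if (truth$dropout_rate < 0 || truth$dropout_rate >= 1) {
    abort_input("dropout_rate must be in [0, 1)")
  }
  n_ent <- length(truth$entities)
  if (n_ent < 1L) abort_input("need at least one entity")
  for (e in truth$entities) {
    if (e$apex_fraction < 1L || e$apex_fraction > truth$n_fractions) {
      abort_input("entity apex_fraction outside [1, n_fractions]")
    }
    if (e$width <= 0) abort_input("entity width must be > 0")
  }
  n_bait <- sum(vapply(truth$subunits, function(s) s$is_bait, logical(1)))
  if (n_bait != 1L) abort_input("exactly one subunit must have is_bait = TRUE")
  ids <- vapply(truth$subunits, function(s) s$protein_id, character(1))
  if (anyDuplicated(ids)) abort_input("duplicate protein_id in truth")
  for (s in truth$subunits) {
    if (length(s$per_entity_ratio) != n_ent) {
      abort_input(sprintf("subunit %s has %d ratios for %d entities",
                          s$protein_id, length(s$per_entity_ratio), n_ent))
    }
  }
  invisible(truth)
}

#' Default two-assembly ground truth
#'
#' The stated world of the simulator: 48 fractions; two partially overlapping
#' bait peaks with apexes at fractions 29 and 33 (both inside the regression
#' window 26--36), widths 0.8 fractions, entity II carrying 1.15x the bait
#' amount of entity I; seven flat-ratio core subunits; three subunits 2x
#' enriched in the high-mass entity II; one entity-I-only partner, two
#' entity-II-only partners, one both-entity partner; six flagged
#' contaminants. Gene names follow the NuRD nomenclature the design emulates
#' (bait MTA2; core MTA1/3, HDAC1/2, MBD3, RBBP4/7; entity-II-enriched CHD4,
#' GATAD2A/B; partners SUZ12, SALL4, CDK2AP1, WDR5) so demo output reads like
#' a real complexome run.
#'
#' @param seed Integer seed for [simulate_table()].
#' @param noise_cv,dropout_rate,replicate_shift Override the default noise
#'   model (CV 0.1, dropout 0.1, shift 1).
#' @return A `synthetic_truth`.
#' @export
default_truth <- function(seed = 42L, noise_cv = 0.1, dropout_rate = 0.1,
                          replicate_shift = 1L) {
  entities <- list(
    entity_spec("I", 29L, 0.8, 1.0),
    entity_spec("II", 33L, 0.8, 1.15)
  )
  su <- function(id, gene, r, ...) subunit_spec(id, gene, r, ...)
  subunits <- list(
    su("P_MTA2", "MTA2", c(1, 1), is_bait = TRUE, role = "bait"),
    # flat-ratio core subunits (equal contribution to both assemblies)
    su("P_MTA1", "MTA1", c(0.5, 0.5), role = "core"),
    su("P_MTA3", "MTA3", c(0.4, 0.4), role = "core"),
    su("P_HDAC1", "HDAC1", c(0.8, 0.8), role = "core"),
    su("P_HDAC2", "HDAC2", c(0.7, 0.7), role = "core"),
    su("P_MBD3", "MBD3", c(0.6, 0.6), role = "core"),
    su("P_RBBP4", "RBBP4", c(1.2, 1.2), role = "core"),
    su("P_RBBP7", "RBBP7", c(0.9, 0.9), role = "core"),
    # 2x enriched in the high-mass entity II
    su("P_CHD4", "CHD4", c(0.4, 0.8), role = "enriched"),
    su("P_GATAD2A", "GATAD2A", c(0.3, 0.6), role = "enriched"),
    su("P_GATAD2B", "GATAD2B", c(0.25, 0.5), role = "enriched"),
    # partners confined to one or both entities
    su("P_SUZ12", "SUZ12", c(0.5, 0), role = "partner"),
    su("P_SALL4", "SALL4", c(0, 0.5), role = "partner"),
    su("P_CDK2AP1", "CDK2AP1", c(0, 0.3), role = "partner"),
    su("P_WDR5", "WDR5", c(0.6, 0.6), role = "partner"),
    # nonspecific background
    su("P_KRT1", "KRT1", c(0, 0), is_contaminant = TRUE),
    su("P_KRT2", "KRT2", c(0, 0), is_contaminant = TRUE),
    su("P_KRT10", "KRT10", c(0, 0), is_contaminant = TRUE),
    su("P_ALB", "ALB", c(0, 0), is_contaminant = TRUE),
    su("P_TUBB5", "TUBB5", c(0, 0), is_contaminant = TRUE),
    su("P_HSPA8", "HSPA8", c(0, 0), is_contaminant = TRUE)
  )
  synthetic_truth(48L, entities, subunits,
                  noise_cv = noise_cv, dropout_rate = dropout_rate,
                  replicate_shift = replicate_shift, seed = seed)
}

# Gaussian kernel at integer fractions, truncated at gel bounds (a protein
# running off the gel loses mass; the kernel is deliberately not renormalized).
gaussian_kernel <- function(fractions, apex, width) {
  exp(-((fractions - apex)^2) / (2 * width^2))
}

# Noise-free expected intensity matrix (proteins x fractions).
expected_intensities <- function(truth, replicate = 1L) {
  shift <- if (replicate == 2L) truth$replicate_shift else 0L
  f <- seq_len(truth$n_fractions)
  n <- length(truth$subunits)
  m <- matrix(0, nrow = n, ncol = truth$n_fractions)
  for (i in seq_len(n)) {
    s <- truth$subunits[[i]]
    if (s$is_contaminant) next
    for (k in seq_along(truth$entities)) {
      e <- truth$entities[[k]]
      m[i, ] <- m[i, ] + s$per_entity_ratio[k] * e$bait_amount *
        .INTENSITY_SCALE * gaussian_kernel(f, e$apex_fraction + shift, e$width)
    }
  }
  rownames(m) <- vapply(truth$subunits, function(s) s$protein_id, character(1))
  m
}

# Per-protein theoretical peptide counts, drawn deterministically from the
# truth seed (shared across replicates, as for a real protein sequence).
peptide_counts <- function(truth) {
  n <- length(truth$subunits)
  with_seed(truth$seed, sample(8:60, n, replace = TRUE))
}

#' Simulate one replicate quantitation table
#'
#' The expected intensity of each non-contaminant protein in fraction f is
#' `sum_e ratio_e * bait_amount_e * G(f; apex_e + shift, width_e)` with
#' `shift = replicate_shift` for replicate 2 and a Gaussian kernel G
#' evaluated at integer fractions. Multiplicative log-normal noise with the
#' truth's CV is applied per cell, then cells are zeroed independently with
#' probability `dropout_rate`. iBAQ columns are intensities divided by a
#' per-protein theoretical peptide count drawn deterministically from the
#' seed. Contaminant rows get seed-deterministic unstructured (flat-random)
#' intensities and carry the contaminant flag.
#'
#' @param truth A `synthetic_truth`.
#' @param replicate 1 or 2; replicate 2 applies the truth's fraction shift
#'   and independent noise.
#' @return A [quant_table()] with one row per subunit.
#' @export
simulate_table <- function(truth, replicate = 1L) {
  validate_truth(truth)
  if (!is_count(replicate) || !(replicate %in% c(1L, 2L))) {
    abort_input("replicate must be 1 or 2")
  }
  replicate <- as.integer(replicate)
  n <- length(truth$subunits)
  nf <- truth$n_fractions
  m <- expected_intensities(truth, replicate)
  pep <- peptide_counts(truth)
  is_cont <- vapply(truth$subunits, function(s) s$is_contaminant, logical(1))

  rep_seed <- (truth$seed * 7L + replicate) %% .Machine$integer.max
  m <- with_seed(rep_seed, {
    # unstructured contaminant background: per-protein level, cell-wise spread
    if (any(is_cont)) {
      for (i in which(is_cont)) {
        level <- stats::runif(1, 0.002, 0.02) * .INTENSITY_SCALE
        m[i, ] <- level * stats::rlnorm(nf, meanlog = 0, sdlog = 1)
      }
    }
    if (truth$noise_cv > 0) {
      sdlog <- sqrt(log(1 + truth$noise_cv^2))
      noise <- matrix(stats::rlnorm(n * nf, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                      nrow = n)
      m <- m * noise
    }
    if (truth$dropout_rate > 0) {
      keep <- matrix(stats::runif(n * nf) >= truth$dropout_rate, nrow = n)
      m <- m * keep
    }
    m
  })

  ibaq <- m / pep
  quant_table(
    protein_id = vapply(truth$subunits, function(s) s$protein_id, character(1)),
    gene_name = vapply(truth$subunits, function(s) s$gene_name, character(1)),
    intensity = m,
    ibaq = ibaq,
    flag_contaminant = is_cont,
    flag_reverse = rep(FALSE, n),
    flag_only_by_site = rep(FALSE, n)
  )
}

#' Default molecular weight marker ladder
#'
#' Anchor fractions for a NativeMark-style 20 kDa--1.2 MDa unstained protein
#' standard on a 48-fraction bottom-to-top cut, placed so the default bait
#' peaks (fractions 29 and 33) annotate to the 1--1.2 MDa region.
#'
#' @return A data.frame with columns `fraction` and `mass_kda`.
#' @export
default_marker_ladder <- function() {
  data.frame(
    fraction = c(3L, 7L, 11L, 15L, 20L, 25L, 30L, 36L),
    mass_kda = c(20, 66, 146, 242, 480, 720, 1048, 1200)
  )
}

#' Write a complete synthetic fixture to disk
#'
#' Writes both replicate quantitation tables (MaxQuant-style TSV), the truth
#' specification (JSON), a marker-ladder TSV, and per-entity membership gene
#' lists (one symbol per line) for the co-occupancy module.
#'
#' @param truth A `synthetic_truth`.
#' @param directory Output directory (created if absent).
#' @return Named character vector of written paths (the manifest), invisibly.
#' @export
write_fixture <- function(truth, directory) {
  validate_truth(truth)
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) abort_io(sprintf("cannot create directory %s", directory))
  paths <- c(
    replicate1 = file.path(directory, "replicate1_proteinGroups.txt"),
    replicate2 = file.path(directory, "replicate2_proteinGroups.txt"),
    truth = file.path(directory, "truth.json"),
    marker_ladder = file.path(directory, "marker_ladder.tsv"),
    entity_I_genes = file.path(directory, "entity_I_genes.txt"),
    entity_II_genes = file.path(directory, "entity_II_genes.txt")
  )
  write_quant_table(simulate_table(truth, 1L), paths[["replicate1"]])
  write_quant_table(simulate_table(truth, 2L), paths[["replicate2"]])
  write_truth(truth, paths[["truth"]])
  ladder <- default_marker_ladder()
  utils::write.table(ladder, paths[["marker_ladder"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (k in seq_along(truth$entities)) {
    genes <- vapply(
      Filter(function(s) !s$is_contaminant && s$per_entity_ratio[k] > 0, truth$subunits),
      function(s) s$gene_name, character(1)
    )
    writeLines(genes, paths[[paste0("entity_", truth$entities[[k]]$label, "_genes")]])
  }
  invisible(paths)
}

#' Serialize a synthetic truth to JSON
#' @param truth A `synthetic_truth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    n_fractions = truth$n_fractions,
    noise_cv = truth$noise_cv,
    dropout_rate = truth$dropout_rate,
    replicate_shift = truth$replicate_shift,
    seed = truth$seed,
    entities = lapply(truth$entities, function(e) {
      list(label = e$label, apex_fraction = e$apex_fraction,
           width = e$width, bait_amount = e$bait_amount)
    }),
    subunits = lapply(truth$subunits, function(s) {
      list(protein_id = s$protein_id, gene_name = s$gene_name,
           per_entity_ratio = I(s$per_entity_ratio),
           is_bait = s$is_bait, is_contaminant = s$is_contaminant,
           role = s$role)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synthetic truth back from JSON
#' @param path File written by [write_truth()].
#' @return A `synthetic_truth` equal to the one written.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  synthetic_truth(
    n_fractions = obj$n_fractions,
    entities = lapply(obj$entities, function(e) {
      entity_spec(e$label, e$apex_fraction, e$width, e$bait_amount)
    }),
    subunits = lapply(obj$subunits, function(s) {
      subunit_spec(s$protein_id, s$gene_name,
                   as.numeric(unlist(s$per_entity_ratio)),
                   is_bait = s$is_bait, is_contaminant = s$is_contaminant,
                   role = s$role)
    }),
    noise_cv = obj$noise_cv,
    dropout_rate = obj$dropout_rate,
    replicate_shift = obj$replicate_shift,
    seed = obj$seed
  )
}
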