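# End-to-end orchestration: read -> filter -> profiles -> align -> cluster
# -> peaks -> entities -> stoichiometry -> (co-occupancy) -> report.
# Replicates are kept separate and reported per replicate; pooled fits are
# used where the two replicates support one estimate (demo patterns).

#' Build a validated run configuration
#'
#' Defaults mirror the analysis design: 48-fraction gels, regression window
#' fractions 26--36, alpha 0.05, unsmoothed peak detection at prominence
#' 0.25, entity call threshold 0.2, bait co-cluster minimum size 15.
#'
#' @param tables Character vector of 1 or 2 replicate table paths.
#' @param bait_id Bait protein identifier.
#' @param out_dir Output directory for the report bundle.
#' @param controls Optional control-list path (nonspecific binders).
#' @param control_mode `"annotate"` (default: keep and mark control-list
#'   proteins) or `"remove"`.
#' @param marker_ladder Optional marker-ladder TSV path.
#' @param window Regression window `c(first, last)`.
#' @param alpha Trend-classification significance level.
#' @param min_prominence,smooth_window Peak-detection parameters.
#' @param call_threshold Entity call threshold.
#' @param cluster_k Minimum bait co-cluster size for the default cut rule.
#' @param gene_lists Optional list: `proxy` (>= 2 paths intersected into the
#'   complex proxy), `partners` (2 paths), `filter` (optional path).
#' @param seed Seed echoed into the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `run_config` list.
#' @export
run_config <- function(tables, bait_id, out_dir,
                       controls = NULL, control_mode = c("annotate", "remove"),
                       marker_ladder = NULL,
                       window = c(26L, 36L), alpha = 0.05,
                       min_prominence = 0.25, smooth_window = 1L,
                       call_threshold = 0.2, cluster_k = 15L,
                       gene_lists = NULL, seed = 1L) {
  control_mode <- match.arg(control_mode)
  if (length(tables) < 1L) abort_input("need at least one replicate table")
  if (length(tables) > 2L) abort_input("at most two replicates are supported")
  if (alpha <= 0 || alpha >= 1) abort_input("alpha must be in (0, 1)")
  if (window[1] > window[2] || window[1] < 1L) abort_input("invalid window")
  structure(
    list(tables = tables, bait_id = bait_id, out_dir = out_dir,
         controls = controls, control_mode = control_mode,
         marker_ladder = marker_ladder,
         window = as.integer(window), alpha = alpha,
         min_prominence = min_prominence,
         smooth_window = as.integer(smooth_window),
         call_threshold = call_threshold, cluster_k = as.integer(cluster_k),
         gene_lists = gene_lists, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a JSON file
#' @param path JSON file whose fields mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}

stage_log <- function(report, stage, msg) {
  message(sprintf("[bnpcp:%s] %s", stage, msg))
  report$stages[[stage]] <- list(status = "ok", note = msg)
  report
}

#' Run the full pipeline
#'
#' Executes the stages in fixed order; a failed stage is recorded with its
#' error and all downstream stages are skipped. All tabular outputs are
#' deterministic for a given config (no timestamps).
#'
#' @param config A [run_config()].
#' @return A `run_report`: config echo, per-stage status, output manifest,
#'   summary statistics, and the in-memory stage results (`$results`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort_input("expected a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("bnpcp")),
    stages = list(), manifest = character(0), summary = list(),
    results = list()
  )
  out <- function(name) file.path(config$out_dir, name)
  n_rep <- length(config$tables)
  failed <- NULL
  run_stage <- function(stage, fun) {
    if (!is.null(failed)) {
      report$stages[[stage]] <<- list(status = "skipped",
                                      note = paste("after failure in", failed))
      return(invisible(NULL))
    }
    tryCatch(fun(), error = function(e) {
      failed <<- stage
      report$stages[[stage]] <<- list(status = "failed",
                                      note = conditionMessage(e))
      message(sprintf("[bnpcp:%s] FAILED: %s", stage, conditionMessage(e)))
    })
  }

  run_stage("read", function() {
    tabs <- lapply(config$tables, read_quant_table)
    controls <- if (!is.null(config$controls)) read_control_list(config$controls)
    report$results$tables <<- tabs
    report$results$controls <<- controls
    report <<- stage_log(report, "read",
      sprintf("%d replicate(s); %s proteins",
              n_rep, paste(vapply(tabs, n_proteins, integer(1)), collapse = "/")))
  })

  run_stage("filter", function() {
    filtered <- lapply(report$results$tables, filter_quant_table,
                       controls = report$results$controls,
                       annotate_controls = config$control_mode == "annotate")
    report$results$filtered <<- filtered
    report$summary$n_proteins_filtered <<- vapply(filtered, n_proteins, integer(1))
    report <<- stage_log(report, "filter",
      sprintf("%s proteins survive QC/control filtering",
              paste(vapply(filtered, n_proteins, integer(1)), collapse = "/")))
  })

  run_stage("profiles", function() {
    ladder <- if (!is.null(config$marker_ladder)) read_marker_ladder(config$marker_ladder)
    profs <- lapply(report$results$filtered, build_profiles)
    for (r in seq_len(n_rep)) {
      p <- out(sprintf("profiles_rep%d.tsv", r))
      write_profiles(profs[[r]], p, ladder = ladder)
      report$manifest[sprintf("profiles_rep%d", r)] <<- p
    }
    report$results$profiles <<- profs
    report$results$ladder <<- ladder
    report <<- stage_log(report, "profiles", sprintf("%d profile set(s) built", n_rep))
  })

  run_stage("align", function() {
    if (n_rep == 2L) {
      al <- align_replicates(report$results$profiles[[1]],
                             report$results$profiles[[2]], config$bait_id,
                             method = "profile")
      report$results$offset <<- al$offset
      report$results$aligned_b <<- al$aligned_b
      report$summary$replicate_offset <<- al$offset
      report <<- stage_log(report, "align",
                           sprintf("replicate 2 aligned with offset %+d", al$offset))
    } else {
      report$results$offset <<- 0L
      report <<- stage_log(report, "align", "single replicate; nothing to align")
    }
  })

  run_stage("cluster", function() {
    trees <- list(); rois <- list()
    for (r in seq_len(n_rep)) {
      dm <- manhattan_matrix(report$results$profiles[[r]])
      tree <- average_linkage(dm)
      roi <- bait_region_of_interest(tree, config$bait_id, k = config$cluster_k)
      mp <- out(sprintf("merges_rep%d.tsv", r))
      write_merge_table(tree, mp)
      report$manifest[sprintf("merges_rep%d", r)] <<- mp
      np <- out(sprintf("dendrogram_rep%d.nwk", r))
      write_newick(tree, np)
      report$manifest[sprintf("dendrogram_rep%d", r)] <<- np
      trees[[r]] <- tree; rois[[r]] <- roi
    }
    report$results$trees <<- trees
    report$results$bait_clusters <<- rois
    report$summary$bait_cluster_size <<- length(rois[[1]]$members)
    report <<- stage_log(report, "cluster",
      sprintf("bait co-cluster: %d members at height %.4g",
              length(rois[[1]]$members), rois[[1]]$height))
  })

  run_stage("peaks", function() {
    calib <- if (!is.null(report$results$ladder)) calibrate_mw(report$results$ladder)
    regions <- lapply(seq_len(n_rep), function(r) {
      detect_peaks(profile_of(report$results$profiles[[r]], config$bait_id),
                   min_prominence = config$min_prominence,
                   smooth_window = config$smooth_window,
                   calibration = calib)
    })
    for (r in seq_len(n_rep)) {
      p <- out(sprintf("entities_rep%d.tsv", r))
      utils::write.table(regions[[r]], p, sep = "\t", quote = FALSE, row.names = FALSE)
      report$manifest[sprintf("entities_rep%d", r)] <<- p
    }
    report$results$regions <<- regions
    report$summary$n_entities <<- nrow(regions[[1]])
    report <<- stage_log(report, "peaks",
      sprintf("%d bait peak(s) in replicate 1", nrow(regions[[1]])))
  })

  run_stage("entities", function() {
    memberships <- lapply(seq_len(n_rep), function(r) {
      entity_assignments(report$results$profiles[[r]],
                         report$results$regions[[r]],
                         call_threshold = config$call_threshold)
    })
    report$results$memberships <<- memberships
    report <<- stage_log(report, "entities",
      sprintf("%d proteins assigned", nrow(memberships[[1]])))
  })

  run_stage("stoichiometry", function() {
    offset <- report$results$offset %||% 0L
    slopes <- lapply(seq_len(n_rep), function(r) {
      w <- if (r == 2L) config$window - offset else config$window
      nf <- report$results$filtered[[r]]$n_fractions
      w <- pmax(1L, pmin(nf, w))
      slope_table(report$results$filtered[[r]], config$bait_id,
                  window = w, alpha = config$alpha, bh = TRUE,
                  drop_zeros = TRUE)
    })
    for (r in seq_len(n_rep)) {
      rep_out <- entity_report(report$results$memberships[[r]], slopes[[r]],
                               report$results$bait_clusters[[r]]$members)
      p <- out(sprintf("entity_report_rep%d.tsv", r))
      utils::write.table(rep_out, p, sep = "\t", quote = FALSE, row.names = FALSE)
      report$manifest[sprintf("entity_report_rep%d", r)] <<- p
      sp <- out(sprintf("slopes_rep%d.tsv", r))
      utils::write.table(slopes[[r]], sp, sep = "\t", quote = FALSE, row.names = FALSE)
      report$manifest[sprintf("slopes_rep%d", r)] <<- sp
    }
    report$results$slopes <<- slopes
    tr <- table(slopes[[1]]$trend)
    report$summary$trend_counts <<- as.list(tr)
    report <<- stage_log(report, "stoichiometry",
      paste(names(tr), unname(tr), sep = "=", collapse = ", "))
  })

  run_stage("cooccupancy", function() {
    gl <- config$gene_lists
    if (is.null(gl)) {
      report <<- stage_log(report, "cooccupancy", "no gene lists; section omitted")
      return(invisible(NULL))
    }
    proxies <- lapply(gl$proxy, read_gene_set)
    proxy <- if (length(proxies) >= 2L) proxy_set(proxies, "complex_proxy")
             else proxies[[1]]
    b <- read_gene_set(gl$partners[[1]])
    c_ <- read_gene_set(gl$partners[[2]])
    part <- venn3(proxy, b, c_)
    vp <- out("venn3.tsv")
    write_venn3(part, vp)
    report$manifest["venn3"] <<- vp
    summ <- list(
      proxy_size = length(proxy$genes),
      overlap_with_B = overlap_percent(proxy, b),
      overlap_with_C = overlap_percent(proxy, c_),
      shared_fraction_of_partners =
        tryCatch(shared_fraction_of_partners(part),
                 bnpcp_error = function(e) NA_integer_)
    )
    if (!is.null(gl$filter)) {
      filt <- read_gene_set(gl$filter)
      pooled <- partition_genes(part, c("AB", "AC", "ABC"), "partner_bound")
      if (length(pooled$genes) > 0L) {
        chain <- partition_filter_chain(pooled, filt)
        summ$chain_percent_retained <- chain$percent_retained
      }
    }
    report$results$venn <<- part
    report$summary$cooccupancy <<- summ
    report <<- stage_log(report, "cooccupancy", "overlap statistics computed")
  })

  run_stage("report", function() {
    rp <- out("report.json")
    payload <- list(
      config = lapply(report$config, function(x) x),
      package_version = report$package_version,
      stages = report$stages,
      manifest = as.list(report$manifest),
      summary = report$summary
    )
    jsonlite::write_json(payload, rp, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    report$manifest["report"] <<- rp
    report <<- stage_log(report, "report", sprintf("written to %s", rp))
  })

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-14s %s  %s\n", s, x$stages[[s]]$status, x$stages[[s]]$note))
  }
  invisible(x)
}

# Replicate-aligned ratio series (replicate 2 mapped into replicate-1
# fraction coordinates) and pooled/per-replicate log-ratio fits for the
# demo pattern checks. Log ratios make the errors exactly normal under
# multiplicative noise, so the flat-subunit p-values are calibrated.
demo_trend_fits <- function(tables, bait_id, protein_id, window, offset) {
  s1 <- ratio_series(tables[[1]], protein_id, bait_id, window)
  if (length(tables) == 1L) {
    f <- fit_slope(s1, 0.5, log_ratios = TRUE)
    return(list(pooled = f, per_rep = list(f)))
  }
  w2 <- pmax(1L, pmin(tables[[2]]$n_fractions, window - offset))
  s2 <- ratio_series(tables[[2]], protein_id, bait_id, w2)
  s2$fractions <- s2$fractions + offset
  f1 <- fit_slope(s1, 0.5, log_ratios = TRUE)
  f2 <- fit_slope(s2, 0.5, log_ratios = TRUE)
  list(pooled = fit_slope(pool_series(list(s1, s2)), 0.5, log_ratios = TRUE),
       per_rep = list(f1, f2))
}

#' Generate, run, and qualitatively check the default synthetic complexome
#'
#' Writes the default two-assembly fixture for the given seed, runs the
#' full pipeline on it, and evaluates six qualitative pattern assertions
#' that mirror the biology the simulator encodes: (1) the bait profile is
#' bimodal; (2) the SALL4-like partner is called in entity II only; (3) the
#' SUZ12-like partner in entity I only; (4) the WDR5-like partner in both;
#' (5) the three entity-II-enriched subunits (CHD4-like) have ascending
#' bait-ratio trends; (6) all core subunits are flat. Entity patterns
#' (1-4) are evaluated on the aligned replicate-consensus profile (the mean
#' of replicate 1 and the shifted replicate 2): a fraction missing in one
#' replicate is covered by the other, which is the point of replication.
#' Trend patterns (5, 6) are judged on median-centered log-ratio fits
#' (pooled and per replicate; see the source comments for the exact rule):
#' the bait is the shared denominator of every ratio, so its noise tilts
#' all slopes coherently and is removed by centering, and a flat claim is
#' only overturned by a signal that replicates at stringent thresholds --
#' the compound assertion spans ten proteins per run, so per-call error
#' rates near the conventional 0.05 would make the joint check fail
#' routinely on truly flat inputs. Failures are reported per pattern in
#' `$demo_patterns`, not raised.
#'
#' @param seed Integer seed for the synthetic truth.
#' @param dir Working directory for fixture and outputs (default: under
#'   `tempdir()`).
#' @return The `run_report`, with `$demo_patterns` (named logicals) and
#'   `$demo_details`.
#' @export
demo_run <- function(seed = 1L, dir = file.path(tempdir(), paste0("bnpcp_demo_", seed))) {
  truth <- default_truth(seed = seed)
  fx <- write_fixture(truth, dir)
  config <- run_config(
    tables = c(fx[["replicate1"]], fx[["replicate2"]]),
    bait_id = "P_MTA2",
    out_dir = file.path(dir, "out"),
    marker_ladder = fx[["marker_ladder"]],
    gene_lists = list(
      proxy = list(fx[["entity_I_genes"]], fx[["entity_II_genes"]]),
      partners = list(fx[["entity_I_genes"]], fx[["entity_II_genes"]]),
      filter = fx[["entity_II_genes"]]
    ),
    seed = seed
  )
  report <- run_pipeline(config)

  patterns <- c(bait_bimodal = NA, sall4_entity_II_only = NA,
                suz12_entity_I_only = NA, wdr5_both_entities = NA,
                chd4_like_ascending = NA, core_subunits_flat = NA)
  details <- list()
  res <- report$results
  ok <- all(vapply(report$stages, function(s) s$status == "ok", logical(1)))
  if (ok) {
    # replicate-consensus profiles: mean of replicate 1 and aligned replicate 2
    cons <- res$profiles[[1]]
    cons$values <- (cons$values + res$aligned_b$values) / 2
    cons_regions <- detect_peaks(profile_of(cons, config$bait_id),
                                 min_prominence = config$min_prominence,
                                 smooth_window = config$smooth_window)
    patterns["bait_bimodal"] <- nrow(cons_regions) == 2L
    details$consensus_regions <- cons_regions

    if (patterns["bait_bimodal"]) {
      m <- entity_assignments(cons, cons_regions,
                              call_threshold = config$call_threshold)
      g <- function(id, label) isTRUE(m[[paste0("call_", label)]][m$protein_id == id])
      patterns["sall4_entity_II_only"] <- g("P_SALL4", "II") && !g("P_SALL4", "I")
      patterns["suz12_entity_I_only"] <- g("P_SUZ12", "I") && !g("P_SUZ12", "II")
      patterns["wdr5_both_entities"] <- g("P_WDR5", "I") && g("P_WDR5", "II")
    } else {
      patterns[c("sall4_entity_II_only", "suz12_entity_I_only",
                 "wdr5_both_entities")] <- FALSE
    }

    # Trend rule on pooled log-ratio fits. Because the bait is the shared
    # denominator of every ratio, its per-fraction noise tilts all slopes
    # coherently; every slope (pooled and per replicate) is therefore
    # centered on the median slope of the assessed subunits (robust to the
    # enriched minority) before testing. "Ascending" demands centered
    # pooled p < 0.01 with a positive centered slope in every replicate.
    # A flat claim is only overturned by a replicated signal: centered
    # pooled p < 0.001 and per-replicate centered p < 0.05 with agreeing
    # sign in every replicate. The band in between contradicts neither
    # pattern: the compound assertion spans ten subunits, so per-call
    # error rates near the conventional 0.05 would fail routinely on
    # truly flat inputs.
    ids <- c("P_CHD4", "P_GATAD2A", "P_GATAD2B", "P_MTA1", "P_MTA3",
             "P_HDAC1", "P_HDAC2", "P_MBD3", "P_RBBP4", "P_RBBP7")
    fits <- lapply(ids, function(id) demo_trend_fits(res$filtered, config$bait_id,
                                                     id, config$window, res$offset))
    names(fits) <- ids
    center <- function(f, med) {
      t_c <- (f$slope - med) / f$stderr_slope
      list(slope = f$slope - med,
           p = 2 * stats::pt(abs(t_c), df = f$n_used - 2L, lower.tail = FALSE))
    }
    med_pooled <- stats::median(vapply(fits, function(f) f$pooled$slope, numeric(1)))
    n_rep_fits <- length(fits[[1]]$per_rep)
    med_rep <- vapply(seq_len(n_rep_fits), function(r) {
      stats::median(vapply(fits, function(f) f$per_rep[[r]]$slope, numeric(1)))
    }, numeric(1))
    centered <- lapply(fits, function(f) {
      list(pooled = center(f$pooled, med_pooled),
           per_rep = lapply(seq_len(n_rep_fits),
                            function(r) center(f$per_rep[[r]], med_rep[r])))
    })
    rep_slopes <- function(f) vapply(f$per_rep, `[[`, numeric(1), "slope")
    rep_ps <- function(f) vapply(f$per_rep, `[[`, numeric(1), "p")
    ascending <- function(f) {
      f$pooled$p < 0.01 && f$pooled$slope > 0 && all(rep_slopes(f) > 0)
    }
    confidently_non_flat <- function(f) {
      f$pooled$p < 0.001 && all(rep_ps(f) < 0.05) &&
        length(unique(sign(c(f$pooled$slope, rep_slopes(f))))) == 1L
    }
    enriched <- c("P_CHD4", "P_GATAD2A", "P_GATAD2B")
    core <- setdiff(ids, enriched)
    patterns["chd4_like_ascending"] <- all(vapply(centered[enriched], ascending, logical(1)))
    patterns["core_subunits_flat"] <- !any(vapply(centered[core], confidently_non_flat, logical(1)))
    details$centered_trend_p <- vapply(centered, function(f) f$pooled$p, numeric(1))
    details$centered_trend_slope <- vapply(centered, function(f) f$pooled$slope, numeric(1))
  } else {
    patterns[] <- FALSE
    details$failure <- "a pipeline stage failed"
  }
  report$demo_patterns <- patterns
  report$demo_details <- details
  report
}

#' Command-line interface
#'
#' Subcommands: `simulate --seed S --out DIR` (write the default synthetic
#' fixture), `demo --seed S [--out DIR]` (run [demo_run()]), `run --config
#' FILE` (run a JSON config through [run_pipeline()]).
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
bnpcp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: bnpcp <simulate|demo|run> [--seed S] [--out DIR] [--config FILE]"
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  status <- 0L
  if (cmd == "simulate") {
    dir <- opt("--out", "bnpcp_fixture")
    paths <- write_fixture(default_truth(seed = seed), dir)
    message(paste("wrote:", paths, collapse = "\n"))
  } else if (cmd == "demo") {
    dir <- opt("--out", file.path(tempdir(), paste0("bnpcp_demo_", seed)))
    report <- demo_run(seed = seed, dir = dir)
    print(report)
    print(report$demo_patterns)
    status <- if (all(report$demo_patterns)) 0L else 1L
  } else if (cmd == "run") {
    cfg <- opt("--config")
    if (is.null(cfg)) { message(usage); return(invisible(1L)) }
    report <- run_pipeline(read_run_config(cfg))
    print(report)
    status <- if (all(vapply(report$stages, function(s) s$status != "failed",
                             logical(1)))) 0L else 1L
  } else {
    message(usage)
    status <- 1L
  }
  invisible(status)
}
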