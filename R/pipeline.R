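#' Default analysis thresholds
#'
#' All tunable thresholds of the pipeline with their default values: the
#' artifact VAF floor (0.12), the subclonal fit window ([0.12, 0.24]), the
#' neutrality R-squared cutoff (0.98), the clonality cellular-frequency
#' cutoff (0.5), the initial and stringent somatic-score floors (10, 15),
#' the read-support minimum (3), the callable exome size (30 Mb), the
#' copy-number event deltas (0.1), pair-classification tolerances
#' (tau_flat 0.01, tau_u 0.10) and the bin size (1 Mb). Any of them can be
#' overridden from the `thresholds` block of a pipeline config.
#'
#' @return Named list of thresholds.
#' @export
defaultThresholds <- function() {
  list(vaf_floor = 0.12, window = c(0.12, 0.24), r2_neutral = 0.98,
       cell_fraction = 0.5, score_initial = 10, score_stringent = 15,
       min_reads = 3L, exome_size = 3e7, n_min = 10L,
       gain_delta = 0.1, loss_delta = 0.1, tau_flat = 0.01, tau_u = 0.10,
       bin_size = 1e6, alpha = 0.05)
}

#' Read and validate a pipeline configuration
#'
#' The config is a single YAML file (or an equivalent list) with blocks
#' `seed`, `outdir`, optional `thresholds` overrides, and either
#' `simulate` (keys `n_pairs`, `classes`, and any [simulationConfig()]
#' argument) or `inputs` (keys `seg`, `purity`, `metadata`, `mutations`
#' dir, optional `genelists`).
#'
#' @param config Path to a YAML file or a list.
#' @return Validated config list with thresholds merged over defaults.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  thr <- defaultThresholds()
  over <- config$thresholds
  for (k in names(over)) {
    if (!k %in% names(thr)) stop("unknown threshold key: ", k)
    thr[[k]] <- if (length(over[[k]]) > 1L) unlist(over[[k]])
                else over[[k]]
  }
  config$thresholds <- thr
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs a 'simulate' or an 'inputs' block")
  if (!is.null(config$inputs)) {
    need <- c("seg", "purity", "metadata", "mutations")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop("config inputs missing: ", paste(miss, collapse = ", "))
    for (k in c("seg", "purity", "metadata")) {
      if (!file.exists(config$inputs[[k]]))
        stop("config input '", k, "' does not exist: ", config$inputs[[k]])
    }
  }
  config
}

#' @keywords internal
simConfigsFromBlock <- function(block, seed) {
  nPairs <- if (is.null(block$n_pairs)) 8L else as.integer(block$n_pairs)
  classes <- if (is.null(block$classes)) 1:4 else unlist(block$classes)
  classes <- rep_len(as.integer(classes), nPairs)
  args <- block[setdiff(names(block), c("n_pairs", "classes"))]
  lapply(seq_len(nPairs), function(i) {
    a <- args
    a$cnClass <- classes[i]
    a$seed <- as.integer(seed + i)
    a$grade <- if (i %% 2L == 0L) "HGD" else "LGD"
    a$adjacency <- if (i %% 3L == 0L) "different_block" else "same_block"
    do.call(simulationConfig, a)
  })
}

#' @keywords internal
lesionVafs <- function(tab, lesion, minReads = 3L) {
  alt <- tab[[paste0(lesion, "_alt")]]
  depth <- tab[[paste0(lesion, "_depth")]]
  v <- alt[alt >= minReads] / depth[alt >= minReads]
  v[is.finite(v)]
}

#' Run the full pipeline
#'
#' Chains the stages -- simulate (or load), copy number, mutation
#' filtering, neutrality, cohort statistics -- and writes each stage's
#' TSV outputs plus a JSON run manifest under `outdir`. Deterministic
#' given the config and seed: re-running produces byte-identical files.
#' Any stage failure aborts with the stage name and cause.
#'
#' @param config Path to a YAML config or a list (see
#'   [readPipelineConfig()]).
#' @param seed Optional override of the config seed.
#' @param outdir Optional override of the config output directory.
#' @param stages Subset of `c("cn", "filter", "neutrality", "cohort")` to
#'   run after the input stage (default all).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
runPipeline <- function(config, seed = NULL, outdir = NULL,
                        stages = c("cn", "filter", "neutrality", "cohort"),
                        quiet = FALSE) {
  cfg <- readPipelineConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$outdir)) stop("config needs an 'outdir'")
  thr <- cfg$thresholds
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[clonalPair] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  pairs <- stage("input", {
    if (!is.null(cfg$simulate)) {
      say("simulating cohort (seed ", cfg$seed, ")")
      simDir <- file.path(cfg$outdir, "simulated")
      simulateCohort(simConfigsFromBlock(cfg$simulate, cfg$seed), simDir)
      loadCohort(file.path(simDir, "metadata.tsv"),
                 file.path(simDir, "segments.tsv"),
                 file.path(simDir, "purity.tsv"), simDir)
    } else {
      say("loading cohort from ", cfg$inputs$metadata)
      loadCohort(cfg$inputs$metadata, cfg$inputs$seg, cfg$inputs$purity,
                 cfg$inputs$mutations)
    }
  })
  results <- list(pairs = pairs)

  tracks <- NULL
  if ("cn" %in% stages) results$cn <- stage("cn", {
    say("copy-number stage: ", length(pairs), " pairs")
    tracks <- list()
    groupOf <- character()
    for (p in pairs) {
      for (role in c("dys", "scc")) {
        prof <- if (role == "dys") dysProfile(p) else sccProfile(p)
        if (is.null(prof)) next
        tr <- callEvents(prof, thr$gain_delta, thr$loss_delta, thr$bin_size)
        tracks[[sampleId(prof)]] <- tr
        groupOf[sampleId(prof)] <-
          if (role == "scc") "SCC" else pairGrade(p)
      }
    }
    fga <- vapply(tracks, fractionGenomeAltered, 0)
    writeTsv(data.frame(sample = names(tracks),
                        group = groupOf[names(tracks)],
                        fga = round(fga, 6)),
             file.path(cfg$outdir, "fga.tsv"))
    for (g in unique(groupOf)) {
      sel <- tracks[names(groupOf)[groupOf == g]]
      cf <- cohortFrequency(sel)
      writeTsv(cf$freq, file.path(cfg$outdir, paste0("freq_", g, ".tsv")))
    }
    classes <- vapply(pairs, function(p)
      classifyPair(tracks[[dysplasiaId(p)]], tracks[[sccId(p)]],
                   thr$tau_flat, thr$tau_u), 0L)
    names(classes) <- vapply(pairs, patientId, "")
    writeTsv(data.frame(patient = names(classes), class = classes),
             file.path(cfg$outdir, "classes.tsv"))
    # per-region frequencies against rates expected from each group's FGA
    cat <- cnEventCatalogue()
    groups <- sort(unique(groupOf))
    sizes <- vapply(groups, function(g) sum(groupOf == g), 0L)
    rates <- vapply(groups, function(g) mean(fga[groupOf == g]), 0)
    rates <- pmin(pmax(rates, 1e-6), 1)
    er <- ExpectedRates(groups, rates, sizes)
    regionRows <- lapply(seq_along(cat), function(i) {
      lab <- paste0(S4Vectors::mcols(cat)$region[i], "_",
                    S4Vectors::mcols(cat)$direction[i])
      hits <- vapply(names(tracks), function(s)
        lab %in% regionsHit(tracks[[s]], cat[i]), TRUE)
      o <- vapply(groups, function(g) sum(hits[groupOf == g]), 0L)
      row <- data.frame(region = lab)
      row[paste0("freq_", groups)] <- as.list(round(o / sizes, 4))
      if (sum(o) > 0) {
        t <- expectedFrequencyTest(o, er)
        row$chi2 <- round(t$chi2, 4); row$p <- round(t$p, 4)
      } else {
        row$chi2 <- NA_real_; row$p <- NA_real_
      }
      row
    })
    tab1 <- do.call(rbind, regionRows)
    tab1$significant_after_bonferroni <-
      !is.na(tab1$p) & tab1$p < bonferroniThreshold(thr$alpha, length(cat))
    writeTsv(tab1, file.path(cfg$outdir, "table1.tsv"))
    list(tracks = tracks, fga = fga, groupOf = groupOf, classes = classes,
         table1 = tab1)
  })

  filtered <- NULL
  if ("filter" %in% stages) results$filter <- stage("filter", {
    say("mutation filter stage")
    filtered <- list()
    rows <- list(); counts <- list()
    for (p in pairs) {
      if (is.null(mutations(p))) next
      pid <- patientId(p)
      raw <- mutations(p)
      init <- initialFilter(raw, thr$score_initial, thr$min_reads)
      str <- stringentFilter(
        LesionPair(pid, dysplasiaId(p), sccId(p), pairGrade(p),
                   pairAdjacency(p), init, dysProfile(p), sccProfile(p)),
        thr$cell_fraction, thr$score_stringent)
      part <- partitionShared(str, thr$min_reads)
      filtered[[pid]] <- list(raw = raw, initial = init, stringent = str,
                               partitioned = part)
      counts[[pid]] <- c(nrow(raw), nrow(part),
                         sum(part$partition == "shared"))
      if (nrow(part))
        rows[[pid]] <- cbind(patient = pid,
                             part[, c("chrom", "pos", "ref", "alt",
                                      "dys_vaf", "scc_vaf", "somatic_score",
                                      "dys_pass", "scc_pass", "partition",
                                      "gene")])
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(patient = character())
    out$dys_vaf <- round(out$dys_vaf, 4); out$scc_vaf <- round(out$scc_vaf, 4)
    writeTsv(out, file.path(cfg$outdir, "filtered.tsv"))
    # curated gene lists
    listPaths <- cfg$inputs$genelists
    if (is.null(listPaths))
      listPaths <- system.file("extdata", "genelists",
                               "cancer_genes_fixture_synthetic.txt",
                               package = "clonalPair")
    gsRows <- list()
    for (lp in listPaths) {
      curated <- readGeneList(lp)
      for (pid in names(filtered)) {
        tl <- genesetTally(filtered[[pid]]$partitioned, curated)
        gsRows[[paste(lp, pid)]] <- data.frame(
          list = basename(lp), patient = pid,
          dys_only = tl$counts[["dys_only"]],
          shared = tl$counts[["shared"]],
          scc_only = tl$counts[["scc_only"]])
      }
    }
    writeTsv(do.call(rbind, gsRows), file.path(cfg$outdir, "genesets.tsv"))
    list(perPatient = filtered, counts = counts)
  })

  fits <- NULL
  if ("neutrality" %in% stages) results$neutrality <- stage("neutrality", {
    say("neutrality stage")
    fits <- list()
    rows <- list(); typeRows <- list()
    for (p in pairs) {
      if (is.null(mutations(p))) next
      pid <- patientId(p)
      tab <- if (!is.null(filtered[[pid]])) filtered[[pid]]$initial
             else initialFilter(mutations(p), thr$score_initial,
                                thr$min_reads)
      for (lesion in c("dys", "scc")) {
        v <- lesionVafs(tab, lesion, thr$min_reads)
        fit <- fitNeutrality(v, thr$window, thr$exome_size, thr$n_min,
                             thr$r2_neutral)
        sid <- if (lesion == "dys") dysplasiaId(p) else sccId(p)
        fits[[pid]][[lesion]] <- fit
        rows[[sid]] <- data.frame(
          patient = pid, sample = sid, lesion = lesion,
          n_window = fit@nWindow, slope = round(fit@slope, 4),
          intercept = round(fit@intercept, 4),
          r2 = round(fit@rSquared, 5), neutral = fit@neutral,
          mu_eff = signif(fit@muEff, 6), status = fit@status,
          fit_model = "ols_with_intercept")
        keep <- tab[[paste0(lesion, "_alt")]] >= thr$min_reads
        sub <- data.frame(
          vaf = tab[[paste0(lesion, "_alt")]][keep] /
            tab[[paste0(lesion, "_depth")]][keep],
          substitution_class = tab$substitution_class[keep])
        tr <- perTypeRates(sub, "vaf", thr$window, thr$exome_size,
                           thr$n_min)
        tr <- cbind(patient = pid, sample = sid, tr)
        tr$slope <- round(tr$slope, 4); tr$r_squared <- round(tr$r_squared, 5)
        tr$mu_eff <- signif(tr$mu_eff, 6)
        typeRows[[sid]] <- tr
      }
    }
    writeTsv(do.call(rbind, rows), file.path(cfg$outdir, "neutrality.tsv"))
    writeTsv(do.call(rbind, typeRows),
             file.path(cfg$outdir, "rates_by_type.tsv"))
    list(fits = fits)
  })

  if ("cohort" %in% stages) results$cohort <- stage("cohort", {
    say("cohort stage")
    vafRows <- list(); callSets <- list(); patientsOf <- character()
    for (p in pairs) {
      if (is.null(mutations(p))) next
      pid <- patientId(p)
      tab <- if (!is.null(filtered[[pid]])) filtered[[pid]]$initial
             else initialFilter(mutations(p), thr$score_initial,
                                thr$min_reads)
      shared <- tab$dys_alt >= thr$min_reads & tab$scc_alt >= thr$min_reads
      for (lesion in c("dys", "scc")) {
        present <- tab[[paste0(lesion, "_alt")]] >= thr$min_reads
        v <- tab[[paste0(lesion, "_alt")]][present] /
          tab[[paste0(lesion, "_depth")]][present]
        vs <- tab[[paste0(lesion, "_alt")]][present & shared] /
          tab[[paste0(lesion, "_depth")]][present & shared]
        for (fl in c(FALSE, TRUE)) {
          cmp <- compareSharedVsAll(v, vs, applyFloor = fl,
                                    floor = thr$vaf_floor)
          sid <- if (lesion == "dys") dysplasiaId(p) else sccId(p)
          vafRows[[paste(sid, fl)]] <- data.frame(
            patient = pid, sample = sid, lesion = lesion,
            floor_applied = fl, n_all = cmp$n_all, n_shared = cmp$n_shared,
            p = signif(cmp$p, 6),
            median_all = round(cmp$median_all, 4),
            median_shared = round(cmp$median_shared, 4),
            direction = cmp$direction)
        }
        sid <- if (lesion == "dys") dysplasiaId(p) else sccId(p)
        present1 <- tab[[paste0(lesion, "_alt")]] >= 1L
        callSets[[sid]] <- data.frame(
          chrom = tab$chrom[present1], pos = tab$pos[present1],
          ref = tab$ref[present1], alt = tab$alt[present1],
          vaf = tab[[paste0(lesion, "_alt")]][present1] /
            tab[[paste0(lesion, "_depth")]][present1])
        patientsOf[sid] <- pid
      }
    }
    writeTsv(do.call(rbind, vafRows),
             file.path(cfg$outdir, "vaf_comparison.tsv"))
    baseline <- if (length(unique(patientsOf)) >= 2L)
      betweenPatientBaseline(callSets, patientsOf) else NULL
    if (!is.null(baseline))
      writeTsv(baseline$binSummary, file.path(cfg$outdir, "baseline.tsv"))
    pids <- vapply(pairs, patientId, "")
    classes <- if (!is.null(results$cn)) results$cn$classes else NULL
    fgaList <- if (!is.null(results$cn)) {
      fl <- lapply(pairs, function(p)
        c(results$cn$fga[[dysplasiaId(p)]], results$cn$fga[[sccId(p)]]))
      names(fl) <- pids; fl
    } else NULL
    mc <- if (!is.null(results$filter)) results$filter$counts else NULL
    neut <- if (!is.null(fits)) {
      nl <- lapply(pids, function(pid)
        if (!is.null(fits[[pid]]))
          classifyPairEvolution(fits[[pid]]$dys, fits[[pid]]$scc)
        else NULL)
      names(nl) <- pids; nl
    } else NULL
    rep <- assembleReport(pids, classes, fgaList, mc, neut,
                          manifest = list(seed = cfg$seed,
                                          thresholds = thr,
                                          stages = stages))
    writeTsv(rep$report, file.path(cfg$outdir, "cohort_report.tsv"))
    jsonlite::write_json(rep$manifest,
                         file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    c(rep, list(baseline = baseline))
  })
  say("done: outputs in ", cfg$outdir)
  invisible(results)
}
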