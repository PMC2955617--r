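# Orchestration: simulate -> preprocess -> kinases -> diff -> enrich ->
# viability from a single validated configuration, with deterministic
# seeding and a provenance manifest.

#' Build a validated run configuration
#'
#' All thresholds default to the study's printed settings: top 100
#' substrates, minimum acquisition signal 1e6, the published dasatinib and
#' TBB dose grids, quadruplicate wells.  When `simulate = TRUE` the inputs
#' are generated by the synthetic module; otherwise `layout_path`,
#' `substrate_path`, `kinase_path`, `pathway_path` and `spot_paths` must
#' point at existing files.
#'
#' @param seed integer master seed; every stage derives its randomness
#'   from it.
#' @param simulate generate synthetic inputs instead of reading files.
#' @param layout_path,substrate_path,kinase_path,pathway_path,spot_paths
#'   input file paths (ignored when `simulate = TRUE`).
#' @param stages character vector of stages to run, in pipeline order.
#' @param min_total_hits,cv_threshold,top_n,exclude_categories,fdr_q,excess_threshold
#'   stage thresholds.
#' @param n_substrates,n_kinases,n_active,n_tumor,n_control,boost,replicate_cv
#'   synthetic-cohort settings.
#' @param viability_n_replicates wells per viability condition.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, simulate = TRUE,
                       layout_path = NULL, substrate_path = NULL,
                       kinase_path = NULL, pathway_path = NULL,
                       spot_paths = NULL,
                       stages = c("simulate", "preprocess", "kinases",
                                  "diff", "enrich", "viability"),
                       min_total_hits = 1e6, cv_threshold = 0.5,
                       top_n = 100, exclude_categories = character(),
                       fdr_q = 0.05, excess_threshold = 0.1,
                       n_substrates = 1024, n_kinases = 120,
                       n_active = 6, n_tumor = 6, n_control = 2,
                       boost = 3, replicate_cv = 0.1,
                       viability_n_replicates = 4) {
  cfg <- list(seed = as.integer(seed), simulate = isTRUE(simulate),
              layout_path = layout_path, substrate_path = substrate_path,
              kinase_path = kinase_path, pathway_path = pathway_path,
              spot_paths = spot_paths, stages = stages,
              min_total_hits = min_total_hits, cv_threshold = cv_threshold,
              top_n = top_n, exclude_categories = exclude_categories,
              fdr_q = fdr_q, excess_threshold = excess_threshold,
              n_substrates = n_substrates, n_kinases = n_kinases,
              n_active = n_active, n_tumor = n_tumor,
              n_control = n_control, boost = boost,
              replicate_cv = replicate_cv,
              viability_n_replicates = viability_n_replicates)
  if (cfg$top_n < 1) stop_ks("top_n must be >= 1")
  if (cfg$fdr_q <= 0 || cfg$fdr_q > 1) stop_ks("fdr_q must lie in (0, 1]")
  if (!cfg$simulate) {
    paths <- c(cfg$layout_path, cfg$substrate_path, cfg$kinase_path,
               cfg$pathway_path, unlist(cfg$spot_paths))
    if (length(paths) == 0) stop_ks("non-simulated run needs input paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop_ks("input file not found: %s", missing[1])
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_ks("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop_ks("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and writes one TSV/CSV/JSON output
#' per stage under `out_dir`, plus a `manifest.json` recording the config
#' hash, seed, package version and per-stage row counts.  Identical config
#' and seed produce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return The manifest (a list), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(packageVersion("kinoscope")),
                   config_hash = hash_config(config),
                   stages = list())
  note <- function(stage, file, rows) {
    manifest$stages[[stage]] <<- list(file = file, rows = rows)
  }
  state <- list()

  if ("simulate" %in% config$stages) {
    if (!config$simulate) stop_ks("simulate stage requested but simulate = FALSE")
    layout <- default_layout(n_substrates = config$n_substrates)
    ann <- with_seed(config$seed, {
      planted <- sample(sprintf("K%03d", seq_len(config$n_kinases)),
                        config$n_active)
      control_set <- sample(setdiff(sprintf("K%03d", seq_len(config$n_kinases)),
                                    planted), config$n_active)
      list(planted = planted, control = control_set)
    })
    anno <- generate_annotation(n_substrates = config$n_substrates,
                                n_kinases = config$n_kinases,
                                seed = config$seed,
                                planted_kinases = ann$planted)
    truth_t <- synthetic_truth(ann$planted, boost = config$boost,
                               replicate_cv = config$replicate_cv,
                               seed = config$seed)
    truth_c <- synthetic_truth(ann$control, boost = config$boost,
                               replicate_cv = config$replicate_cv,
                               seed = config$seed + 1000L)
    cohort <- simulate_cohort(layout, anno$substrates, truth_t, truth_c,
                              n_tumor = config$n_tumor,
                              n_control = config$n_control)
    state$layout <- layout
    state$anno <- anno
    state$cohort <- cohort
    state$truth <- list(tumor = truth_t, control = truth_c)

    write_layout(layout, file.path(out_dir, "layout.tsv"))
    spots_all <- do.call(rbind, lapply(c(cohort$tumor, cohort$control),
                                       function(s) {
                                         cbind(sample_id = s$sample_id,
                                               s$spots)
                                       }))
    write_tsv_file(spots_all, file.path(out_dir, "spots.tsv"))
    jsonlite::write_json(
      list(active_kinases = ann$planted, control_kinases = ann$control,
           boost = config$boost, seed = config$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE)
    note("simulate", "spots.tsv", nrow(spots_all))
  } else if (!config$simulate) {
    state$layout <- load_layout(config$layout_path)
    state$anno <- load_annotations(config$substrate_path, config$kinase_path,
                                   config$pathway_path,
                                   layout = state$layout)
    scans <- lapply(config$spot_paths, function(p) {
      df <- read_tsv_file(p, "spot file")
      array_scan(sub("\\.[^.]*$", "", basename(p)), df, state$layout)
    })
    state$cohort <- list(tumor = scans, control = list())
  }

  if ("preprocess" %in% config$stages) {
    scans <- c(state$cohort$tumor, state$cohort$control)
    pp <- preprocess_scans(scans, state$layout,
                           min_total_hits = config$min_total_hits,
                           cv_threshold = config$cv_threshold)
    state$pp <- pp
    out <- data.frame(substrate_id = rownames(pp$matrix), pp$matrix,
                      check.names = FALSE)
    write_tsv_file(out, file.path(out_dir, "profiles.tsv"))
    note("preprocess", "profiles.tsv", nrow(out))
  }

  n_tumor_kept <- if (!is.null(state$pp)) {
    sum(colnames(state$pp$matrix) %in%
          vapply(state$cohort$tumor, `[[`, character(1), "sample_id"))
  } else 0

  if ("kinases" %in% config$stages) {
    tumor_mat <- state$pp$matrix[, seq_len(n_tumor_kept), drop = FALSE]
    avg <- group_average(tumor_mat)
    top <- select_top_substrates(avg, config$top_n)
    act <- score_kinases(top, avg, state$anno$substrates,
                         kinases = state$anno$kinases)
    act_f <- filter_kinases(act, config$exclude_categories,
                            state$anno$kinases)
    state$avg <- avg
    state$top <- top
    state$activities <- act_f
    write_tsv_file(act_f[, setdiff(names(act_f), "category_list")],
                   file.path(out_dir, "kinase_activity.tsv"))
    note("kinases", "kinase_activity.tsv", nrow(act_f))
  }

  if ("diff" %in% config$stages) {
    mat <- state$pp$matrix
    a <- mat[, seq_len(n_tumor_kept), drop = FALSE]
    b <- mat[, -seq_len(n_tumor_kept), drop = FALSE]
    if (ncol(b) >= 2) {
      dres <- moderated_t(a, b)
      state$diff <- dres
      write_tsv_file(dres, file.path(out_dir, "differential.tsv"))
      note("diff", "differential.tsv", nrow(dres))
    } else {
      message("skipping diff stage: control group has < 2 samples")
    }
  }

  if ("enrich" %in% config$stages) {
    active <- call_active_kinases(state$top, state$avg,
                                  state$anno$substrates, k = 10)
    er <- enrich(active, state$anno$pathways, state$anno$kinases$kinase_id)
    state$enrich <- er
    write_tsv_file(er, file.path(out_dir, "enrichment.tsv"))
    note("enrich", "enrichment.tsv", nrow(er))
  }

  if ("viability" %in% config$stages) {
    grids <- list(dasatinib = default_dose_grid("dasatinib"),
                  tbb = default_dose_grid("tbb"))
    truths <- list(
      dasatinib = preset_viability_truth("dasatinib",
                                         seed = config$seed + 2000L),
      tbb = preset_viability_truth("tbb", seed = config$seed + 3000L))
    fits <- lapply(names(grids), function(d) {
      raw <- simulate_viability(grids[[d]]$doses, truths[[d]],
                                n_replicates = config$viability_n_replicates,
                                drug = d, unit = grids[[d]]$unit)
      fit_4pl(normalize_plate(raw))
    })
    names(fits) <- names(grids)
    fit_tab <- do.call(rbind, lapply(fits, function(f) {
      data.frame(drug = f$drug, lower = f$lower, upper = f$upper,
                 ec50 = f$ec50, hill = f$hill, rss = f$rss,
                 converged = f$converged,
                 ic50 = ifelse(is.na(f$ic50), "not_reached",
                               format(f$ic50, digits = 6)),
                 unit = f$unit, stringsAsFactors = FALSE)
    }))
    write_tsv_file(fit_tab, file.path(out_dir, "viability_fits.tsv"))

    # combination: drug A (dasatinib-like) over its grid with drug B fixed
    # at its IC50-level effect
    combo_truth <- viability_truth(lower = 0.05, upper = 0.5, ec50 = 200,
                                   hill = 1, seed = config$seed + 4000L)
    raw_a <- simulate_viability(grids$dasatinib$doses, truths$dasatinib,
                                n_replicates = config$viability_n_replicates,
                                drug = "dasatinib")
    raw_ab <- simulate_viability(grids$dasatinib$doses, combo_truth,
                                 n_replicates = config$viability_n_replicates,
                                 drug = "dasatinib+tbb")
    comb <- analyze_combination(normalize_plate(raw_a), 0.5,
                                normalize_plate(raw_ab),
                                excess_threshold = config$excess_threshold,
                                schedule = "drug B 30 min before drug A")
    state$combination <- comb
    write_tsv_file(comb$table, file.path(out_dir, "combination.tsv"))
    note("viability", "viability_fits.tsv + combination.tsv",
         nrow(fit_tab) + nrow(comb$table))
    state$fits <- fits
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(c(manifest, list(state = state)),
                      class = "pipeline_result"))
}

# md5 of the canonical YAML rendering of the config
hash_config <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
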