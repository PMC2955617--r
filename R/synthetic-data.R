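# Synthetic chips, annotations, lysate-array scans and viability plates with
# planted ground truth, so every downstream stage has a recovery-testable
# input.

#' Ground truth for a simulated kinome-array experiment
#'
#' Describes the data-generating process for [simulate_arrays()]: a set of
#' truly active kinases whose substrates are boosted above a log-normal
#' spot-intensity background.
#'
#' @param active_kinases character vector of planted active kinase ids.
#' @param boost multiplicative intensity factor (>= 1) applied to substrates
#'   annotated to any active kinase.
#' @param background_log_mean,background_log_sd parameters of the log-normal
#'   background intensity (natural-log scale).
#' @param replicate_cv coefficient of variation of the multiplicative
#'   replicate-to-replicate jitter within a triplicate.
#' @param dropout_rate probability that any given spot is missing from the
#'   scan.
#' @param seed integer seed; the generator is fully deterministic given the
#'   truth object.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(active_kinases, boost = 3,
                            background_log_mean = log(500),
                            background_log_sd = 0.5,
                            replicate_cv = 0.1, dropout_rate = 0.01,
                            seed = 1L) {
  if (boost < 1) stop_ks("boost must be >= 1")
  if (replicate_cv < 0) stop_ks("replicate_cv must be >= 0")
  if (dropout_rate < 0 || dropout_rate > 1) stop_ks("dropout_rate must be in [0,1]")
  if (background_log_sd < 0) stop_ks("background_log_sd must be >= 0")
  structure(list(active_kinases = as.character(active_kinases), boost = boost,
                 background_log_mean = background_log_mean,
                 background_log_sd = background_log_sd,
                 replicate_cv = replicate_cv, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a random substrate/kinase/pathway annotation with known truth
#'
#' Builds a many-to-many substrate->kinase map (each kinase gets
#' `substrates_per_kinase` substrates; a fraction `multi_map_rate` of
#' assignments reuse substrates already claimed by another kinase, so one
#' substrate may report on several kinases), a kinase metadata table in
#' which approximately `cell_cycle_fraction` of kinases are tagged
#' `cell_cycle`, and a pathway catalog of random kinase subsets plus an
#' optional planted pathway covering chosen kinases.
#'
#' @param n_substrates,n_kinases counts; `n_substrates >= n_kinases >= 1`.
#' @param substrates_per_kinase substrates assigned to each kinase.
#' @param multi_map_rate fraction of assignments drawn from substrates
#'   already assigned to another kinase (0 forces a one-to-at-most-one map).
#' @param cell_cycle_fraction fraction of kinases tagged `cell_cycle`.
#' @param seed integer seed.
#' @param n_pathways,pathway_size size of the random pathway catalog.
#' @param planted_kinases optional kinase ids covered exactly by the planted
#'   pathway `"PW_planted"`.
#' @return list with `substrates` ([substrate_annotation()]), `kinases`
#'   ([kinase_table()]) and `pathways` ([pathway_annotation()]).
#' @export
generate_annotation <- function(n_substrates = 1024, n_kinases = 120,
                                substrates_per_kinase = 8,
                                multi_map_rate = 0.2,
                                cell_cycle_fraction = 0.27,
                                seed = 1L,
                                n_pathways = 15, pathway_size = 8,
                                planted_kinases = NULL) {
  if (n_kinases < 1 || n_substrates < n_kinases) {
    stop_ks("need n_substrates >= n_kinases >= 1")
  }
  n_fresh <- ceiling(n_kinases * substrates_per_kinase * (1 - multi_map_rate))
  if (n_fresh > n_substrates) {
    stop_ks("parameter error: %d kinases x %d substrates each is infeasible for %d substrates at multi_map_rate %.2f",
            n_kinases, substrates_per_kinase, n_substrates, multi_map_rate)
  }
  substrate_ids <- sprintf("S%04d", seq_len(n_substrates))
  kinase_ids <- sprintf("K%03d", seq_len(n_kinases))

  with_seed(seed, {
    pool <- sample(substrate_ids)  # unassigned substrates, random order
    assigned <- character(0)
    owner <- list()                # substrate -> kinases already owning it
    rows <- vector("list", n_kinases)
    for (i in seq_len(n_kinases)) {
      k <- kinase_ids[i]
      mine <- character(0)
      for (j in seq_len(substrates_per_kinase)) {
        reuse <- runif(1) < multi_map_rate
        cand <- setdiff(assigned, mine)
        if (reuse && length(cand) > 0) {
          s <- sample(cand, 1)
        } else if (length(pool) > 0) {
          s <- pool[1]; pool <- pool[-1]
          assigned <- c(assigned, s)
        } else if (length(cand) > 0) {
          s <- sample(cand, 1)
        } else {
          stop_ks("parameter error: no substrate available for kinase %s", k)
        }
        mine <- c(mine, s)
      }
      rows[[i]] <- data.frame(substrate_id = mine, kinase_id = k,
                              stringsAsFactors = FALSE)
    }
    sub_df <- do.call(rbind, rows)

    n_cc <- round(cell_cycle_fraction * n_kinases)
    cc <- sample(kinase_ids, n_cc)
    kin_df <- data.frame(
      kinase_id = kinase_ids,
      name = kinase_ids,
      description = paste("synthetic kinase", kinase_ids),
      categories = ifelse(kinase_ids %in% cc, "cell_cycle", ""),
      known_drugs = "",
      stringsAsFactors = FALSE
    )

    pw_rows <- lapply(seq_len(n_pathways), function(p) {
      data.frame(pathway_id = sprintf("PW%02d", p),
                 pathway_name = sprintf("synthetic pathway %02d", p),
                 kinase_id = sample(kinase_ids, min(pathway_size, n_kinases)),
                 stringsAsFactors = FALSE)
    })
    pw_df <- do.call(rbind, pw_rows)
    if (!is.null(planted_kinases)) {
      if (!all(planted_kinases %in% kinase_ids)) {
        stop_ks("planted_kinases must be drawn from the generated kinases")
      }
      pw_df <- rbind(pw_df, data.frame(
        pathway_id = "PW_planted", pathway_name = "planted pathway",
        kinase_id = planted_kinases, stringsAsFactors = FALSE))
    }

    list(substrates = substrate_annotation(sub_df),
         kinases = kinase_table(kin_df),
         pathways = pathway_annotation(pw_df))
  })
}

#' Simulate lysate-array scans under a planted truth
#'
#' For each sample, every substrate draws a log-normal background level;
#' substrates annotated to any active kinase have their expected level
#' multiplied by `truth$boost`.  Replicate spots jitter multiplicatively at
#' `truth$replicate_cv`, spots drop out at `truth$dropout_rate`, positive
#' controls sit at the 99th percentile of the background distribution and
#' negative controls at the 1st.  `total_hits` of each scan is the sum of
#' its emitted spot intensities.
#'
#' @param layout a [chip_layout()].
#' @param annotation a [substrate_annotation()] (active kinases must be a
#'   subset of its kinases).
#' @param truth a [synthetic_truth()].
#' @param n_samples number of arrays to simulate (>= 1).
#' @param condition condition label stored on each scan.
#' @param sample_prefix prefix for generated sample ids.
#' @return list of [array_scan()] objects.
#' @export
simulate_arrays <- function(layout, annotation, truth, n_samples,
                            condition = "normal_medium",
                            sample_prefix = "sample") {
  stopifnot(inherits(layout, "chip_layout"),
            inherits(annotation, "substrate_annotation"),
            inherits(truth, "synthetic_truth"))
  if (n_samples < 1) stop_ks("parameter error: n_samples must be >= 1")
  extra <- setdiff(truth$active_kinases, annotation$kinases)
  if (length(extra) > 0) {
    stop_ks("active kinases absent from annotation: %s",
            paste(extra, collapse = ", "))
  }

  active_subs <- names(annotation$map)[vapply(annotation$map, function(k) {
    any(k %in% truth$active_kinases)
  }, logical(1))]

  spots <- layout$spots
  is_sub <- spots$control_type == "none"
  sub_ids <- unique(spots$substrate_id[is_sub])
  boosted <- sub_ids %in% active_subs
  pos_level <- qlnorm(0.99, truth$background_log_mean, truth$background_log_sd)
  neg_level <- qlnorm(0.01, truth$background_log_mean, truth$background_log_sd)

  with_seed(truth$seed, {
    lapply(seq_len(n_samples), function(i) {
      # substrate-level expected intensity for this sample
      level <- rlnorm(length(sub_ids), truth$background_log_mean,
                      truth$background_log_sd)
      level[boosted] <- level[boosted] * truth$boost
      names(level) <- sub_ids

      base <- numeric(nrow(spots))
      base[is_sub] <- level[spots$substrate_id[is_sub]]
      base[spots$control_type == "positive"] <- pos_level
      base[spots$control_type == "negative"] <- neg_level

      jitter <- 1 + rnorm(nrow(spots), 0, truth$replicate_cv)
      intensity <- pmax(base * jitter, 0)
      keep <- runif(nrow(spots)) >= truth$dropout_rate

      df <- data.frame(
        spot_id = spots$spot_id,
        substrate_id = spots$substrate_id,
        replicate_idx = spots$replicate_idx,
        control_type = spots$control_type,
        raw_intensity = intensity,
        flagged = FALSE,
        stringsAsFactors = FALSE
      )[keep, , drop = FALSE]
      rownames(df) <- NULL
      array_scan(sprintf("%s%02d", sample_prefix, i), df, layout,
                 condition = condition)
    })
  })
}

#' Simulate the default study cohort
#'
#' A cohort shaped like the published design: `n_tumor` tumor-like samples
#' sharing one planted active-kinase set and `n_control` control-like
#' samples simulated under a different planted set, all on the same chip.
#'
#' @param layout,annotation chip layout and substrate annotation.
#' @param truth_tumor,truth_control [synthetic_truth()] objects for the two
#'   groups; their seeds keep the groups independent but reproducible.
#' @param n_tumor,n_control group sizes.
#' @return list with `tumor` and `control` lists of scans.
#' @export
simulate_cohort <- function(layout, annotation, truth_tumor, truth_control,
                            n_tumor = 6, n_control = 2) {
  list(
    tumor = simulate_arrays(layout, annotation, truth_tumor, n_tumor,
                            sample_prefix = "tumor"),
    control = simulate_arrays(layout, annotation, truth_control, n_control,
                              sample_prefix = "control")
  )
}

#' Ground truth for a simulated dose-response experiment
#'
#' Parameters of the four-parameter-logistic viability curve generated by
#' [simulate_viability()].
#'
#' @param lower,upper asymptote viabilities (fraction of vehicle),
#'   `0 <= lower <= upper`.
#' @param ec50 inflection concentration (same unit as the dose grid), > 0.
#' @param hill slope, > 0.
#' @param noise_sd additive viability noise standard deviation.
#' @param seed integer seed.
#' @return Object of class `viability_truth`.
#' @export
viability_truth <- function(lower = 0.25, upper = 1, ec50 = 100, hill = 1,
                            noise_sd = 0.02, seed = 1L) {
  if (lower < 0 || lower > upper) stop_ks("need 0 <= lower <= upper")
  if (ec50 <= 0) stop_ks("ec50 must be > 0")
  if (hill <= 0) stop_ks("hill must be > 0")
  if (noise_sd < 0) stop_ks("noise_sd must be >= 0")
  structure(list(lower = lower, upper = upper, ec50 = ec50, hill = hill,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "viability_truth")
}

#' Drug-shaped viability truth presets
#'
#' Curve shapes mirroring the two study drugs' printed dose-response
#' behaviour.  The TBB-like curve reaches a full response inside its tested
#' grid (viability floor 0.25 attained by the second-highest dose, so an
#' absolute IC50 exists); the dasatinib-like curve plateaus at 60%
#' viability (a maximum decrease of 40%), so its absolute IC50 is never
#' reached.
#'
#' @param drug `"dasatinib"` or `"tbb"`.
#' @param noise_sd,seed passed to [viability_truth()].
#' @return A [viability_truth()].
#' @export
preset_viability_truth <- function(drug = c("dasatinib", "tbb"),
                                   noise_sd = 0.02, seed = 1L) {
  drug <- match.arg(tolower(drug), c("dasatinib", "tbb"))
  switch(drug,
         dasatinib = viability_truth(lower = 0.6, upper = 1, ec50 = 200,
                                     hill = 1.5, noise_sd = noise_sd,
                                     seed = seed),
         tbb = viability_truth(lower = 0.25, upper = 1, ec50 = 100,
                               hill = 2, noise_sd = noise_sd, seed = seed))
}

#' Simulate a plate-reader viability table
#'
#' Emits a long-format raw-absorbance table (columns `drug`, `dose`, `unit`,
#' `replicate`, `absorbance`, `role`) with blank wells, vehicle-control
#' wells (true viability 1) and treated wells whose true viability follows
#' the four-parameter-logistic curve of `truth`; all wells receive additive
#' noise at `truth$noise_sd` on the viability scale, so
#' [normalize_plate()] has real blank/vehicle structure to work on.
#'
#' @param dose_grid positive, strictly increasing concentrations.
#' @param truth a [viability_truth()].
#' @param n_replicates wells per condition (the published assays used
#'   quadruplicate wells).
#' @param drug,unit labels stored in the table.
#' @param blank_absorbance,vehicle_span true blank level and the
#'   absorbance span corresponding to viability 1.
#' @return data.frame in the long plate format accepted by
#'   [normalize_plate()].
#' @export
simulate_viability <- function(dose_grid, truth, n_replicates = 4,
                               drug = "drug", unit = "nM",
                               blank_absorbance = 0.1, vehicle_span = 1.0) {
  if (any(dose_grid <= 0)) stop_ks("parameter error: doses must be positive")
  if (is.unsorted(dose_grid, strictly = TRUE)) {
    stop_ks("parameter error: doses must be strictly increasing")
  }
  if (n_replicates < 1) stop_ks("parameter error: n_replicates must be >= 1")
  stopifnot(inherits(truth, "viability_truth"))

  with_seed(truth$seed, {
    mk <- function(role, dose, true_viab) {
      viab <- true_viab + rnorm(n_replicates, 0, truth$noise_sd)
      data.frame(drug = drug, dose = dose, unit = unit,
                 replicate = seq_len(n_replicates),
                 absorbance = blank_absorbance + vehicle_span * viab,
                 role = role, stringsAsFactors = FALSE)
    }
    blank <- data.frame(drug = drug, dose = NA_real_, unit = unit,
                        replicate = seq_len(n_replicates),
                        absorbance = blank_absorbance +
                          vehicle_span * rnorm(n_replicates, 0, truth$noise_sd),
                        role = "blank", stringsAsFactors = FALSE)
    vehicle <- mk("vehicle", NA_real_, 1)
    treated <- do.call(rbind, lapply(dose_grid, function(d) {
      mk("treated", d, fourpl(d, truth$lower, truth$upper, truth$ec50,
                              truth$hill))
    }))
    rbind(blank, vehicle, treated)
  })
}
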