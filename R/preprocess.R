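# Acquisition QC, replicate QC, background correction, median-of-triplicate
# summarization and cross-array quantile normalization.

#' Construct an array scan
#'
#' One sample's raw spot intensities, validated against a chip layout.
#'
#' @param sample_id sample identifier.
#' @param spots data.frame with columns `spot_id`, `substrate_id`,
#'   `replicate_idx`, `control_type`, `raw_intensity` (>= 0) and optionally
#'   `flagged` (logical, default `FALSE`).  Spots may be missing (dropouts),
#'   but every `spot_id` must exist in the layout.
#' @param layout the [chip_layout()] the scan was acquired on.
#' @param condition condition label (e.g. `"normal_medium"`, `"starved"`).
#' @param metadata optional named list of free-form acquisition metadata.
#' @return Object of class `array_scan`: list with `sample_id`, `condition`,
#'   `spots`, `total_hits` (sum of raw intensities), `metadata`.
#' @export
array_scan <- function(sample_id, spots, layout, condition = "normal_medium",
                       metadata = list()) {
  assert_columns(spots, c("spot_id", "substrate_id", "replicate_idx",
                          "control_type", "raw_intensity"), "scan spot table")
  if (is.null(spots$flagged)) spots$flagged <- FALSE
  if (any(spots$raw_intensity < 0, na.rm = TRUE)) {
    stop_ks("raw intensities must be >= 0")
  }
  unknown <- setdiff(spots$spot_id, layout$spots$spot_id)
  if (length(unknown) > 0) {
    stop_ks("scan contains spot_id(s) absent from layout: %s",
            paste(head(unknown, 5), collapse = ", "))
  }
  structure(list(sample_id = sample_id, condition = condition, spots = spots,
                 total_hits = sum(spots$raw_intensity, na.rm = TRUE),
                 metadata = metadata),
            class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("array_scan '%s' (%s): %d spots, total_hits = %.4g\n",
              x$sample_id, x$condition, nrow(x$spots), x$total_hits))
  invisible(x)
}

#' Acquisition quality control
#'
#' An array passes acquisition QC when its total collected signal
#' (`total_hits`, the sum of all raw spot intensities) reaches the minimum
#' acquisition threshold.  The default threshold of 1e6 mirrors the minimum
#' hit count required of a usable scan; the boundary is inclusive.
#'
#' @param scan an [array_scan()].
#' @param min_total_hits inclusive minimum total signal.
#' @return list with `pass` (logical), `total_hits` and `reason`
#'   (`NA` when passing).
#' @export
acquisition_qc <- function(scan, min_total_hits = 1e6) {
  stopifnot(inherits(scan, "array_scan"))
  pass <- scan$total_hits >= min_total_hits
  list(pass = pass, total_hits = scan$total_hits,
       reason = if (pass) NA_character_ else {
         sprintf("total_hits %.6g below minimum %.6g", scan$total_hits,
                 min_total_hits)
       })
}

# Build a substrates x replicates intensity matrix from a scan (NA where a
# replicate spot is missing or flagged).
replicate_matrix <- function(scan, layout, use_flagged = FALSE) {
  sp <- scan$spots[scan$spots$control_type == "none", , drop = FALSE]
  if (!use_flagged) sp <- sp[!sp$flagged, , drop = FALSE]
  subs <- sort(unique(layout$spots$substrate_id[layout$spots$control_type == "none"]))
  m <- matrix(NA_real_, nrow = length(subs), ncol = max(layout$n_replicates, 1),
              dimnames = list(subs, NULL))
  m[cbind(match(sp$substrate_id, subs), sp$replicate_idx + 1L)] <- sp$raw_intensity
  m
}

row_cv <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  s <- sqrt(ss / pmax(n - 1, 1))
  cv <- ifelse(n < 2, 0, ifelse(mu > 0, s / mu, ifelse(s > 0, Inf, 0)))
  list(n = n, mean = mu, sd = s, cv = cv)
}

#' Replicate quality control
#'
#' Per substrate, computes the coefficient of variation (sd/mean) of the
#' surviving replicate spots.  Where the CV exceeds `cv_threshold`, the
#' replicate farthest from the replicate median is flagged as an outlier and
#' the CV recomputed once.  Substrates with fewer than `min_replicates`
#' surviving replicates are flagged as dropouts (an absent triplicate is a
#' dropout, not an error).
#'
#' @param scan an [array_scan()].
#' @param layout the scan's [chip_layout()].
#' @param cv_threshold CV above which one outlier replicate is ejected.
#' @param min_replicates minimum surviving replicates for a substrate to be
#'   retained.
#' @return The scan with outlier spots marked in `spots$flagged` and a `qc`
#'   data.frame (`substrate_id`, `n_surviving`, `cv`, `high_cv`, `dropout`)
#'   attached.
#' @export
replicate_qc <- function(scan, layout, cv_threshold = 0.5,
                         min_replicates = 2) {
  stopifnot(inherits(scan, "array_scan"), inherits(layout, "chip_layout"))
  m <- replicate_matrix(scan, layout)
  st <- row_cv(m)
  high <- which(st$cv > cv_threshold & st$n >= 2)

  flagged_cells <- NULL
  if (length(high) > 0) {
    med <- apply(m[high, , drop = FALSE], 1, median, na.rm = TRUE)
    dev <- abs(m[high, , drop = FALSE] - med)
    worst <- max.col(replace(dev, is.na(dev), -Inf), ties.method = "first")
    flagged_cells <- cbind(high, worst)
    m[flagged_cells] <- NA_real_
    st <- row_cv(m)
  }

  qc <- data.frame(
    substrate_id = rownames(m),
    n_surviving = st$n,
    cv = st$cv,
    high_cv = seq_len(nrow(m)) %in% high,
    dropout = st$n < min_replicates,
    stringsAsFactors = FALSE
  )
  rownames(qc) <- NULL

  if (!is.null(flagged_cells)) {
    bad <- data.frame(substrate_id = rownames(m)[flagged_cells[, 1]],
                      replicate_idx = flagged_cells[, 2] - 1L)
    key_bad <- paste(bad$substrate_id, bad$replicate_idx)
    key_all <- paste(scan$spots$substrate_id, scan$spots$replicate_idx)
    scan$spots$flagged <- scan$spots$flagged | key_all %in% key_bad
  }
  scan$qc <- qc
  scan
}

#' Background-correct a scan using its negative controls
#'
#' Subtracts the mean negative-control intensity from every substrate spot
#' and clips the result at zero.  Control spots are left untouched.
#'
#' @param scan an [array_scan()].
#' @return The corrected scan.
#' @export
background_correct <- function(scan) {
  stopifnot(inherits(scan, "array_scan"))
  neg <- scan$spots$control_type == "negative" & !scan$spots$flagged
  if (!any(neg)) {
    stop_ks("no negative-control spots present; disable background correction for this chip")
  }
  bg <- mean(scan$spots$raw_intensity[neg])
  is_sub <- scan$spots$control_type == "none"
  scan$spots$raw_intensity[is_sub] <-
    pmax(scan$spots$raw_intensity[is_sub] - bg, 0)
  scan$metadata$background <- bg
  scan
}

#' Summarize replicate spots to one value per substrate
#'
#' Per substrate, the summarized intensity is the median of the surviving
#' (unflagged, present) replicates; with exactly two survivors the median
#' equals their mean.  Substrates flagged as dropouts by [replicate_qc()]
#' are reported as `NA` and carried in the profile's QC table.
#'
#' @param scan an [array_scan()] that has been through [replicate_qc()].
#' @param layout the scan's [chip_layout()].
#' @return Object of class `substrate_profile`: list with `sample_id`,
#'   `values` (named numeric, one entry per layout substrate, `NA` for
#'   dropouts), `qc` (from [replicate_qc()]) and `condition`.
#' @export
summarize_triplicates <- function(scan, layout) {
  stopifnot(inherits(scan, "array_scan"))
  if (is.null(scan$qc)) {
    stop_ks("summarize_triplicates requires replicate_qc to have been applied")
  }
  m <- replicate_matrix(scan, layout)
  vals <- apply(m, 1, median, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  vals[scan$qc$dropout[match(names(vals), scan$qc$substrate_id)]] <- NA_real_
  structure(list(sample_id = scan$sample_id, values = vals, qc = scan$qc,
                 condition = scan$condition),
            class = "substrate_profile")
}

#' Quantile-normalize a set of arrays
#'
#' Makes every array's intensity distribution equal to the reference
#' distribution formed by averaging order statistics across arrays.  Each
#' value is replaced by the reference value at its within-array rank; tied
#' values all receive the mean of the reference values at the ranks the tie
#' group occupies.  Missing values are imputed on the reference distribution
#' at the substrate's mean empirical quantile across the arrays in which it
#' was observed, and flagged in the `"imputed"` attribute.
#'
#' @param x numeric matrix, substrates in rows, arrays (>= 2) in columns;
#'   `NA`s allowed.
#' @return A matrix of the same shape with attribute `"imputed"` (logical
#'   matrix marking imputed cells).
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop_ks("quantile normalization needs >= 2 arrays")
  n <- nrow(x)
  if (n < 1) stop_ks("empty intensity matrix")
  p_grid <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)

  # reference: mean of order statistics, mapped to a common grid when
  # columns have unequal numbers of observed values
  cols_sorted <- lapply(seq_len(ncol(x)), function(j) sort(x[, j]))
  m_obs <- lengths(cols_sorted)
  if (any(m_obs == 0)) stop_ks("array %d has no observed values", which(m_obs == 0)[1])
  on_grid <- vapply(cols_sorted, function(v) {
    s <- length(v)
    if (s == n) v else {
      approx((seq_len(s) - 1) / max(s - 1, 1), v, xout = p_grid,
             rule = 2)$y
    }
  }, numeric(n))
  ref <- rowMeans(on_grid)

  out <- x
  imputed <- is.na(x)
  emp_q <- matrix(NA_real_, n, ncol(x))  # within-array empirical quantiles
  for (j in seq_len(ncol(x))) {
    obs <- which(!is.na(x[, j]))
    v <- x[obs, j]
    s <- length(v)
    if (s == n) {
      # exact rank mapping; tie groups get the mean of their reference block
      rmin <- rank(v, ties.method = "min")
      rmax <- rank(v, ties.method = "max")
      val <- ref[rmin]
      for (i in which(rmax > rmin)) val[i] <- mean(ref[rmin[i]:rmax[i]])
      out[obs, j] <- val
    } else {
      q <- (rank(v, ties.method = "average") - 1) / max(s - 1, 1)
      out[obs, j] <- approx(p_grid, ref, xout = q, rule = 2)$y
      emp_q[obs, j] <- q
    }
    if (s == n) emp_q[obs, j] <- (rank(v, ties.method = "average") - 1) /
        max(n - 1, 1)
  }
  if (any(imputed)) {
    mean_q <- rowMeans(emp_q, na.rm = TRUE)
    for (j in seq_len(ncol(x))) {
      na_i <- which(imputed[, j])
      fillable <- na_i[!is.nan(mean_q[na_i])]
      out[fillable, j] <- approx(p_grid, ref, xout = mean_q[fillable],
                                 rule = 2)$y
    }
  }
  attr(out, "imputed") <- imputed
  out
}

#' Preprocess a set of scans into a normalized profile matrix
#'
#' The default stage order is acquisition QC, replicate QC, background
#' correction, median summarization, then cross-array quantile
#' normalization of the summarized profiles
#' (`normalize = "after_summarize"`); alternatively the spot-level replicate
#' values can be quantile-normalized before summarization
#' (`normalize = "before_summarize"`).  Arrays failing acquisition QC are
#' excluded with a logged reason.
#'
#' @param scans list of [array_scan()] objects.
#' @param layout their [chip_layout()].
#' @param min_total_hits acquisition QC threshold (see [acquisition_qc()]).
#' @param cv_threshold,min_replicates replicate QC settings
#'   (see [replicate_qc()]).
#' @param correct_background subtract mean negative-control intensity?
#' @param normalize when to quantile-normalize.
#' @return list with `matrix` (substrates x samples, normalized), `profiles`
#'   (list of `substrate_profile`), `qc` (per-array acquisition results) and
#'   `excluded` (sample ids failing acquisition QC).
#' @export
preprocess_scans <- function(scans, layout, min_total_hits = 1e6,
                             cv_threshold = 0.5, min_replicates = 2,
                             correct_background = TRUE,
                             normalize = c("after_summarize",
                                           "before_summarize")) {
  normalize <- match.arg(normalize)
  stopifnot(length(scans) >= 1)

  acq <- lapply(scans, acquisition_qc, min_total_hits = min_total_hits)
  keep <- vapply(acq, `[[`, logical(1), "pass")
  excluded <- vapply(scans[!keep], `[[`, character(1), "sample_id")
  for (i in which(!keep)) {
    message(sprintf("excluding array %s: %s", scans[[i]]$sample_id,
                    acq[[i]]$reason))
  }
  scans <- scans[keep]
  if (length(scans) < 2) {
    stop_ks("fewer than 2 arrays passed acquisition QC; normalization undefined")
  }

  scans <- lapply(scans, function(s) {
    s <- replicate_qc(s, layout, cv_threshold = cv_threshold,
                      min_replicates = min_replicates)
    if (correct_background) s <- background_correct(s)
    s
  })

  if (normalize == "before_summarize") {
    # normalize the per-replicate spot values across arrays, then summarize
    mats <- lapply(scans, replicate_matrix, layout = layout)
    flat <- vapply(mats, as.vector, numeric(length(mats[[1]])))
    normed <- quantile_normalize(flat)
    for (i in seq_along(scans)) {
      m <- matrix(normed[, i], nrow = nrow(mats[[i]]),
                  dimnames = dimnames(mats[[i]]))
      vals <- apply(m, 1, median, na.rm = TRUE)
      vals[is.nan(vals)] <- NA_real_
      drop <- scans[[i]]$qc$dropout[match(names(vals),
                                          scans[[i]]$qc$substrate_id)]
      vals[drop] <- NA_real_
      scans[[i]]$.profile <- vals
    }
    profiles <- lapply(scans, function(s) {
      structure(list(sample_id = s$sample_id, values = s$.profile, qc = s$qc,
                     condition = s$condition), class = "substrate_profile")
    })
    mat <- vapply(profiles, `[[`, numeric(length(profiles[[1]]$values)),
                  "values")
  } else {
    profiles <- lapply(scans, summarize_triplicates, layout = layout)
    mat <- vapply(profiles, `[[`, numeric(length(profiles[[1]]$values)),
                  "values")
    rownames(mat) <- names(profiles[[1]]$values)
    mat <- quantile_normalize(mat)
  }
  colnames(mat) <- vapply(profiles, `[[`, character(1), "sample_id")
  rownames(mat) <- names(profiles[[1]]$values)
  list(matrix = mat, profiles = profiles, qc = acq, excluded = excluded)
}
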