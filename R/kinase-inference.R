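# Top-N substrate selection, substrate->kinase aggregation and ranking of
# kinase activity, with category-exclusion reruns.

#' Average substrate profiles across samples
#'
#' Per substrate, the arithmetic mean over the samples in which the
#' substrate passed QC (non-`NA`); substrates failing QC in every sample
#' are omitted.  Averaging across a series of tumour samples before top-N
#' selection finds the substrates commonly phosphorylated across the series.
#'
#' @param x a numeric matrix (substrates x samples) such as
#'   `preprocess_scans()$matrix`, or a list of `substrate_profile` objects.
#' @return Named numeric vector of per-substrate means.
#' @export
group_average <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    if (length(x) == 0) stop_ks("empty profile list")
    stopifnot(all(vapply(x, inherits, logical(1), "substrate_profile")))
    vals <- vapply(x, `[[`, numeric(length(x[[1]]$values)), "values")
    rownames(vals) <- names(x[[1]]$values)
    x <- vals
  }
  x <- as.matrix(x)
  if (ncol(x) == 0 || nrow(x) == 0) stop_ks("empty profile matrix")
  out <- rowMeans(x, na.rm = TRUE)
  out[!is.nan(out)]
}

#' Select the top-N substrates of a profile
#'
#' Returns the `n` substrates with the highest summarized intensity in
#' descending order.  Ties spanning the cut are broken deterministically by
#' lexicographic substrate id, so the selection is reproducible.
#'
#' @param profile named numeric vector (substrate -> intensity); `NA`
#'   entries are ignored.
#' @param n number of substrates to select (default 100, the conventional
#'   core-analysis input size); if `n` exceeds the universe, all substrates
#'   are returned.
#' @return Character vector of substrate ids, highest intensity first.
#' @export
select_top_substrates <- function(profile, n = 100) {
  profile <- profile[!is.na(profile)]
  if (length(profile) == 0) stop_ks("profile is empty")
  ord <- order(-profile, names(profile), method = "radix")
  names(profile)[head(ord, n)]
}

#' Score and rank kinases from the top substrates
#'
#' For every kinase with at least one annotated substrate among the top
#' list, computes `n_hits` (the number of such substrates) and
#' `mean_intensity` (mean summarized intensity over them).  A substrate
#' annotated to several kinases contributes fully to each, so kinases
#' sharing a single top substrate share its intensity.  Kinases are ranked
#' by `mean_intensity` descending, ties by `n_hits` descending then kinase
#' id.
#'
#' @param top_substrates character vector from [select_top_substrates()].
#' @param profile the named intensity vector the selection was made from.
#' @param annotation a [substrate_annotation()].
#' @param kinases optional [kinase_table()]; when given, `name`,
#'   `description` and `known_drugs` columns are joined on.
#' @return data.frame of class `kinase_activity` with columns `rank`,
#'   `kinase_id`, `mean_intensity`, `n_hits` (plus metadata columns when
#'   `kinases` is supplied).
#' @export
score_kinases <- function(top_substrates, profile, annotation,
                          kinases = NULL) {
  stopifnot(inherits(annotation, "substrate_annotation"))
  top_substrates <- as.character(top_substrates)
  hits <- annotation$map[intersect(names(annotation$map), top_substrates)]
  if (length(hits) == 0) {
    res <- data.frame(rank = integer(0), kinase_id = character(0),
                      mean_intensity = numeric(0), n_hits = integer(0))
    class(res) <- c("kinase_activity", "data.frame")
    return(res)
  }
  long <- data.frame(
    substrate_id = rep(names(hits), lengths(hits)),
    kinase_id = unlist(hits, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  long$intensity <- profile[long$substrate_id]
  agg <- split(long$intensity, long$kinase_id)
  res <- data.frame(
    kinase_id = names(agg),
    mean_intensity = vapply(agg, mean, numeric(1)),
    n_hits = lengths(agg),
    stringsAsFactors = FALSE
  )
  ord <- order(-res$mean_intensity, -res$n_hits, res$kinase_id,
               method = "radix")
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res <- res[, c("rank", "kinase_id", "mean_intensity", "n_hits")]
  rownames(res) <- NULL
  if (!is.null(kinases)) {
    i <- match(res$kinase_id, kinases$kinase_id)
    res$name <- kinases$name[i]
    res$description <- kinases$description[i]
    res$known_drugs <- kinases$known_drugs[i]
  }
  class(res) <- c("kinase_activity", "data.frame")
  res
}

#' Remove kinases bearing excluded category tags and re-rank
#'
#' Used to rerun the activity ranking leaving out whole kinase categories —
#' typically `cell_cycle`, whose members can be artificially upregulated by
#' cell culturing and would otherwise mask tumour-specific activity.
#'
#' @param activities a `kinase_activity` data.frame from [score_kinases()].
#' @param exclude_categories character vector of category tags to drop;
#'   empty means no filtering.
#' @param kinases the [kinase_table()] carrying the category tags.
#' @return The filtered `kinase_activity` table with ranks recomputed over
#'   the survivors; a warning is raised if nothing survives.
#' @export
filter_kinases <- function(activities, exclude_categories, kinases) {
  stopifnot(inherits(kinases, "kinase_table"))
  known <- sort(unique(unlist(kinases$category_list)))
  unknown <- setdiff(exclude_categories, known)
  if (length(unknown) > 0) {
    stop_ks("unknown category name(s): %s (known tags: %s)",
            paste(unknown, collapse = ", "),
            if (length(known)) paste(known, collapse = ", ") else "<none>")
  }
  if (length(exclude_categories) == 0) return(activities)
  cats <- kinases$category_list[match(activities$kinase_id,
                                      kinases$kinase_id)]
  drop <- vapply(cats, function(x) any(x %in% exclude_categories),
                 logical(1))
  drop[is.na(drop)] <- FALSE
  out <- activities[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("all kinases were excluded by category filter")
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Identify the most active kinases from a top-substrate list
#'
#' Active-kinase identification combines the two evidence streams the
#' top-substrate readout provides — how strongly a kinase's substrates are
#' phosphorylated and how many of them reach the top list — by ranking
#' kinases on their total attributable top-substrate signal
#' (`n_hits x mean_intensity`, i.e. the summed intensity of the kinase's
#' top substrates), ties broken by higher mean intensity then kinase id.
#' Ranking on mean intensity alone (the report order of [score_kinases()])
#' is not identifiable under many-to-many annotation: a kinase sharing a
#' single strongly phosphorylated substrate with a truly active kinase
#' inherits its full mean intensity as a one-hit entry, whereas the summed
#' signal separates sustained multi-substrate activity from single-substrate
#' aliasing.
#'
#' @param top_substrates,profile,annotation as in [score_kinases()].
#' @param k number of kinases to call active (default 10).
#' @return Character vector of up to `k` kinase ids, strongest evidence
#'   first.
#' @seealso [score_kinases()] for the report-shaped ranking.
#' @export
call_active_kinases <- function(top_substrates, profile, annotation,
                                k = 10) {
  act <- score_kinases(top_substrates, profile, annotation)
  total <- act$mean_intensity * act$n_hits
  ord <- order(-total, -act$mean_intensity, act$kinase_id, method = "radix")
  head(act$kinase_id[ord], k)
}

#' Cross-sample hit frequency of kinases
#'
#' Per-sample alternative to averaging first: selects the top-`n`
#' substrates within each sample and reports, for every kinase, in how many
#' samples it had at least one hit, together with its mean per-sample hit
#' count.
#'
#' @param mat normalized profile matrix (substrates x samples).
#' @param annotation a [substrate_annotation()].
#' @param n top-substrate count per sample.
#' @return data.frame with `kinase_id`, `n_samples_hit`, `mean_hits`,
#'   sorted by `n_samples_hit` then `mean_hits` descending.
#' @export
kinase_hit_frequency <- function(mat, annotation, n = 100) {
  mat <- as.matrix(mat)
  per_sample <- lapply(seq_len(ncol(mat)), function(j) {
    prof <- setNames(mat[, j], rownames(mat))
    top <- select_top_substrates(prof, n)
    score_kinases(top, prof, annotation)
  })
  all_k <- sort(unique(unlist(lapply(per_sample, `[[`, "kinase_id"))))
  hits <- vapply(per_sample, function(s) {
    out <- setNames(rep(0L, length(all_k)), all_k)
    out[s$kinase_id] <- s$n_hits
    out
  }, integer(length(all_k)))
  hits <- matrix(hits, nrow = length(all_k))
  res <- data.frame(
    kinase_id = all_k,
    n_samples_hit = rowSums(hits > 0),
    mean_hits = rowMeans(hits),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$n_samples_hit, -res$mean_hits, res$kinase_id,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}
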