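# Hypergeometric pathway over-representation: a transparent ranking of
# pathways by enrichment of the active-kinase set, computed over a
# user-supplied kinase->pathway table.

#' Pathway over-representation of an active kinase set
#'
#' For every pathway, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap between the active set and the pathway's
#' members when `active_set_size` kinases are drawn without replacement
#' from the universe.  Results carry BH-adjusted q-values and are ranked by
#' ascending p, ties broken by larger overlap then pathway id.  An empty
#' active set yields p = 1 for every pathway (with a warning).
#'
#' @param active_kinases character vector of active kinase ids (a subset of
#'   `universe`), typically the ranked kinases from [score_kinases()].
#' @param pathways a [pathway_annotation()]; member kinases must lie in
#'   `universe`.
#' @param universe character vector of all detectable kinases.
#' @return data.frame of class `enrichment_result` with columns
#'   `rank`, `pathway_id`, `pathway_name`, `overlap`, `pathway_size`,
#'   `active_set_size`, `universe_size`, `expected_overlap`, `p`, `fdr`.
#' @export
enrich <- function(active_kinases, pathways, universe) {
  stopifnot(inherits(pathways, "pathway_annotation"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop_ks("empty kinase universe")
  active_kinases <- unique(as.character(active_kinases))
  if (!all(active_kinases %in% universe)) {
    stop_ks("active kinases must be a subset of the universe")
  }
  outside <- setdiff(unlist(pathways$sets), universe)
  if (length(outside) > 0) {
    stop_ks("pathway member(s) outside the universe: %s",
            paste(head(outside, 5), collapse = ", "))
  }
  if (length(active_kinases) == 0) {
    warning("empty active set: all pathway p-values are 1 by convention")
  }

  N <- length(universe)
  k <- length(active_kinases)
  res <- do.call(rbind, lapply(names(pathways$sets), function(pw) {
    members <- pathways$sets[[pw]]
    m <- length(members)
    ov <- length(intersect(members, active_kinases))
    p <- if (k == 0) 1 else phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(pathway_id = pw,
               pathway_name = unname(pathways$names[pw]),
               overlap = ov, pathway_size = m, active_set_size = k,
               universe_size = N, expected_overlap = k * m / N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_fdr(res$p)
  ord <- order(res$p, -res$overlap, res$pathway_id, method = "radix")
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res <- res[, c("rank", "pathway_id", "pathway_name", "overlap",
                 "pathway_size", "active_set_size", "universe_size",
                 "expected_overlap", "p", "fdr")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Shortlist of the top-ranked pathways
#'
#' @param results an `enrichment_result` from [enrich()].
#' @param k shortlist length (the conventional report shows up to five
#'   pathways).
#' @return The first `min(k, nrow(results))` rows.
#' @export
top_pathways <- function(results, k = 5) {
  stopifnot(inherits(results, "data.frame"))
  if (k <= 0) return(results[0, , drop = FALSE])
  head(results, k)
}
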