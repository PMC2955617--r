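# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation kept separate from the
# package's code path.

# Naive quantile normalization: sort each column, average order statistics,
# map back by rank; ties all receive the mean of their tied reference
# values.  Complete matrices only.
oracle_quantile_normalize <- function(x) {
  stopifnot(!anyNA(x))
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    rmin <- rank(x[, j], ties.method = "min")
    rmax <- rank(x[, j], ties.method = "max")
    out[, j] <- vapply(seq_len(nrow(x)),
                       function(i) mean(ref[rmin[i]:rmax[i]]), numeric(1))
  }
  out
}

# Textbook pooled two-sample t on log2(x+1) data.
oracle_pooled_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  s2 <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / (na + nb - 2)
  (ma - mb) / sqrt(s2 * (1 / na + 1 / nb))
}

# Exact upper-tail hypergeometric probability by enumeration over all
# possible overlap counts (choose() is exact in double precision for the
# small universes used here).
oracle_hyper_upper <- function(overlap, pathway_size, universe_size,
                               active_size) {
  ks <- overlap:min(pathway_size, active_size)
  sum(choose(pathway_size, ks) *
        choose(universe_size - pathway_size, active_size - ks)) /
    choose(universe_size, active_size)
}

# Tiny layout: n substrates x r replicates plus one negative and one
# positive control.
toy_layout <- function(n = 4, r = 3, n_neg = 2, n_pos = 2) {
  default_layout(n_substrates = n, n_replicates = r,
                 n_negative = n_neg, n_positive = n_pos, chip_id = "toy")
}

# Scan with prescribed replicate intensities: `values` is a matrix
# (substrates x replicates, NA = missing spot).
toy_scan <- function(layout, values, neg = 50, pos = 5000,
                     sample_id = "s1") {
  sp <- layout$spots
  is_sub <- sp$control_type == "none"
  subs <- sort(unique(sp$substrate_id[is_sub]))
  stopifnot(nrow(values) == length(subs))
  inten <- numeric(nrow(sp))
  inten[is_sub] <- values[cbind(match(sp$substrate_id[is_sub], subs),
                                sp$replicate_idx[is_sub] + 1L)]
  inten[sp$control_type == "negative"] <- neg
  inten[sp$control_type == "positive"] <- pos
  df <- data.frame(spot_id = sp$spot_id, substrate_id = sp$substrate_id,
                   replicate_idx = sp$replicate_idx,
                   control_type = sp$control_type, raw_intensity = inten,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$raw_intensity), , drop = FALSE]
  array_scan(sample_id, df, layout)
}

# Annotation from an explicit substrate -> kinases list.
toy_annotation <- function(map) {
  substrate_annotation(data.frame(
    substrate_id = rep(names(map), lengths(map)),
    kinase_id = unlist(map, use.names = FALSE),
    stringsAsFactors = FALSE))
}
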