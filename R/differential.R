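# Tumor-vs-control specificity contrast per substrate: empirical-Bayes
# moderated t-statistic with BH false-discovery-rate control.

#' Invert the trigamma function
#'
#' Newton iteration on `1/trigamma`, which is nearly linear; used by
#' [estimate_prior()] to solve the moment equation for the prior degrees of
#' freedom.
#'
#' @param y positive values.
#' @return `x` such that `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  todo <- is.na(out) & is.finite(y) & y > 0
  x <- 0.5 + 1 / y[todo]
  for (i in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[todo]) / psigamma(x, 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[todo] <- x
  out[!is.finite(y) | y <= 0] <- NaN
  out
}

#' Estimate the variance-shrinkage prior
#'
#' Empirical-Bayes moment matching on log sample variances.  Under the
#' hierarchical model the per-substrate sample variances are distributed as
#' `s0_sq * F(df, d0)`; the mean and variance of `log(s2)` are matched to
#' their theoretical digamma/trigamma moments to solve for the prior
#' degrees of freedom `d0` and prior variance `s0_sq`.  When the observed
#' dispersion of log variances does not exceed the sampling dispersion
#' `trigamma(df/2)`, the moment equation has no positive solution and
#' `d0 = Inf` is returned (complete shrinkage to a common variance).
#'
#' @param s2 per-substrate sample variances (>= 2 values, not all zero).
#' @param df residual degrees of freedom of each variance (scalar).
#' @return Object of class `variance_prior`: list with `d0` (prior df,
#'   possibly `Inf`) and `s0_sq` (prior variance).
#' @export
estimate_prior <- function(s2, df) {
  s2 <- as.numeric(s2)
  if (length(s2) < 2) stop_ks("need >= 2 sample variances")
  if (all(s2 <= 0)) stop_ks("degenerate input: all sample variances are zero")
  s2 <- s2[s2 > 0]
  z <- log(s2)
  vz <- var(z)
  if (vz < 1e-12) {
    # no dispersion at all: the common value is the prior
    return(structure(list(d0 = Inf, s0_sq = exp(mean(z))),
                     class = "variance_prior"))
  }
  evar <- vz - trigamma(df / 2)
  if (evar <= 0) {
    s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2))
    return(structure(list(d0 = Inf, s0_sq = s0_sq), class = "variance_prior"))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' Moderated two-sample t contrast between sample groups
#'
#' Per substrate, computes the mean log-intensity difference between groups
#' A and B, the pooled sample variance, the empirical-Bayes shrunken
#' variance `(d0*s0_sq + df*s2) / (d0 + df)` and the moderated t-statistic
#' `log_fc / (s_tilde * sqrt(1/na + 1/nb))`, with two-sided p-values from a
#' t distribution on `df + d0` degrees of freedom and BH-adjusted q-values
#' across substrates.  With `d0 = 0` this is the ordinary pooled two-sample
#' t; with `d0 = Inf` every substrate uses the common prior variance.
#'
#' @param group_a,group_b numeric matrices (substrates x samples, >= 2
#'   samples each) of normalized intensities with matching row names.
#' @param prior optional [estimate_prior()] result; estimated from the
#'   pooled variances when `NULL`.
#' @param log_transform log2-transform intensities after adding `offset`?
#'   (Background-corrected intensities can be exactly zero.)
#' @param offset additive offset used before the log transform.
#' @return data.frame of class `differential_result` with columns
#'   `substrate_id`, `log_fc`, `t_mod`, `df_total`, `p`, `fdr`, sorted by
#'   `p`; the prior used is attached as attribute `"prior"`.
#' @export
moderated_t <- function(group_a, group_b, prior = NULL,
                        log_transform = TRUE, offset = 1) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  na <- ncol(group_a); nb <- ncol(group_b)
  if (na < 2 || nb < 2) stop_ks("each group needs >= 2 samples")
  if (!identical(rownames(group_a), rownames(group_b))) {
    stop_ks("group matrices must share the same substrates (row names)")
  }
  if (log_transform) {
    group_a <- log2(group_a + offset)
    group_b <- log2(group_b + offset)
  }
  ma <- rowMeans(group_a); mb <- rowMeans(group_b)
  ssa <- rowSums((group_a - ma)^2)
  ssb <- rowSums((group_b - mb)^2)
  df <- na + nb - 2
  s2 <- (ssa + ssb) / df
  if (is.null(prior)) prior <- estimate_prior(s2, df)
  d0 <- prior$d0; s0 <- prior$s0_sq

  if (is.infinite(d0)) {
    s2_post <- rep(s0, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  log_fc <- ma - mb
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, log_fc / se, ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
  p <- 2 * pt(-abs(t_mod), df = df_total)
  res <- data.frame(
    substrate_id = rownames(group_a) %||% as.character(seq_along(log_fc)),
    log_fc = log_fc,
    t_mod = t_mod,
    df_total = df_total,
    p = p,
    stringsAsFactors = FALSE
  )
  res$fdr <- bh_fdr(res$p)
  res <- res[order(res$p, res$substrate_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "prior") <- prior
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment with enforced monotonicity, stable under input
#' reordering (each p-value keeps its position).
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_ks("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Tumor-specific substrates from a differential result
#'
#' Convenience selector: substrates with `fdr < q` that are higher in the
#' first (tumour) group.
#'
#' @param res a `differential_result` from [moderated_t()].
#' @param q FDR threshold (configurable; 0.05 by default).
#' @return Character vector of substrate ids.
#' @export
tumor_specific <- function(res, q = 0.05) {
  res$substrate_id[res$fdr < q & res$log_fc > 0]
}
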