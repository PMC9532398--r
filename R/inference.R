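# Null-model inference: calibration of graph statistics against the UBCM,
# degree-bucketed one-sided significance testing for nodewise coefficients,
# two-stage FDR correction, significance fractions and the structural
# diversity index.

# Registry of named graph-level statistics usable with calibrate().
builtin_statistic <- function(name) {
  switch(name,
    mean_s = function(g) mean(structural_coefficients(g)$nodes$s, na.rm = TRUE),
    mean_c = function(g) mean(structural_coefficients(g)$nodes$c, na.rm = TRUE),
    global_s = function(g) structural_coefficients(g)$global$s,
    global_c = function(g) structural_coefficients(g)$global$c,
    stop(sprintf(
      "unknown statistic '%s' (use mean_s, mean_c, global_s, global_c, or a function)",
      name
    ))
  )
}

#' Calibrate an observed statistic against null-model values
#'
#' The calibrated value of an observed statistic `x(G)` against `R` null
#' replicates is the average natural-log ratio
#' `C = (1/R') * sum(log(x(G) / x(G_r)))` over the `R'` retained samples.
#' Ratios of like-united quantities make the argument of the logarithm
#' dimensionless; the natural log is used. Null samples with zero,
#' negative or undefined statistic are dropped and counted; if fewer than
#' `min_valid` (a fraction of `R`) remain the result is `NA`.
#'
#' @param observed observed statistic value (positive, finite).
#' @param null_values statistic values on the null replicates.
#' @param min_valid minimum fraction of valid null samples required.
#' @return A list of class `calibration`: `observed`, `null_values`,
#'   `calibrated`, `R`, `n_dropped`.
#' @export
calibrate_values <- function(observed, null_values, min_valid = 0.5) {
  R <- length(null_values)
  if (!is.finite(observed) || observed <= 0) {
    return(structure(
      list(observed = observed, null_values = null_values,
           calibrated = NA_real_, R = R, n_dropped = R,
           note = "observed statistic zero or undefined"),
      class = "calibration"
    ))
  }
  ok <- is.finite(null_values) & null_values > 0
  kept <- null_values[ok]
  calibrated <- if (length(kept) >= max(1, min_valid * R)) {
    mean(log(observed / kept))
  } else {
    NA_real_
  }
  structure(
    list(observed = observed, null_values = null_values,
         calibrated = calibrated, R = R, n_dropped = R - length(kept)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: observed %.4g, calibrated %.4g (R=%d, dropped %d)\n",
              x$observed, x$calibrated, x$R, x$n_dropped))
  invisible(x)
}

#' Calibrate a graph statistic against the UBCM
#'
#' Fits the UBCM to the observed degree sequence, draws `R` sampled graphs,
#' evaluates the statistic on each, and returns the average log-ratio of the
#' observed to the null values (see [calibrate_values()]). A calibrated
#' value near 0 means the statistic is what the degree sequence alone
#' predicts; positive means enrichment.
#'
#' @param graph observed [simple_graph].
#' @param statistic a statistic name (`"mean_s"`, `"mean_c"`, `"global_s"`,
#'   `"global_c"`) or a `function(graph) -> scalar`.
#' @param R number of null samples.
#' @param seed optional master seed for the sampling stream.
#' @param model optional pre-fitted [fit_ubcm()] model (skips refitting).
#' @param min_valid minimum fraction of valid null samples.
#' @return A `calibration` object (see [calibrate_values()]).
#' @export
calibrate <- function(graph, statistic, R = 100L, seed = NULL, model = NULL,
                      min_valid = 0.5) {
  stopifnot(inherits(graph, "simple_graph"), R >= 1)
  f <- if (is.function(statistic)) statistic else builtin_statistic(statistic)
  observed <- f(graph)
  if (is.null(model)) model <- fit_ubcm(graph)
  null_values <- with_seed(seed, {
    vapply(seq_len(R), function(r) f(sample_ubcm(model)), numeric(1))
  })
  calibrate_values(observed, null_values, min_valid = min_valid)
}

# Nodewise coefficient matrices on R null samples: rows = samples, columns =
# nodes of the observed graph (identities preserved).
null_coefficient_samples <- function(model, R, seed = NULL) {
  with_seed(seed, {
    s_mat <- matrix(NA_real_, R, model$n)
    c_mat <- matrix(NA_real_, R, model$n)
    for (r in seq_len(R)) {
      nc <- node_coefficients(path_census(sample_ubcm(model))$nodes)
      s_mat[r, ] <- nc$s
      c_mat[r, ] <- nc$c
    }
    list(s = s_mat, c = c_mat)
  })
}

# Degree-bucketed one-sided upper-tail p-values. Under the UBCM the null
# distribution of any nodewise statistic is identical for nodes with equal
# observed degree (degrees are the model's sufficient statistics), so null
# values are pooled into buckets keyed by the observed degrees -- a node in a
# sampled graph contributes to the bucket of its observed-graph degree.
# Empirical quantiles are taken at levels 0, 1/nq, ..., (nq-1)/nq and
# p = 1 - alpha_max, where alpha_max is the largest level whose quantile lies
# strictly below the observed value. This yields p in {1/nq, ..., 1} -- a
# resolution of 0.01 for 100 percentiles with R >= 100 -- and p = 1 when the
# observed value does not exceed the bucket minimum.
bucket_pvalues <- function(observed, deg, null_mat, n_quantiles = 100L) {
  n <- length(observed)
  p <- rep(NA_real_, n)
  untestable <- rep(FALSE, n)
  levels <- (seq_len(n_quantiles) - 1L) / n_quantiles
  for (dv in unique(deg)) {
    members <- which(deg == dv)
    vals <- as.vector(null_mat[, members, drop = FALSE])
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L) {
      untestable[members] <- TRUE
      next
    }
    qs <- quantile(vals, probs = levels, type = 1, names = FALSE)
    for (u in members) {
      if (!is.finite(observed[u])) next
      below <- which(qs < observed[u])
      # integer arithmetic keeps p exactly on the grid {1/nq, ..., 1}
      k_max <- if (length(below)) max(below) else 1L
      p[u] <- (n_quantiles - k_max + 1L) / n_quantiles
    }
  }
  list(p = p, untestable = untestable)
}

#' Degree-bucketed significance of nodewise coefficients
#'
#' Tests, one-sidedly (upper tail), whether each node's structural
#' similarity or complementarity exceeds what the UBCM fitted to the
#' observed degrees predicts. Because node degrees are the UBCM's sufficient
#' statistics, nodes with equal observed degree share a null distribution;
#' null coefficient values from `R` sampled graphs are pooled into buckets
#' keyed by observed degree (giving at least `R` null observations per
#' node), summarized by `n_quantiles` empirical quantiles, and
#' `p = 1 - alpha_max` with `alpha_max` the largest quantile level strictly
#' below the observed value. Raw p-values are adjusted with the two-stage
#' FDR procedure ([adjust_fdr_bky()]).
#'
#' Nodes with an undefined observed coefficient get no p-value; nodes whose
#' bucket contains no defined null values are flagged untestable. Both
#' count as not significant downstream.
#'
#' @param graph observed [simple_graph].
#' @param coefficient `"s"` (similarity) or `"c"` (complementarity).
#' @param R null samples (>= 100 recommended for 0.01 resolution).
#' @param n_quantiles quantile grid size (default 100 percentiles).
#' @param alpha significance level applied to adjusted p-values.
#' @param seed optional master seed.
#' @param model,null_samples optional precomputed [fit_ubcm()] model and
#'   `null_coefficient_samples()` output, to share samples across calls.
#' @return An object of class `node_significance`: data.frame `table` with
#'   `node, label, degree, value, p, p_adj, significant, untestable` plus
#'   fields `coefficient`, `R`, `n_quantiles`, `alpha`.
#' @export
node_pvalues <- function(graph, coefficient = c("s", "c"), R = 100L,
                         n_quantiles = 100L, alpha = 0.05, seed = NULL,
                         model = NULL, null_samples = NULL) {
  coefficient <- match.arg(coefficient)
  stopifnot(inherits(graph, "simple_graph"), R >= 1, n_quantiles >= 2)
  d <- degrees(graph)
  obs <- node_coefficients(path_census(graph)$nodes)[[coefficient]]
  if (is.null(model)) model <- fit_ubcm(graph)
  if (is.null(null_samples)) {
    null_samples <- null_coefficient_samples(model, R, seed = seed)
  }
  bp <- bucket_pvalues(obs, d, null_samples[[coefficient]], n_quantiles)

  p_adj <- rep(NA_real_, graph$n)
  ok <- !is.na(bp$p)
  if (any(ok)) p_adj[ok] <- adjust_fdr_bky(bp$p[ok], alpha = alpha)
  significant <- !is.na(p_adj) & p_adj <= alpha

  structure(
    list(
      table = data.frame(
        node = seq_len(graph$n), label = graph$labels, degree = d,
        value = obs, p = bp$p, p_adj = p_adj,
        significant = significant, untestable = bp$untestable,
        row.names = NULL
      ),
      coefficient = coefficient, R = R,
      n_quantiles = n_quantiles, alpha = alpha
    ),
    class = "node_significance"
  )
}

#' @export
print.node_significance <- function(x, ...) {
  cat(sprintf(
    "node_significance (%s): %d/%d nodes significant at alpha=%g (R=%d)\n",
    x$coefficient, sum(x$table$significant), nrow(x$table), x$alpha, x$R
  ))
  invisible(x)
}

#' Two-stage FDR adjustment (Benjamini-Krieger-Yekutieli)
#'
#' Two-stage linear step-up procedure: a first Benjamini-Hochberg pass at
#' level `alpha / (1 + alpha)` estimates the number of true nulls
#' `m0 = m - r1` from its rejection count `r1`; the second pass then runs
#' BH at the sharpened level `alpha * m / ((1 + alpha) * m0)`. The returned
#' adjusted p-values are the second-stage BH-adjusted values scaled by
#' `m0 (1 + alpha) / m` and capped at 1, so a hypothesis is rejected
#' exactly when its adjusted value is `<= alpha`. The adjustment is
#' order-preserving but, unlike plain BH, specific to the `alpha` used.
#'
#' @param pvalues raw p-values in `(0, 1]` (no `NA`s).
#' @param alpha target FDR level.
#' @return Adjusted p-values, same length and order as `pvalues`.
#' @export
adjust_fdr_bky <- function(pvalues, alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1] with no NAs")
  }
  m <- length(p)
  alpha_prime <- alpha / (1 + alpha)
  bh <- p.adjust(p, method = "BH")
  r1 <- sum(bh <= alpha_prime)
  if (r1 == 0L || r1 == m) {
    return(pmin(1, bh * (1 + alpha)))
  }
  pmin(1, bh * (m - r1) / m * (1 + alpha))
}

#' Significance fractions for similarity and complementarity
#'
#' Partitions the nodes of a graph into four classes by the significance
#' flags of their similarity and complementarity coefficients: S-only,
#' C-only, both, neither. Untestable nodes and nodes with undefined
#' coefficients count as not significant.
#'
#' @param sig_s,sig_c [node_pvalues()] results for `"s"` and `"c"` on the
#'   same graph at the same `alpha`.
#' @param alpha significance level; defaults to the level stored in the
#'   inputs (which must agree).
#' @return A list of class `diversity_proportions`: `p_S`, `p_C`, `p_B`,
#'   `p_N` (summing to 1), `alpha`, `n`.
#' @export
significance_fractions <- function(sig_s, sig_c, alpha = NULL) {
  stopifnot(inherits(sig_s, "node_significance"),
            inherits(sig_c, "node_significance"))
  if (!identical(sig_s$table$label, sig_c$table$label)) {
    stop("significance results computed on different node sets")
  }
  if (is.null(alpha)) {
    if (sig_s$alpha != sig_c$alpha) stop("inputs use different alpha levels")
    alpha <- sig_s$alpha
  }
  flag <- function(x) !is.na(x$table$p_adj) & x$table$p_adj <= alpha
  fs <- flag(sig_s)
  fc <- flag(sig_c)
  n <- length(fs)
  structure(
    list(
      p_S = sum(fs & !fc) / n,
      p_C = sum(!fs & fc) / n,
      p_B = sum(fs & fc) / n,
      p_N = sum(!fs & !fc) / n,
      alpha = alpha, n = n
    ),
    class = "diversity_proportions"
  )
}

#' Structural diversity index
#'
#' Entropy-based summary of how evenly a graph's nodes split between
#' significant similarity, significant complementarity, and both. With
#' `p_S, p_C, p_B, p_N` the fractions of S-only / C-only / both / neither
#' nodes, the conditional proportions `p_X / (1 - p_N)` (for X in S, C, B)
#' form a distribution over the nodes with at least one significant
#' coefficient, and
#' `S_alpha = (1 - p_N) * H(conditionals) / log2(3)`,
#' where `H` is Shannon entropy in bits and `log2(3)` normalizes to
#' `[0, 1]`. `S_alpha = 0` when no node is significant (`0 * H := 0`) and
#' `S_alpha = 1` iff every node is significant and the three conditional
#' classes are equally populated. The `(1 - p_N)` prefactor penalizes
#' graphs with mostly null, random-like structure.
#'
#' @param proportions a `diversity_proportions` object from
#'   [significance_fractions()], or a numeric vector
#'   `c(p_S, p_C, p_B, p_N)` summing to 1.
#' @return The index value in `[0, 1]`.
#' @examples
#' structural_diversity(c(0.3, 0.2, 0.1, 0.4)) # ~0.5524
#' @export
structural_diversity <- function(proportions) {
  if (inherits(proportions, "diversity_proportions")) {
    pr <- c(proportions$p_S, proportions$p_C, proportions$p_B, proportions$p_N)
  } else {
    pr <- as.numeric(proportions)
  }
  if (length(pr) != 4L || any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
    stop("proportions must be 4 nonnegative values summing to 1")
  }
  p_N <- pr[4]
  if (1 - p_N <= 0) return(0)
  cond <- pr[1:3] / (1 - p_N)
  nz <- cond[cond > 0]
  H <- max(0, -sum(nz * log2(nz))) # clamp float noise when a conditional is ~1
  min(1, (1 - p_N) * H / log2(3))
}

#' Full diversity pipeline for a graph
#'
#' Fits the UBCM once, draws one shared set of `R` null samples, tests both
#' coefficients, and returns the significance fractions and the structural
#' diversity index.
#'
#' @inheritParams node_pvalues
#' @return A list with `sig_s`, `sig_c`, `proportions`, `S_alpha`.
#' @export
diversity_index <- function(graph, R = 100L, alpha = 0.05, n_quantiles = 100L,
                            seed = NULL) {
  model <- fit_ubcm(graph)
  ns <- null_coefficient_samples(model, R, seed = seed)
  sig_s <- node_pvalues(graph, "s", R = R, n_quantiles = n_quantiles,
                        alpha = alpha, model = model, null_samples = ns)
  sig_c <- node_pvalues(graph, "c", R = R, n_quantiles = n_quantiles,
                        alpha = alpha, model = model, null_samples = ns)
  prop <- significance_fractions(sig_s, sig_c, alpha = alpha)
  list(sig_s = sig_s, sig_c = sig_c, proportions = prop,
       S_alpha = structural_diversity(prop))
}
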