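test_that("calibration is the average log-ratio with dropped-sample bookkeeping", {
  expect_equal(calibrate_values(0.1, rep(0.1, 20))$calibrated, 0)
  expect_equal(calibrate_values(0.2, rep(0.1, 20))$calibrated, log(2))

  # zero / undefined null values are dropped and counted
  cal <- calibrate_values(0.2, c(rep(0.1, 8), 0, NA))
  expect_equal(cal$n_dropped, 2L)
  expect_equal(cal$calibrated, log(2))

  # too few valid samples -> undefined
  expect_true(is.na(calibrate_values(0.2, c(0.1, rep(0, 9)))$calibrated))

  # undefined observed statistic -> undefined with diagnostic
  cal0 <- calibrate_values(0, rep(0.1, 5))
  expect_true(is.na(cal0$calibrated))
  expect_match(cal0$note, "observed")
})

test_that("graph calibration is reproducible and self-null centered", {
  g <- gen_er(60, 0.1, seed = 20)
  c1 <- calibrate(g, "mean_s", R = 20, seed = 4)
  c2 <- calibrate(g, "mean_s", R = 20, seed = 4)
  expect_equal(c1$calibrated, c2$calibrated)

  # named statistic and equivalent function give the same result
  f <- function(gr) mean(structural_coefficients(gr)$nodes$s, na.rm = TRUE)
  c3 <- calibrate(g, f, R = 20, seed = 4)
  expect_equal(c3$calibrated, c1$calibrated)

  # a graph drawn from its own UBCM calibrates to ~0
  model <- fit_ubcm(gen_er(80, 0.08, seed = 31))
  gnull <- sample_ubcm(model, seed = 7)
  # the observed graph is a single draw, so the calibrated value fluctuates
  # on the scale of the null spread itself, not the Monte-Carlo mean error
  cal <- calibrate(gnull, "mean_s", R = 60, seed = 8)
  null_sd <- stats::sd(log(cal$null_values[cal$null_values > 0]))
  expect_lt(abs(cal$calibrated), 4 * null_sd)
})

test_that("degree-bucketed p-values follow the quantile convention", {
  bp <- structcoef:::bucket_pvalues
  null_mat <- matrix(runif(400, 0.2, 0.4), nrow = 100, ncol = 4)

  # observed above every bucket quantile: p at the floor 1/n_quantiles
  res <- bp(c(0.9, 0.1, 0.3, NA), deg = c(2, 2, 2, 5),
            null_mat = null_mat, n_quantiles = 100)
  expect_equal(res$p[1], 0.01)
  # observed below every quantile: p = 1
  expect_equal(res$p[2], 1)
  # undefined observed value: no p-value
  expect_true(is.na(res$p[4]))
  # p-values live on the grid {1/nq, ..., 1}
  expect_true(res$p[3] %in% (seq(1, 100) / 100))

  # identical-degree nodes with identical observed values get identical p
  res2 <- bp(c(0.31, 0.31), deg = c(2, 2), null_mat = null_mat[, 1:2],
             n_quantiles = 100)
  expect_equal(res2$p[1], res2$p[2])

  # all-NA bucket: untestable
  res3 <- bp(c(0.5), deg = 3, null_mat = matrix(NA_real_, 10, 1),
             n_quantiles = 100)
  expect_true(res3$untestable[1])
  expect_true(is.na(res3$p[1]))
})

test_that("node significance testing is deterministic and degree-consistent", {
  g <- gen_er(50, 0.12, seed = 42)
  s1 <- node_pvalues(g, "s", R = 50, seed = 9)
  s2 <- node_pvalues(g, "s", R = 50, seed = 9)
  expect_identical(s1$table, s2$table)
  ok <- !is.na(s1$table$p)
  expect_true(all(s1$table$p[ok] > 0 & s1$table$p[ok] <= 1))
  # granularity: p-values sit on the percentile grid
  expect_true(all(s1$table$p[ok] %in% (seq(1, 100) / 100)))
})

# Literal transcription of the two-stage step-up procedure used as an
# independent oracle for rejection decisions: stage 1 runs linear step-up at
# alpha/(1+alpha); its rejection count r1 estimates the true nulls m - r1;
# stage 2 reruns linear step-up at level alpha/(1+alpha) * m/(m - r1).
bky_reject_naive <- function(p, alpha) {
  m <- length(p)
  step_up <- function(q) {
    o <- order(p)
    ps <- p[o]
    below <- which(ps <= seq_len(m) / m * q)
    rej <- logical(m)
    if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
    rej
  }
  q1 <- alpha / (1 + alpha)
  r1 <- sum(step_up(q1))
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(q1 * m / (m - r1))
}

test_that("two-stage FDR adjustment matches the reference procedure", {
  pv <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
          0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569,
          0.594, 0.696)
  # frozen values from an independent implementation of the two-stage
  # procedure (adjusted so that rejection at level alpha is padj <= alpha)
  expect_equal(
    adjust_fdr_bky(pv, alpha = 0.05),
    c(0.01995, 0.0798, 0.16758, 0.16758, 0.16758, 0.1995, 0.2109,
      0.391875, 0.391875, 0.391875, 0.391875, 0.391875, 0.391875,
      0.391875, 0.425184375, 0.425184375, 0.4506352941, 0.6237, 0.6237,
      0.69426),
    tolerance = 1e-9
  )
  expect_equal(
    adjust_fdr_bky(pv, alpha = 0.1)[1:3],
    c(0.0198, 0.0792, 0.16632),
    tolerance = 1e-9
  )

  # rejection sets equal the literal two-stage transcription on random input
  set.seed(555)
  for (rep in 1:20) {
    p <- c(runif(12), runif(8, 0, 0.05))
    for (alpha in c(0.01, 0.05, 0.1)) {
      expect_equal(adjust_fdr_bky(p, alpha) <= alpha,
                   bky_reject_naive(p, alpha))
    }
  }

  # adjusted values are monotone in the order of the raw p-values
  p <- sort(runif(30))
  expect_true(!is.unsorted(adjust_fdr_bky(p, 0.05)))

  # degenerate inputs
  expect_equal(adjust_fdr_bky(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr_bky(c(0.5, 0)), "0, 1")
  expect_error(adjust_fdr_bky(c(0.5, NA)), "0, 1")
})

fake_sig <- function(p_adj, alpha = 0.05) {
  structure(
    list(table = data.frame(
      node = seq_along(p_adj), label = as.character(seq_along(p_adj)),
      p_adj = p_adj
    ), alpha = alpha),
    class = "node_significance"
  )
}

test_that("significance fractions partition the node set", {
  # 10 nodes: 3 S-only, 2 C-only, 1 both, 4 neither
  ps <- c(0.01, 0.01, 0.01, 1, 1, 0.01, 1, 1, 1, 1)
  pc <- c(1, 1, 1, 0.01, 0.01, 0.01, 1, 1, 1, 1)
  fr <- significance_fractions(fake_sig(ps), fake_sig(pc))
  expect_equal(c(fr$p_S, fr$p_C, fr$p_B, fr$p_N), c(0.3, 0.2, 0.1, 0.4))

  # untestable (NA) counts as not significant
  fr2 <- significance_fractions(fake_sig(c(NA, 0.01)), fake_sig(c(NA, 1)))
  expect_equal(fr2$p_N, 0.5)
  expect_equal(fr2$p_S, 0.5)

  # extremes
  fr3 <- significance_fractions(fake_sig(rep(1, 4)), fake_sig(rep(1, 4)))
  expect_equal(fr3$p_N, 1)
  fr4 <- significance_fractions(fake_sig(rep(0.01, 4)), fake_sig(rep(0.01, 4)))
  expect_equal(fr4$p_B, 1)

  expect_error(
    significance_fractions(fake_sig(c(0.5, 0.5)), fake_sig(rep(0.5, 3))),
    "different node sets"
  )
})

test_that("structural diversity index matches the entropy formula", {
  expect_equal(structural_diversity(c(0, 0, 0, 1)), 0)
  expect_equal(structural_diversity(c(1 / 3, 1 / 3, 1 / 3, 0)), 1)
  expect_equal(structural_diversity(c(1, 0, 0, 0)), 0) # single class: H = 0

  # worked value, cross-checked against an independent entropy routine
  pr <- c(0.3, 0.2, 0.1, 0.4)
  cond <- pr[1:3] / (1 - pr[4])
  H_indep <- vegan::diversity(cond, index = "shannon", base = 2)
  expect_equal(structural_diversity(pr), (1 - pr[4]) * H_indep / log2(3))
  expect_equal(structural_diversity(pr), 0.5523719, tolerance = 1e-6)

  # index stays in [0, 1] across a grid of valid proportion vectors
  grid <- seq(0, 1, by = 0.1)
  for (a in grid) for (b in grid) for (cc in grid) {
    d <- 1 - a - b - cc
    if (d < -1e-9) next
    v <- structural_diversity(c(a, b, cc, max(d, 0)) /
                                sum(a, b, cc, max(d, 0)))
    expect_true(v >= 0 && v <= 1 + 1e-12)
  }

  expect_error(structural_diversity(c(0.5, 0.5)), "4 nonnegative")
  expect_error(structural_diversity(c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
})

test_that("diversity pipeline shares null samples across both coefficients", {
  g <- gen_er(40, 0.15, seed = 13)
  div <- diversity_index(g, R = 30, alpha = 0.05, seed = 2)
  fr <- div$proportions
  expect_equal(fr$p_S + fr$p_C + fr$p_B + fr$p_N, 1)
  expect_equal(div$S_alpha, structural_diversity(fr))
  # reproducible under the master seed
  div2 <- diversity_index(g, R = 30, alpha = 0.05, seed = 2)
  expect_equal(div2$S_alpha, div$S_alpha)
})
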