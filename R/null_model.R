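#' Fit the Undirected Binary Configuration Model (UBCM)
#'
#' The UBCM is the maximum-entropy distribution over simple undirected
#' graphs on `n` nodes whose expected degree sequence equals a target
#' sequence; it is the ERGM with node degrees as sufficient statistics.
#' Every node carries a nonnegative fitness `x_i` and each pair links
#' independently with probability `p_ij = x_i x_j / (1 + x_i x_j)`. Fitting
#' solves the `n` coupled equations `sum_{j != i} p_ij = d_i`.
#'
#' The solver is damped Newton iteration on `theta_i = log x_i` for the
#' nodes with `d_i > 0` (`d_i = 0` forces `x_i = 0` exactly). Saturated
#' nodes (`d_i = n - 1`) push their fitness towards infinity; `theta` is
#' capped at +/-45, large enough that the residual of a saturated node is
#' far below any practical tolerance while keeping all products finite in
#' double precision. The fit is deterministic.
#'
#' @param degrees nonnegative integer degree sequence (`d_i <= n - 1`), or a
#'   [simple_graph] whose observed degrees (taken verbatim, not binned) are
#'   the target.
#' @param tolerance maximum allowed `|expected - target|` degree error
#'   (default `1e-8`).
#' @param max_iter Newton iteration cap.
#' @return An object of class `ubcm`: list with `x` (fitness), `degrees`
#'   (target), `expected_degrees`, `residual` (max abs error), `tolerance`,
#'   `iterations`, `n`, `labels`.
#' @examples
#' m <- fit_ubcm(c(2, 2, 2, 2)) # C4 degrees: p_ij = 2/3 for all pairs
#' ubcm_pij(m)[1, 2]
#' @export
fit_ubcm <- function(degrees, tolerance = 1e-8, max_iter = 500L) {
  labels <- NULL
  if (inherits(degrees, "simple_graph")) {
    labels <- degrees$labels
    degrees <- degrees(degrees)
  }
  d <- as.numeric(degrees)
  n <- length(d)
  if (any(d < 0) || any(d != round(d))) stop("degrees must be nonnegative integers")
  if (any(d > n - 1)) stop("validation error: degree exceeds n - 1")
  if (is.null(labels)) labels <- as.character(seq_len(n))

  x <- numeric(n)
  act <- which(d > 0)
  if (length(act) >= 2L) {
    theta_cap <- 45
    th <- log(d[act] / sqrt(sum(d) + 1))
    th <- pmin(pmax(th, -theta_cap), theta_cap)
    na <- length(act)
    da <- d[act]

    pij_of <- function(th) {
      xx <- exp(th)
      xp <- outer(xx, xx)
      p <- xp / (1 + xp)
      diag(p) <- 0
      p
    }
    resid_of <- function(th) {
      p <- pij_of(th)
      list(p = p, r = da - rowSums(p))
    }

    st <- resid_of(th)
    it <- 0L
    while (max(abs(st$r)) > tolerance && it < max_iter) {
      it <- it + 1L
      w <- st$p * (1 - st$p)
      J <- w
      diag(J) <- rowSums(w)
      step <- tryCatch(
        solve(J, st$r),
        error = function(e) solve(J + diag(1e-12 * (1 + max(diag(J))), na), st$r)
      )
      step <- pmin(pmax(step, -10), 10)
      lam <- 1
      repeat {
        th_new <- pmin(pmax(th + lam * step, -theta_cap), theta_cap)
        st_new <- resid_of(th_new)
        if (max(abs(st_new$r)) < max(abs(st$r)) || lam < 1e-6) break
        lam <- lam / 2
      }
      th <- th_new
      st <- st_new
      if (all(abs(th) >= theta_cap) && lam < 1e-6) break
    }
    if (max(abs(st$r)) > tolerance) {
      stop(sprintf(
        "UBCM fit did not converge: max degree residual %.3g after %d iterations",
        max(abs(st$r)), it
      ))
    }
    x[act] <- exp(th)
    expected <- d
    expected[act] <- rowSums(st$p)
    iterations <- it
    residual <- max(abs(st$r))
  } else if (length(act) == 1L) {
    stop("degree sequence with a single nonzero degree is infeasible")
  } else {
    expected <- d
    iterations <- 0L
    residual <- 0
  }

  structure(
    list(x = x, degrees = d, expected_degrees = expected,
         residual = residual, tolerance = tolerance,
         iterations = iterations, n = n, labels = labels),
    class = "ubcm"
  )
}

#' @export
print.ubcm <- function(x, ...) {
  cat(sprintf("ubcm: n=%d, max degree residual %.3g (%d Newton iterations)\n",
              x$n, x$residual, x$iterations))
  invisible(x)
}

#' Pairwise link probabilities of a fitted UBCM
#'
#' @param model a fitted [fit_ubcm()] object.
#' @return Symmetric `n x n` matrix with `p_ij = x_i x_j / (1 + x_i x_j)`
#'   and zero diagonal.
#' @export
ubcm_pij <- function(model) {
  stopifnot(inherits(model, "ubcm"))
  xp <- outer(model$x, model$x)
  p <- xp / (1 + xp)
  p[!is.finite(p)] <- 1 # Inf * 0-safe: overflow products mean p -> 1
  diag(p) <- 0
  dimnames(p) <- list(model$labels, model$labels)
  p
}

#' Sample a graph from a fitted UBCM
#'
#' Draws each unordered pair independently with its model probability
#' `p_ij`. The returned graph keeps all `n` nodes (isolates allowed), so
#' node identities line up with the observed graph the model was fitted to.
#'
#' @param model a fitted [fit_ubcm()] object.
#' @param seed optional integer; same seed, same graph.
#' @return A [simple_graph] on `model$n` nodes.
#' @export
sample_ubcm <- function(model, seed = NULL) {
  stopifnot(inherits(model, "ubcm"))
  n <- model$n
  p <- ubcm_pij(model)
  pv <- p[upper.tri(p)]
  keep <- with_seed(seed, runif(length(pv)) < pv)
  ut <- which(upper.tri(p), arr.ind = TRUE)
  simple_graph(ut[keep, , drop = FALSE], labels = model$labels)
}
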