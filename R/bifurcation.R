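#' Symmetric equilibrium level
#'
#' Solves the uniform fixed point of a rotationally symmetric network at
#' constant coupling `g`. With `m` repressors per gene and row strength sum
#' `S`, the level solves `x = alpha0 + beta / (1 + g S x^h)` for the OR gate
#' and `x = alpha0 + beta / (1 + g wbar x^(m h))` for the AND gate (`wbar`
#' the geometric mean of incoming strengths). Both right-hand sides are
#' strictly decreasing in `x`, so the root is unique; it is found by
#' bracketed root-finding on `[0, alpha0 + beta]` and polished by Newton
#' steps to residual below 1e-12.
#'
#' @param net a rotationally symmetric `cfr_network` (uniform couplings and
#'   kinetics, no knockout).
#' @param g constant coupling value (>= 0).
#' @return the equilibrium level `x*` (scalar).
#' @examples
#' net <- cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1)
#' symmetric_equilibrium(net, 0)     # exactly alpha0 + beta
#' symmetric_equilibrium(net, 0.15)
#' @export
symmetric_equilibrium <- function(net, g) {
  check_rot_symmetric(net)
  stopifnot(length(g) == 1L, is.finite(g), g >= 0)
  a0 <- net$production_basal[1]
  b <- net$production_max[1]
  d <- net$degradation[1]
  h <- net$hill_coefficient
  W <- coupling_matrix(net)
  if (g == 0) return((a0 + b) / d)
  if (net$gate == "OR") {
    S <- sum(W[1, ])
    f <- function(x) a0 + b / (1 + g * S * exp_pow(x, h)) - d * x
    fp <- function(x) -b * g * S * h * exp_pow(x, h - 1) /
      (1 + g * S * exp_pow(x, h))^2 - d
  } else {
    R <- which(W[1, ] > 0)
    wbar <- exp(mean(log(W[1, R])))
    mh <- length(R) * h
    f <- function(x) a0 + b / (1 + g * wbar * exp_pow(x, mh)) - d * x
    fp <- function(x) -b * g * wbar * mh * exp_pow(x, mh - 1) /
      (1 + g * wbar * exp_pow(x, mh))^2 - d
  }
  hi <- (a0 + b) / d
  root <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  for (k in 1:4) root <- root - f(root) / fp(root)  # Newton polish
  if (abs(f(root)) > 1e-10) {
    stop(sprintf("symmetric equilibrium residual %.3g exceeds 1e-10 on [0, %g]",
                 abs(f(root)), hi), call. = FALSE)
  }
  root
}

#' Analytic Jacobian of the dynamics
#'
#' Closed-form Jacobian of the right-hand side at state `x` with the
#' coupling frozen at `g`. External signals are additive constants and do not
#' enter. Validated against central finite differences in the test suite.
#'
#' @param net a `cfr_network`.
#' @param g a numeric coupling value, or a `cfr_schedule` to be frozen at
#'   time `t`.
#' @param x nonnegative state vector.
#' @param t time at which to freeze a schedule (default 0).
#' @return the `n x n` Jacobian matrix.
#' @export
network_jacobian <- function(net, g, x, t = 0) {
  stopifnot(inherits(net, "cfr_network"))
  if (inherits(g, "cfr_schedule")) g <- g_at(g, t)
  n <- net$n_genes
  x <- pmax(as.numeric(x), 0)
  W <- coupling_matrix(net)
  h <- net$hill_coefficient
  kappa <- as.numeric(!net$knockout)
  b <- net$production_max
  J <- diag(-net$degradation, n)
  if (net$gate == "OR") {
    xh <- exp_pow(x, h)
    xh1 <- exp_pow(x, h - 1)
    D <- 1 + g * as.vector(W %*% xh)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (W[i, j] > 0) {
          J[i, j] <- J[i, j] -
            kappa[i] * b[i] * g * W[i, j] * h * xh1[j] / D[i]^2
        }
      }
    }
  } else {
    xs <- pmax(x, 1e-300)
    for (i in seq_len(n)) {
      R <- which(W[i, ] > 0)
      w <- W[i, R]
      e <- h * length(w) * w / sum(w)
      wbar <- exp(mean(log(w)))
      Ti <- if (any(x[R] == 0)) 0 else
        g * wbar * exp(sum(e * log(xs[R])))
      Di <- 1 + Ti
      for (k in seq_along(R)) {
        j <- R[k]
        J[i, j] <- J[i, j] -
          kappa[i] * b[i] * Ti * e[k] / (xs[j] * Di^2)
      }
    }
  }
  J
}

#' Asymmetric (winner-take-all / pair-high) equilibrium
#'
#' Locates the fate-specialized equilibrium branch at constant coupling `g`:
#' one gene high and the rest low for the OR gate, or two genes high under
#' the AND gate. The full `n`-dimensional fixed-point system is solved by a
#' damped Newton iteration with the analytic Jacobian, started from the
#' high/low ansatz (`alpha0 + beta` on the chosen high genes, `alpha0`
#' elsewhere). Returns `NULL` when no such equilibrium exists (no
#' convergence, or the converged state lacks the high/low pattern) — for the
#' classic repressilator that is the expected outcome at every coupling.
#'
#' @param net a `cfr_network`.
#' @param g constant coupling value.
#' @param hi indices of the putative high gene(s); default gene 1 (OR) or
#'   genes 1 and 3 (AND).
#' @param pattern_ratio high/low ratio required to accept the pattern
#'   (default 3).
#' @return `NULL`, or a list with the equilibrium `x`, `residual` (max
#'   absolute fixed-point defect), `lead_re` (leading Jacobian eigenvalue
#'   real part), `stable` flag, and `hi`.
#' @export
wta_equilibrium <- function(net, g, hi = NULL, pattern_ratio = 3) {
  stopifnot(inherits(net, "cfr_network"))
  n <- net$n_genes
  if (is.null(hi)) hi <- if (net$gate == "OR") 1L else c(1L, 3L)
  f <- cfr_rhs(net, coupling_schedule("constant", g))
  x <- rep(net$production_basal[1], n)
  x[hi] <- net$production_basal[hi] + net$production_max[hi]
  res <- function(x) f(0, x)
  r <- res(x)
  for (it in 1:80) {
    J <- network_jacobian(net, g, x)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- pmax(x + lam * step, 0)
      rn <- res(xn)
      if (max(abs(rn)) < max(abs(r)) || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- xn; r <- rn
    if (max(abs(r)) < 1e-13) break
  }
  if (max(abs(r)) > 1e-10) return(NULL)
  lo <- setdiff(seq_len(n), hi)
  if (min(x[hi]) < pattern_ratio * max(x[lo])) return(NULL)
  ev <- eigen(network_jacobian(net, g, x), only.values = TRUE)$values
  lead <- max(Re(ev))
  list(x = x, residual = max(abs(r)), lead_re = lead,
       stable = lead < 0, hi = hi)
}

#' Trace an equilibrium branch over a coupling grid
#'
#' @param net a `cfr_network`.
#' @param g_grid increasing vector of coupling values.
#' @param kind `"symmetric"` (uniform branch) or `"asymmetric"`
#'   (winner-take-all / pair-high branch via [wta_equilibrium()]).
#' @param hi high genes for the asymmetric branch (see [wta_equilibrium()]).
#' @return data frame with `g`, state columns `x1..xn` (NA where the branch
#'   does not exist), `lead_re`, `stable`, `residual`.
#' @export
equilibrium_branch <- function(net, g_grid, kind = c("symmetric", "asymmetric"),
                               hi = NULL) {
  kind <- match.arg(kind)
  n <- net$n_genes
  rows <- lapply(g_grid, function(g) {
    if (kind == "symmetric") {
      xs <- symmetric_equilibrium(net, g)
      x <- rep(xs, n)
      f <- cfr_rhs(net, coupling_schedule("constant", g))
      r <- max(abs(f(0, x)))
      ev <- eigen(network_jacobian(net, g, x), only.values = TRUE)$values
      lead <- max(Re(ev))
      c(g = g, stats::setNames(x, paste0("x", 1:n)),
        lead_re = lead, stable = as.numeric(lead < 0), residual = r)
    } else {
      w <- wta_equilibrium(net, g, hi = hi)
      if (is.null(w)) {
        c(g = g, stats::setNames(rep(NA_real_, n), paste0("x", 1:n)),
          lead_re = NA_real_, stable = NA_real_, residual = NA_real_)
      } else {
        c(g = g, stats::setNames(w$x, paste0("x", 1:n)),
          lead_re = w$lead_re, stable = as.numeric(w$stable),
          residual = w$residual)
      }
    }
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$stable <- out$stable == 1
  out
}

#' Regime boundaries in coupling strength
#'
#' Maps the two boundaries that delimit the oscillatory window of a
#' rotationally symmetric network:
#' \itemize{
#'   \item `g_lower` — where the symmetric (multipotent) equilibrium loses
#'     linear stability, detected by bisection on the sign of the leading
#'     Jacobian eigenvalue real part along the symmetric branch;
#'   \item `g_upper` — where a stable fate-specialized (winner-take-all, or
#'     pair-high under AND) equilibrium first exists, detected by bisection
#'     on existence-plus-stability of that branch.
#' }
#' Either boundary may be absent in range: the classic repressilator has a
#' `g_lower` but no fate-specialized equilibria at any coupling, so its
#' `g_upper` is reported absent rather than treated as an error. If the
#' oscillatory window and the stable specialized branch overlap (bistability)
#' the boundaries simply record both onsets; no hysteresis is suppressed.
#'
#' @param net a rotationally symmetric `cfr_network`.
#' @param g_range length-2 positive range to search (default `c(1e-6, 50)`).
#' @param n_scan log-spaced scan points used to bracket sign changes
#'   (default 40).
#' @param tol_rel relative bracket width at which bisection stops
#'   (default 1e-3).
#' @param hi high genes for the specialized branch (see [wta_equilibrium()]).
#' @return A `cfr_boundaries`: list with `g_lower`, `g_upper` (NA when
#'   absent), the final brackets, and method notes.
#' @examples
#' \donttest{
#' net <- cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1)
#' regime_boundaries(net, c(1e-3, 5))
#' }
#' @export
regime_boundaries <- function(net, g_range = c(1e-6, 50), n_scan = 40,
                              tol_rel = 1e-3, hi = NULL) {
  check_rot_symmetric(net)
  stopifnot(length(g_range) == 2L, all(g_range > 0), g_range[1] < g_range[2])
  grid <- exp(seq(log(g_range[1]), log(g_range[2]), length.out = n_scan))

  lead_at <- function(g) {
    xs <- symmetric_equilibrium(net, g)
    ev <- eigen(network_jacobian(net, g, rep(xs, net$n_genes)),
                only.values = TRUE)$values
    max(Re(ev))
  }
  leads <- vapply(grid, lead_at, numeric(1))
  notes <- character(0)

  g_lower <- NA_real_
  lower_bracket <- c(NA_real_, NA_real_)
  sgn <- leads > 0
  if (any(sgn) && !sgn[1]) {
    k <- which(sgn)[1]
    lo <- grid[k - 1]; hi_g <- grid[k]
    while ((hi_g - lo) / hi_g > tol_rel) {
      mid <- sqrt(lo * hi_g)
      if (lead_at(mid) > 0) hi_g <- mid else lo <- mid
    }
    g_lower <- (lo + hi_g) / 2
    lower_bracket <- c(lo, hi_g)
  } else if (all(!sgn)) {
    notes <- c(notes, "regime absent: symmetric equilibrium stable over the whole range")
  } else {
    notes <- c(notes, "symmetric equilibrium already unstable at g_range[1]")
  }

  stable_wta <- function(g) {
    w <- wta_equilibrium(net, g, hi = hi)
    !is.null(w) && w$stable
  }
  wta_flags <- vapply(grid, stable_wta, logical(1))
  g_upper <- NA_real_
  upper_bracket <- c(NA_real_, NA_real_)
  if (any(wta_flags) && !wta_flags[1]) {
    k <- which(wta_flags)[1]
    lo <- grid[k - 1]; hi_g <- grid[k]
    while ((hi_g - lo) / hi_g > tol_rel) {
      mid <- sqrt(lo * hi_g)
      if (stable_wta(mid)) hi_g <- mid else lo <- mid
    }
    g_upper <- (lo + hi_g) / 2
    upper_bracket <- c(lo, hi_g)
  } else if (all(!wta_flags)) {
    notes <- c(notes,
               "regime absent: no stable fate-specialized equilibrium in range")
  } else {
    notes <- c(notes, "fate-specialized branch already stable at g_range[1]")
    g_upper <- g_range[1]
  }

  structure(
    list(g_lower = g_lower, g_upper = g_upper,
         lower_bracket = lower_bracket, upper_bracket = upper_bracket,
         g_range = g_range, tol_rel = tol_rel, n_scan = n_scan,
         notes = notes,
         method = list(lower = "bisection on leading eigenvalue sign, symmetric branch",
                       upper = "bisection on existence+stability of the specialized branch")),
    class = "cfr_boundaries"
  )
}

#' @export
print.cfr_boundaries <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.6g", v)
  cat(sprintf("<cfr_boundaries> g_lower = %s, g_upper = %s\n",
              fmt(x$g_lower), fmt(x$g_upper)))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Serialize regime boundaries to JSON
#'
#' @param b a `cfr_boundaries`.
#' @param path optional output path.
#' @return JSON string (invisibly if written to file).
#' @export
boundaries_to_json <- function(b, path = NULL) {
  stopifnot(inherits(b, "cfr_boundaries"))
  js <- jsonlite::toJSON(unclass(b), digits = NA, auto_unbox = TRUE,
                         null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# internal: a spec is rotationally symmetric when per-gene vectors are uniform
# and nothing is knocked out
check_rot_symmetric <- function(net) {
  uni <- function(v) diff(range(v)) <= 1e-12 * max(abs(v), 1)
  ok <- uni(net$coupling_forward) && uni(net$coupling_reverse) &&
    uni(net$production_max) && uni(net$production_basal) &&
    uni(net$degradation) && !any(net$knockout)
  if (!ok) {
    stop("this analysis requires a rotationally symmetric network ",
         "(uniform couplings and kinetics, no knockout)", call. = FALSE)
  }
  invisible(TRUE)
}
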