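#' Right-hand side of the repression dynamics
#'
#' Builds the time-derivative function of the model. For the OR gate the
#' repressor inputs to gene i combine additively in one saturating term:
#' \deqn{dx_i/dt = \kappa_i [\alpha_{0,i} + \beta_i / (1 + g(t) \sum_j W_{ij}
#' x_j^h)] - \delta_i x_i + s_i(t)}
#' where \eqn{\kappa_i} is 0 for knocked-out genes and 1 otherwise, and
#' `W` is the relative coupling matrix. For the AND gate the repressors
#' combine multiplicatively inside one term:
#' \deqn{dx_i/dt = \kappa_i [\alpha_{0,i} + \beta_i / (1 + g(t) \bar w_i
#' \prod_j x_j^{h m_{ij}})] - \delta_i x_i + s_i(t)}
#' with \eqn{\bar w_i} the geometric mean of the incoming edge strengths and
#' exponent weights \eqn{m_{ij} = |R_i| W_{ij} / \sum_j W_{ij}} (so that the
#' exponents sum to \eqn{|R_i| h}). For equal incoming strengths the weights
#' are all 1 and the term reduces to the plain product
#' \eqn{\bar w_i \prod_j x_j^h}; unequal strengths tilt the stoichiometry of
#' the repressing complex towards the stronger edge. A low level of any
#' single repressor makes the product small, so repression requires *all*
#' inputs to be high (AND semantics).
#'
#' Products and powers are evaluated in log space, so large states cannot
#' overflow.
#'
#' @param net a `cfr_network`.
#' @param schedule a `cfr_schedule` (default: constant g = 1).
#' @param signals a `cfr_signal`, list of them, or `NULL`.
#' @return function `f(t, x)` returning the derivative vector.
#' @seealso [simulate_network()], [network_jacobian()]
#' @examples
#' net <- cfr_network(3, "cyclic", "OR")
#' f <- cfr_rhs(net, coupling_schedule("constant", 5))
#' f(0, c(1, 2, 3))
#' @export
cfr_rhs <- function(net, schedule = coupling_schedule("constant", 1),
                    signals = NULL) {
  stopifnot(inherits(net, "cfr_network"), inherits(schedule, "cfr_schedule"))
  n <- net$n_genes
  W <- coupling_matrix(net)
  h <- net$hill_coefficient
  kappa <- as.numeric(!net$knockout)
  alpha0 <- net$production_basal
  beta <- net$production_max
  delta <- net$degradation
  has_sig <- !is.null(signals) &&
    (inherits(signals, "cfr_signal") || length(signals) > 0)

  if (net$gate == "OR") {
    function(t, x) {
      x <- pmax(x, 0)
      g <- g_at(schedule, t)
      D <- 1 + g * as.vector(W %*% exp_pow(x, h))
      dx <- kappa * (alpha0 + beta / D) - delta * x
      if (has_sig) dx <- dx + signal_at(signals, t, n)
      dx
    }
  } else {
    reps <- lapply(seq_len(n), function(i) which(W[i, ] > 0))
    wbar <- vapply(seq_len(n), function(i) exp(mean(log(W[i, reps[[i]]]))),
                   numeric(1))
    expo <- lapply(seq_len(n), function(i) {
      w <- W[i, reps[[i]]]
      h * length(w) * w / sum(w)
    })
    function(t, x) {
      x <- pmax(x, 0)
      g <- g_at(schedule, t)
      D <- numeric(n)
      for (i in seq_len(n)) {
        xi <- x[reps[[i]]]
        # any repressor at zero removes repression entirely
        term <- if (any(xi == 0)) 0 else
          exp(sum(expo[[i]] * log(xi)) + log(wbar[i]))
        D[i] <- 1 + g * term
      }
      dx <- kappa * (alpha0 + beta / D) - delta * x
      if (has_sig) dx <- dx + signal_at(signals, t, n)
      dx
    }
  }
}

# x^h guarded against overflow: computed as exp(h log x), capped below the
# double-precision ceiling so products stay finite
exp_pow <- function(x, h) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- exp(pmin(h * log(x[pos]), 700))
  out
}

#' Integrate the network dynamics
#'
#' Deterministic, stiff-capable integration (lsoda) of the repression
#' dynamics, sampled on a uniform reporting grid. Given identical settings
#' the result is bit-reproducible.
#'
#' @param net a `cfr_network`.
#' @param schedule a `cfr_schedule`.
#' @param x0 nonnegative initial state (length `n_genes`).
#' @param t_max end of the integration horizon (start is `t0`).
#' @param signals optional `cfr_signal` or list of them.
#' @param t0 start time (default 0).
#' @param n_out number of reporting grid points (default 2000).
#' @param rtol,atol integrator tolerances (defaults 1e-8, 1e-10).
#' @param method deSolve method name (default `"lsoda"`).
#' @return A `cfr_trajectory`: list with `times`, state matrix `x` (rows =
#'   grid points, columns = genes), coupling values `g`, signal matrix
#'   `signal` (or NULL), the `network`/`schedule`/`signals` used, and
#'   integrator `settings`.
#' @examples
#' p <- cfr_preset("repressilator")
#' traj <- simulate_network(p$network, p$schedule, x0 = c(1, 1.05, 0.95),
#'                          t_max = 60, n_out = 500)
#' @export
simulate_network <- function(net, schedule, x0, t_max, signals = NULL,
                             t0 = 0, n_out = 2000,
                             rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(net, "cfr_network"), inherits(schedule, "cfr_schedule"))
  if (!is.finite(t_max) || t_max <= t0) {
    stop("`t_max` must be finite and greater than `t0`", call. = FALSE)
  }
  x0 <- as.numeric(x0)
  if (length(x0) != net$n_genes || any(!is.finite(x0)) || any(x0 < 0)) {
    stop("`x0` must be a nonnegative vector of length n_genes", call. = FALSE)
  }
  f <- cfr_rhs(net, schedule, signals)
  times <- seq(t0, t_max, length.out = n_out)
  sol <- deSolve::ode(
    y = x0, times = times,
    func = function(t, y, parms) list(f(t, y)),
    parms = NULL, method = method, rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed: ", paste(utils::capture.output(
      deSolve::diagnostics(sol)), collapse = "\n"), call. = FALSE)
  }
  X <- unname(sol[, -1, drop = FALSE])
  if (anyNA(X) || any(!is.finite(X))) {
    stop("integration produced non-finite state values", call. = FALSE)
  }
  neg <- X < 0
  if (any(X[neg] < -1e-9)) {
    warning("integrator undershoot below -1e-9 clamped to zero",
            call. = FALSE)
  }
  X[neg] <- 0
  colnames(X) <- paste0("x", seq_len(net$n_genes))
  sig_mat <- NULL
  if (!is.null(signals) &&
      (inherits(signals, "cfr_signal") || length(signals) > 0)) {
    sig_mat <- t(vapply(times, function(t) signal_at(signals, t, net$n_genes),
                        numeric(net$n_genes)))
  }
  structure(
    list(times = times, x = X, g = g_at(schedule, times), signal = sig_mat,
         network = net, schedule = schedule, signals = signals,
         settings = list(t0 = t0, t_max = t_max, n_out = n_out, rtol = rtol,
                         atol = atol, method = method, x0 = x0)),
    class = "cfr_trajectory"
  )
}

#' Seeded start near the symmetric state
#'
#' Draws an initial condition as a small multiplicative perturbation of the
#' symmetric equilibrium at coupling `g`. The exactly symmetric state is
#' dynamically invariant, so a deterministic run started there would never
#' desymmetrize; ensemble runs therefore start from seeded perturbations.
#'
#' @param net a rotationally symmetric `cfr_network`.
#' @param g coupling value at which to solve the symmetric equilibrium.
#' @param seed integer seed.
#' @param rel relative perturbation half-width (default 0.05).
#' @return nonnegative numeric vector of length `n_genes`.
#' @export
perturbed_start <- function(net, g, seed, rel = 0.05) {
  xs <- symmetric_equilibrium(net, g)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xs * stats::runif(net$n_genes, 1 - rel, 1 + rel)
}

# save/restore the global RNG state so seeded helpers do not perturb it
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cfr_trajectory <- function(x, ...) {
  cat(sprintf("<cfr_trajectory> %d genes, t in [%.4g, %.4g], %d samples\n",
              ncol(x$x), min(x$times), max(x$times), length(x$times)))
  cat(sprintf("  g in [%.4g, %.4g] (%s schedule), gate %s\n",
              min(x$g), max(x$g), x$schedule$kind, x$network$gate))
  invisible(x)
}

#' Tidy data frame view of a trajectory
#'
#' @param x a `cfr_trajectory`.
#' @param ... unused.
#' @return data frame with columns `time`, `gene`, `level`, `g_value`,
#'   `signal_value`.
#' @export
as.data.frame.cfr_trajectory <- function(x, ...) {
  n <- ncol(x$x)
  m <- length(x$times)
  sig <- if (is.null(x$signal)) matrix(0, m, n) else x$signal
  data.frame(
    time = rep(x$times, n),
    gene = rep(seq_len(n), each = m),
    level = as.vector(x$x),
    g_value = rep(x$g, n),
    signal_value = as.vector(sig)
  )
}

#' Write / read a trajectory as tidy CSV
#'
#' The CSV holds the long-format samples; the network, schedule, signal, and
#' integrator settings are embedded as a JSON comment header so the file
#' round-trips to an equivalent `cfr_trajectory`.
#'
#' @param traj a `cfr_trajectory`.
#' @param path output file.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `cfr_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cfr_trajectory"))
  meta <- jsonlite::toJSON(trajectory_meta(traj), digits = NA,
                           auto_unbox = TRUE, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#cfrsim ", meta), con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#cfrsim ")) {
    stop("not a cfrsim trajectory file: ", path, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sub("^#cfrsim ", "", first),
                             simplifyVector = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  n <- max(df$gene)
  m <- nrow(df) / n
  X <- matrix(df$level, nrow = m, ncol = n)
  colnames(X) <- paste0("x", seq_len(n))
  net <- do.call(cfr_network, meta$network)
  sched <- do.call(coupling_schedule, meta$schedule)
  sigs <- NULL
  if (length(meta$signals) > 0) {
    sigs <- lapply(seq_len(nrow(meta$signals)), function(i)
      do.call(signal_protocol, as.list(meta$signals[i, ])))
  }
  sig_mat <- NULL
  if (any(df$signal_value != 0)) {
    sig_mat <- matrix(df$signal_value, nrow = m, ncol = n)
  }
  structure(
    list(times = df$time[seq_len(m)], x = X,
         g = df$g_value[seq_len(m)], signal = sig_mat,
         network = net, schedule = sched, signals = sigs,
         settings = meta$settings),
    class = "cfr_trajectory"
  )
}

# internal: serializable description of a trajectory's provenance
trajectory_meta <- function(traj) {
  net <- unclass(traj$network)
  names(net)[names(net) == "knockout"] <- "knockout"
  sched <- unclass(traj$schedule)
  sched <- sched[!vapply(sched, is.null, logical(1))]
  sigs <- traj$signals
  if (!is.null(sigs)) {
    if (inherits(sigs, "cfr_signal")) sigs <- list(sigs)
    sigs <- do.call(rbind, lapply(sigs, function(s)
      data.frame(target_gene = s$target_gene, amplitude = s$amplitude,
                 t_on = s$t_on, t_off = s$t_off)))
  }
  list(network = net, schedule = sched, signals = sigs,
       settings = traj$settings)
}

#' Columnar binary cache for trajectories
#'
#' Writes the tidy samples to a Parquet file (via the `arrow` package) for
#' fast reloading of large sweeps. Provenance metadata are stored in the
#' file's key-value metadata.
#'
#' @param traj a `cfr_trajectory`.
#' @param path output `.parquet` file.
#' @return `path`, invisibly.
#' @export
write_trajectory_cache <- function(traj, path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the `arrow` package is required for the columnar cache",
         call. = FALSE)
  }
  df <- as.data.frame(traj)
  tbl <- arrow::arrow_table(df)
  tbl$metadata$cfrsim <- as.character(jsonlite::toJSON(
    trajectory_meta(traj), digits = NA, auto_unbox = TRUE, null = "null"))
  arrow::write_parquet(tbl, path)
  invisible(path)
}

#' @rdname write_trajectory_cache
#' @export
read_trajectory_cache <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the `arrow` package is required for the columnar cache",
         call. = FALSE)
  }
  tbl <- arrow::read_parquet(path, as_data_frame = FALSE)
  meta <- jsonlite::fromJSON(tbl$metadata$cfrsim, simplifyVector = TRUE)
  df <- as.data.frame(tbl)
  n <- max(df$gene)
  m <- nrow(df) / n
  X <- matrix(df$level, nrow = m, ncol = n)
  colnames(X) <- paste0("x", seq_len(n))
  net <- do.call(cfr_network, meta$network)
  sched <- do.call(coupling_schedule, meta$schedule)
  structure(
    list(times = df$time[seq_len(m)], x = X, g = df$g_value[seq_len(m)],
         signal = NULL, network = net, schedule = sched, signals = NULL,
         settings = meta$settings),
    class = "cfr_trajectory"
  )
}

# internal: restrict a trajectory to a time window (samples in [from, to])
traj_window <- function(traj, from = -Inf, to = Inf) {
  keep <- traj$times >= from & traj$times <= to
  traj$times <- traj$times[keep]
  traj$x <- traj$x[keep, , drop = FALSE]
  traj$g <- traj$g[keep]
  if (!is.null(traj$signal)) traj$signal <- traj$signal[keep, , drop = FALSE]
  traj
}
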