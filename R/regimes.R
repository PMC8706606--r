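#' Classification thresholds
#'
#' Decision thresholds for [classify_regime()]. The regimes are defined
#' operationally, since the model distinguishes them only qualitatively:
#' \itemize{
#'   \item *oscillatory*: post-transient relative amplitude (max - min over
#'     post-transient mean) at least `osc_rel_amp` on at least one gene, with
#'     at least `min_peaks` detected peaks on the widest-swinging gene;
#'   \item *multipotent*: steady (all relative amplitudes below
#'     `steady_rel_amp`) with all per-gene means within `equal_tol` of the
#'     grand mean;
#'   \item *differentiated*: steady with dominance ratio (top mean over
#'     second mean) at least `dominance_ratio`; under an AND gate a
#'     co-dominant *pair* (two means within a factor 2 of each other, both at
#'     least `dominance_ratio` times the third) also counts;
#'   \item *undetermined*: anything in between (amplitude inside the
#'     hysteresis band between steady and oscillatory, or steady but neither
#'     equal nor dominated).
#' }
#'
#' @param osc_rel_amp relative amplitude above which a gene counts as
#'   oscillating (default 0.05).
#' @param steady_rel_amp relative amplitude below which the trajectory counts
#'   as steady (default 0.001).
#' @param equal_tol relative tolerance for "all means equal" (default 0.05).
#' @param dominance_ratio top/second mean ratio defining dominance
#'   (default 3).
#' @param hysteresis relative band used by [dwell_times()] to suppress
#'   chatter at sub-state crossings (default 0.02).
#' @param min_peaks minimum detected peaks for the oscillatory label
#'   (default 3).
#' @return named list of thresholds.
#' @export
cfr_thresholds <- function(osc_rel_amp = 0.05, steady_rel_amp = 0.001,
                           equal_tol = 0.05, dominance_ratio = 3,
                           hysteresis = 0.02, min_peaks = 3) {
  list(osc_rel_amp = osc_rel_amp, steady_rel_amp = steady_rel_amp,
       equal_tol = equal_tol, dominance_ratio = dominance_ratio,
       hysteresis = hysteresis, min_peaks = min_peaks)
}

#' Classify a trajectory into a response mode
#'
#' Assigns one of the model's three response modes — `multipotent` (all
#' transcription factors co-expressed at a common steady level),
#' `oscillatory` (sustained cycling through fate-biased sub-states), or
#' `differentiated` (a winner-take-all steady state with one gene, or one
#' AND-gate pair, dominant) — or `undetermined` when the trajectory sits
#' inside the hysteresis band between categories. Classification is defined
#' at constant coupling; trajectories under a ramp are refused unless
#' classified piecewise via [classify_piecewise()].
#'
#' @param traj a `cfr_trajectory` with a constant coupling schedule (or a
#'   constant tail; see `from`).
#' @param transient_fraction fraction of the horizon discarded as transient
#'   (default 0.5).
#' @param thresholds see [cfr_thresholds()].
#' @param from optional absolute time from which to analyze (overrides
#'   `transient_fraction`).
#' @return A `cfr_regime`: list with `label`, per-gene `means` and
#'   `amplitudes`, `period` (oscillatory only), `dominant` (gene index or
#'   pair, differentiated only), `dwell` (dwell-time table, oscillatory
#'   only), the `thresholds` used and the analysis `window`.
#' @examples
#' p <- cfr_preset("repressilator")
#' traj <- simulate_network(p$network, p$schedule, x0 = c(1, 1.05, 0.95),
#'                          t_max = 120, n_out = 1500)
#' classify_regime(traj)$label
#' @export
classify_regime <- function(traj, transient_fraction = 0.5,
                            thresholds = cfr_thresholds(), from = NULL) {
  stopifnot(inherits(traj, "cfr_trajectory"))
  g <- traj$g
  if (is.null(from)) {
    if (diff(range(g)) > 1e-12 * max(abs(g), 1)) {
      stop("coupling varies along this trajectory; classify at constant g ",
           "or use classify_piecewise()", call. = FALSE)
    }
    t0 <- traj$times[1]
    from <- t0 + transient_fraction * (max(traj$times) - t0)
  }
  win <- traj_window(traj, from = from)
  classify_window(win, traj, thresholds, from)
}

# internal: classification decision rules on an already-windowed trajectory.
# Under a ramp (detrend = TRUE) amplitudes are measured on residuals from a
# per-gene linear fit, so that the drift of the moving equilibrium is not
# mistaken for oscillation, and the steady threshold is relaxed to the
# oscillation threshold (windows between regimes come out undetermined).
classify_window <- function(win, full_traj, thresholds, from,
                            detrend = FALSE) {
  X <- win$x
  n <- ncol(X)
  means <- colMeans(X)
  if (detrend) {
    tt <- win$times - mean(win$times)
    Xd <- apply(X, 2, function(v) stats::lm.fit(cbind(1, tt), v)$residuals)
    amps <- apply(Xd, 2, function(v) max(v) - min(v))
  } else {
    amps <- apply(X, 2, function(v) max(v) - min(v))
  }
  rel <- amps / pmax(means, .Machine$double.eps)
  th <- thresholds
  if (detrend) th$steady_rel_amp <- th$osc_rel_amp

  label <- "undetermined"
  period <- NULL
  dominant <- NULL
  dwell <- NULL

  if (max(rel) >= th$osc_rel_amp) {
    lead <- which.max(amps)
    pk <- find_peaks(win$times, if (detrend) Xd[, lead] else X[, lead])
    if (length(pk$t) >= th$min_peaks) {
      label <- "oscillatory"
      period <- stats::median(diff(pk$t))
      if (!detrend) {
        dwell <- suppressWarnings(
          dwell_times(full_traj, from = from, hysteresis = th$hysteresis))
      }
    }
  } else if (max(rel) < th$steady_rel_amp) {
    s <- sort(means, decreasing = TRUE)
    if ((max(means) - min(means)) <= th$equal_tol * mean(means)) {
      label <- "multipotent"
    } else if (full_traj$network$gate == "AND" && n >= 3 &&
               s[2] >= th$dominance_ratio * max(s[3], .Machine$double.eps) &&
               s[1] <= 2 * s[2]) {
      label <- "differentiated"
      dominant <- sort(unname(order(means, decreasing = TRUE)[1:2]))
    } else if (s[1] >= th$dominance_ratio * max(s[2], .Machine$double.eps)) {
      label <- "differentiated"
      dominant <- unname(which.max(means))
    }
  }

  structure(
    list(label = label, means = means, amplitudes = amps,
         relative_amplitudes = rel, period = period, dominant = dominant,
         dwell = dwell, thresholds = th,
         window = c(from = from, to = max(win$times)),
         g = win$g[1]),
    class = "cfr_regime"
  )
}

#' Piecewise classification along a coupling ramp
#'
#' Splits a ramped trajectory into `n_windows` equal time windows, treats the
#' coupling as locally constant in each, and classifies each window (with no
#' additional transient discard). Used to verify the temporal sequence
#' multipotent -> oscillatory -> differentiated along a slow ramp.
#'
#' @param traj a `cfr_trajectory`.
#' @param n_windows number of windows (default 8).
#' @param thresholds see [cfr_thresholds()].
#' @return data frame with one row per window: `t_from`, `t_to`, `g_mid`,
#'   `label`.
#' @export
classify_piecewise <- function(traj, n_windows = 8,
                               thresholds = cfr_thresholds()) {
  stopifnot(inherits(traj, "cfr_trajectory"))
  edges <- seq(min(traj$times), max(traj$times), length.out = n_windows + 1)
  out <- lapply(seq_len(n_windows), function(k) {
    win <- traj_window(traj, edges[k], edges[k + 1])
    rep <- classify_window(win, traj, thresholds, edges[k], detrend = TRUE)
    data.frame(t_from = edges[k], t_to = edges[k + 1],
               g_mid = g_at(traj$schedule, (edges[k] + edges[k + 1]) / 2),
               label = rep$label)
  })
  do.call(rbind, out)
}

#' Sub-state dwell times
#'
#' Partitions the post-transient window into contiguous fate-biased
#' sub-states. Under an OR gate a sub-state is the currently dominant
#' (argmax) gene; under an AND gate it is the currently co-dominant top-two
#' gene pair. A relative hysteresis band suppresses chatter: the incumbent
#' keeps the sub-state until a challenger exceeds the relevant incumbent
#' level by the band; an exact tie resolves to the incumbent. Sub-states tile
#' the analyzed window without gaps, so their fractions sum to one.
#'
#' @param traj a `cfr_trajectory`.
#' @param transient_fraction fraction of the horizon discarded (default 0.5).
#' @param hysteresis relative hysteresis band (default 0.02).
#' @param from optional absolute start time (overrides `transient_fraction`).
#' @return data frame with columns `substate` (e.g. `"2"` or `"1+3"`),
#'   `t_entry`, `t_exit`, `duration`; the per-sub-state fractions of total
#'   classified time are attached as attribute `"fractions"`, and the cyclic
#'   order of first appearance as attribute `"order"`. Zero rows (with a
#'   warning) if no dominance crossings occur.
#' @examples
#' p <- cfr_preset("double-or")
#' traj <- simulate_network(p$network, p$schedule,
#'                          x0 = perturbed_start(p$network, 0.15, seed = 1),
#'                          t_max = 400, n_out = 4000)
#' dw <- dwell_times(traj)
#' attr(dw, "fractions")
#' @export
dwell_times <- function(traj, transient_fraction = 0.5, hysteresis = 0.02,
                        from = NULL) {
  stopifnot(inherits(traj, "cfr_trajectory"))
  if (is.null(from)) {
    t0 <- traj$times[1]
    from <- t0 + transient_fraction * (max(traj$times) - t0)
  }
  win <- traj_window(traj, from = from)
  X <- win$x
  tt <- win$times
  m <- nrow(X)
  pair_mode <- traj$network$gate == "AND"

  state_id <- character(m)
  if (pair_mode) {
    cur <- sort(order(X[1, ], decreasing = TRUE)[1:2])
    for (k in seq_len(m)) {
      top2 <- order(X[k, ], decreasing = TRUE)[1:2]
      cand <- sort(top2)
      if (!identical(cand, cur)) {
        entering <- setdiff(cand, cur)
        leaving <- setdiff(cur, cand)
        # switch only when every entering gene clearly beats the gene it evicts
        if (length(entering) > 0 &&
            min(X[k, entering]) > max(X[k, leaving]) * (1 + hysteresis)) {
          cur <- cand
        }
      }
      state_id[k] <- paste(cur, collapse = "+")
    }
  } else {
    cur <- which.max(X[1, ])
    for (k in seq_len(m)) {
      cand <- which.max(X[k, ])
      if (cand != cur && X[k, cand] > X[k, cur] * (1 + hysteresis)) {
        cur <- cand
      }
      state_id[k] <- as.character(cur)
    }
  }

  runs <- rle(state_id)
  nruns <- length(runs$lengths)
  if (nruns <= 1L) {
    warning("no sub-state crossings detected in the analyzed window",
            call. = FALSE)
    out <- data.frame(substate = character(0), t_entry = numeric(0),
                      t_exit = numeric(0), duration = numeric(0))
    attr(out, "fractions") <- numeric(0)
    attr(out, "order") <- character(0)
    return(out)
  }
  ends <- cumsum(runs$lengths)
  starts <- c(1L, ends[-nruns] + 1L)
  # boundaries midway between the last sample of one run and the first of the next
  bounds <- c(tt[1], (tt[ends[-nruns]] + tt[starts[-1]]) / 2, tt[m])
  out <- data.frame(
    substate = runs$values,
    t_entry = bounds[-(nruns + 1)],
    t_exit = bounds[-1]
  )
  out$duration <- out$t_exit - out$t_entry
  fr <- tapply(out$duration, out$substate, sum) / sum(out$duration)
  attr(out, "fractions") <- fr[order(names(fr))]
  attr(out, "order") <- unique(runs$values)
  out
}

#' Oscillation period
#'
#' Median peak-to-peak interval of one gene's post-transient expression.
#' Errors on non-oscillatory input.
#'
#' @param traj a `cfr_trajectory`.
#' @param gene gene index measured (default 1).
#' @param transient_fraction fraction of horizon discarded (default 0.5).
#' @param min_peaks minimum number of peaks required (default 3).
#' @return period in model time units.
#' @export
oscillation_period <- function(traj, gene = 1, transient_fraction = 0.5,
                               min_peaks = 3) {
  stopifnot(inherits(traj, "cfr_trajectory"))
  t0 <- traj$times[1]
  win <- traj_window(traj, from = t0 + transient_fraction *
                       (max(traj$times) - t0))
  v <- win$x[, gene]
  if ((max(v) - min(v)) < 0.05 * max(mean(v), .Machine$double.eps)) {
    stop("period undefined: gene ", gene, " is not oscillating", call. = FALSE)
  }
  pk <- find_peaks(win$times, v)
  if (length(pk$t) < min_peaks) {
    stop("period undefined: fewer than ", min_peaks, " peaks detected",
         call. = FALSE)
  }
  stats::median(diff(pk$t))
}

# internal: local maxima with a prominence filter and quadratic refinement
# of the peak time (the reporting grid quantizes raw peak locations)
find_peaks <- function(t, v, prominence = 0.2) {
  m <- length(v)
  if (m < 3) return(list(t = numeric(0), v = numeric(0)))
  span <- max(v) - min(v)
  idx <- which(v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] >= v[3:m]) + 1L
  idx <- idx[v[idx] > min(v) + prominence * span]
  if (length(idx) == 0) return(list(t = numeric(0), v = numeric(0)))
  tp <- vapply(idx, function(i) {
    if (i <= 1L || i >= m) return(t[i])
    y0 <- v[i - 1]; y1 <- v[i]; y2 <- v[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den >= 0) return(t[i])
    dt <- (t[i + 1] - t[i - 1]) / 2
    t[i] + 0.5 * (y0 - y2) / den * dt
  }, numeric(1))
  list(t = tp, v = v[idx])
}

#' @export
print.cfr_regime <- function(x, ...) {
  cat(sprintf("<cfr_regime> %s (g = %.4g)\n", x$label, x$g))
  cat("  means:", paste(signif(x$means, 4), collapse = ", "), "\n")
  cat("  amplitudes:", paste(signif(x$amplitudes, 4), collapse = ", "), "\n")
  if (!is.null(x$period)) cat(sprintf("  period: %.4g\n", x$period))
  if (!is.null(x$dominant)) {
    cat("  dominant:", paste(x$dominant, collapse = "+"), "\n")
  }
  if (!is.null(x$dwell)) {
    fr <- attr(x$dwell, "fractions")
    cat("  dwell fractions:",
        paste(sprintf("%s=%.3f", names(fr), fr), collapse = " "), "\n")
  }
  invisible(x)
}

#' Serialize a regime report to JSON
#'
#' @param report a `cfr_regime`.
#' @param path optional output path; if omitted the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
regime_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "cfr_regime"))
  obj <- list(
    label = report$label,
    g = report$g,
    means = report$means,
    amplitudes = report$amplitudes,
    period = report$period,
    dominant = report$dominant,
    dwell_fractions = as.list(attr(report$dwell, "fractions")),
    thresholds = report$thresholds,
    window = as.list(report$window)
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write a dwell-time table to CSV
#'
#' @param dwell the data frame returned by [dwell_times()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dwell_csv <- function(dwell, path) {
  utils::write.csv(dwell, path, row.names = FALSE)
  invisible(path)
}
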