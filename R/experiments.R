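#' Empirical end of the oscillatory regime
#'
#' Estimates the coupling value at which the limit cycle disappears, by
#' quasi-static continuation: starting from an on-cycle state in the middle
#' of the oscillatory window, the coupling is increased in small multiplicative
#' steps, carrying the final state forward, until the trajectory collapses
#' onto a fate-specialized equilibrium; the collapse point is then refined by
#' bisection. In this model family the cycle typically survives well beyond
#' the coupling at which the winner-take-all states first become stable
#' (a bistable overlap), so the *oscillatory boundary* relevant to fate
#' selection under a slow ramp is this cycle-death coupling, not the
#' winner-take-all onset; both are reported by the experiment layer.
#'
#' @param net a rotationally symmetric `cfr_network`.
#' @param boundaries optional precomputed [regime_boundaries()] result.
#' @param seed seed for the on-cycle starting perturbation (default 1).
#' @param step multiplicative continuation step (default 1.04).
#' @param t_each horizon integrated at each continuation level (default 200).
#' @param tol_rel relative bisection width (default 0.005).
#' @return list with `g_exit`, the final `bracket`, and the `g_upper` /
#'   `g_lower` of the underlying boundary analysis.
#' @export
oscillation_end <- function(net, boundaries = NULL, seed = 1, step = 1.04,
                            t_each = 200, tol_rel = 0.005) {
  if (is.null(boundaries)) boundaries <- regime_boundaries(net)
  g_lo <- boundaries$g_lower
  if (is.na(g_lo)) {
    stop("no oscillation onset found; cannot locate the oscillatory exit",
         call. = FALSE)
  }
  g_hi0 <- if (!is.na(boundaries$g_upper)) boundaries$g_upper else g_lo
  g_mid <- sqrt(g_lo * max(g_hi0, g_lo * 2))
  x <- perturbed_start(net, g_mid, seed = seed, rel = 0.2)

  diff_at <- function(g, x) {
    tr <- simulate_network(net, coupling_schedule("constant", g), x,
                           t_max = t_each, n_out = 800)
    list(label = classify_regime(tr, transient_fraction = 0.6)$label,
         x = tr$x[nrow(tr$x), ])
  }
  g <- g_mid
  x_osc <- x
  g_osc <- g_mid
  found <- FALSE
  while (g < g_hi0 * 40) {
    g <- g * step
    r <- diff_at(g, x_osc)
    if (r$label == "differentiated") { found <- TRUE; break }
    x_osc <- r$x
    g_osc <- g
  }
  if (!found) {
    return(list(g_exit = NA_real_, bracket = c(g_osc, NA_real_),
                g_lower = g_lo, g_upper = boundaries$g_upper))
  }
  lo <- g_osc; hi <- g
  while ((hi - lo) / hi > tol_rel) {
    mid <- sqrt(lo * hi)
    r <- diff_at(mid, x_osc)
    if (r$label == "differentiated") hi <- mid else { lo <- mid; x_osc <- r$x }
  }
  list(g_exit = (lo + hi) / 2, bracket = c(lo, hi),
       g_lower = g_lo, g_upper = boundaries$g_upper)
}

#' Wild-type cycling order of the fate sub-states
#'
#' Measures the deterministic cyclic order in which singleton sub-states are
#' visited during a sustained oscillation at constant coupling. Used to
#' define the "preceding" sub-state in knockout comparisons and the successor
#' map of the fate predictor.
#'
#' @param net a `cfr_network`.
#' @param g constant coupling inside the oscillatory window.
#' @param seed seed for the starting perturbation (default 1).
#' @param t_max horizon (default 400).
#' @return integer vector giving the cyclic visiting order, starting from
#'   gene 1.
#' @export
cycling_order <- function(net, g, seed = 1, t_max = 400) {
  if (net$gate != "OR") {
    stop("cycling_order is defined for singleton (OR-gate) sub-states",
         call. = FALSE)
  }
  x0 <- perturbed_start(net, g, seed = seed)
  tr <- simulate_network(net, coupling_schedule("constant", g), x0,
                         t_max = t_max, n_out = 4000)
  dw <- dwell_times(tr)
  seqs <- as.integer(dw$substate)
  if (length(unique(seqs)) < net$n_genes) {
    stop("not all sub-states visited; is g inside the oscillatory window?",
         call. = FALSE)
  }
  k1 <- which(seqs == 1L)[1]
  ord <- seqs[k1:(k1 + net$n_genes - 1L)]
  if (anyDuplicated(ord)) {
    stop("sub-state sequence is not a simple cycle", call. = FALSE)
  }
  ord
}

# internal: successor map fate -> next fate in the cycling order
successor_map <- function(ord) {
  stats::setNames(c(ord[-1], ord[1]), ord)
}

# internal: per-run reproducible sub-seeds from a master seed
derive_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Coupling-ramp fate-choice ensemble
#'
#' Simulates an ensemble of cells driven from the multipotent regime through
#' the oscillatory window into differentiation by a slowly increasing global
#' coupling, and summarizes the distribution of adopted fates. Initial
#' conditions are seeded perturbations of the symmetric state.
#'
#' For each run the expression state is recorded at the boundary crossings
#' of interest: the quasi-static oscillatory exit (cycle death, see
#' [oscillation_end()]), the winner-take-all onset, and the *dynamic* exit
#' of the protocol, which lags the static one because a finite ramp rate
#' delays the cycle's collapse. The dynamic crossing is calibrated from a
#' cohort of 20 pilot runs under the same ramp (their seeds come from the
#' same master stream but are never scored): the crossing is the centre of
#' the window in which every pilot still faces exactly one inter-sub-state
#' transition, between the latest penultimate-dwell entry and the earliest
#' final-dwell entry. The *predicted* fate of each run is the successor —
#' in the empirically measured cycling order — of its dominant gene at that
#' dynamic crossing, because capture into a fate basin occurs during the
#' final inter-sub-state transition; the agreement between this prediction
#' and the realized fates is reported.
#'
#' @param net a rotationally symmetric `cfr_network`.
#' @param ramp optional `cfr_schedule`; by default a linear ramp spanning 20
#'   oscillation periods between the oscillation onset and exit, from half
#'   the onset coupling to 20% past the exit.
#' @param n_runs ensemble size (default 300).
#' @param seed master seed; per-run seeds are derived reproducibly.
#' @param thresholds classification thresholds.
#' @param settle extra horizon at the final coupling before classification
#'   (default 80 time units).
#' @param ic_net network used to construct initial conditions (defaults to
#'   `net`; pass the wild-type when running a knockout ensemble so that
#'   wild-type and mutant runs are seed-paired).
#' @param boundaries,exit optional precomputed [regime_boundaries()] /
#'   [oscillation_end()] results (recomputed otherwise).
#' @return A `cfr_ensemble`: list with per-run data frame `runs` (seed, final
#'   label, fate, predicted fate, argmax at the exit and winner-take-all
#'   crossings, commitment time), fate `counts` and `proportions` with exact
#'   binomial 95% confidence intervals, `predictor_agreement`,
#'   `chisq_uniform_p`, the number of undetermined runs, and protocol
#'   metadata.
#' @examples
#' \donttest{
#' net <- cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1)
#' ens <- ramp_ensemble(net, n_runs = 20, seed = 7)
#' ens$proportions
#' }
#' @export
ramp_ensemble <- function(net, ramp = NULL, n_runs = 300, seed = 1,
                          thresholds = cfr_thresholds(), settle = 80,
                          ic_net = net, boundaries = NULL, exit = NULL) {
  if (is.null(exit)) {
    if (is.null(boundaries)) boundaries <- regime_boundaries(ic_net)
    exit <- oscillation_end(ic_net, boundaries, seed = seed)
  }
  g_lower <- exit$g_lower
  g_exit <- exit$g_exit
  if (is.na(g_exit)) {
    stop("oscillatory exit not found; the ramp cannot cross it", call. = FALSE)
  }
  g_mid <- sqrt(g_lower * g_exit)
  period <- {
    tr <- simulate_network(ic_net, coupling_schedule("constant", g_mid),
                           perturbed_start(ic_net, g_mid, seed), t_max = 200,
                           n_out = 2000)
    oscillation_period(tr)
  }
  ord <- cycling_order(ic_net, g_mid, seed = seed)
  succ <- successor_map(ord)
  if (is.null(ramp)) {
    g0 <- g_lower / 2
    g1 <- g_exit * 1.2
    rate <- (g_exit - g_lower) / (20 * period)
    ramp <- coupling_schedule("linear_ramp", g0, g1,
                              t_start = 0, t_end = (g1 - g0) / rate)
  }
  if (is.na(time_of_g(ramp, g_exit))) {
    stop("the ramp never crosses the oscillatory exit boundary g_exit = ",
         signif(g_exit, 4), call. = FALSE)
  }
  t_cross_static <- time_of_g(ramp, g_exit)
  t_cross_wta <- if (!is.na(exit$g_upper)) time_of_g(ramp, exit$g_upper)
    else NA_real_
  t_end <- ramp$t_end
  horizon <- t_end + settle
  n <- net$n_genes
  R <- thresholds$dominance_ratio

  n_pilots <- 20L
  all_seeds <- derive_seeds(seed, n_runs + n_pilots)
  seeds <- if (n_runs > 0) all_seeds[seq_len(n_runs)] else integer(0)

  # The ramp rate delays the cycle's collapse past the quasi-static exit, so
  # the boundary crossing is calibrated dynamically from a pilot cohort
  # whose seeds are never reused for scored runs. For each pilot the final
  # dwell is its adopted fate and the penultimate dwell its last oscillatory
  # sub-state; the crossing is placed centrally in the window in which every
  # pilot still faces exactly one inter-sub-state transition: between the
  # latest penultimate-dwell entry and the earliest final-dwell entry.
  t_pen <- t_fin <- rep(NA_real_, n_pilots)
  for (k in seq_len(n_pilots)) {
    x0p <- perturbed_start(ic_net, g_at(ramp, 0),
                           all_seeds[n_runs + k])
    x0p[net$knockout] <- 0
    pilot <- simulate_network(net, ramp, x0p, t_max = horizon, n_out = 2500)
    pdw <- suppressWarnings(dwell_times(pilot, from = pilot$times[1],
                                        hysteresis = thresholds$hysteresis))
    if (nrow(pdw) >= 2) {
      t_pen[k] <- pdw$t_entry[nrow(pdw) - 1L]
      t_fin[k] <- pdw$t_entry[nrow(pdw)]
    }
  }
  t_cross <- if (all(is.na(t_pen))) t_cross_static else
    (max(t_pen, na.rm = TRUE) + min(t_fin, na.rm = TRUE)) / 2
  g_cross <- g_at(ramp, t_cross)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    x0 <- perturbed_start(ic_net, g_at(ramp, 0), seeds[i])
    x0[net$knockout] <- 0
    tr <- simulate_network(net, ramp, x0, t_max = horizon, n_out = 2500)
    fin <- classify_regime(tr, thresholds = thresholds,
                           from = t_end + settle * 0.4)
    state_at <- function(tq) {
      if (is.na(tq)) return(rep(NA_real_, n))
      apply(tr$x, 2, function(v) stats::approx(tr$times, v, tq)$y)
    }
    xc <- state_at(t_cross)
    xs_static <- state_at(t_cross_static)
    xw <- state_at(t_cross_wta)
    am <- unname(which.max(xc))
    fate <- if (fin$label == "differentiated") fin$dominant[1] else NA_integer_
    ratio <- apply(tr$x, 1, function(r) {
      s <- sort(r, decreasing = TRUE)
      s[1] / max(s[2], .Machine$double.eps)
    })
    t_commit <- commitment_time(tr$times, ratio, R)
    rows[[i]] <- data.frame(
      seed = seeds[i], label = fin$label, fate = fate,
      argmax_cross = am, predicted = unname(succ[as.character(am)]),
      argmax_exit = unname(which.max(xs_static)),
      argmax_wta = if (all(is.na(xw))) NA_integer_ else unname(which.max(xw)),
      t_commit = t_commit
    )
  }
  runs <- if (n_runs > 0) do.call(rbind, rows) else
    data.frame(seed = integer(0), label = character(0), fate = integer(0),
               argmax_cross = integer(0), predicted = integer(0),
               argmax_exit = integer(0), argmax_wta = integer(0),
               t_commit = numeric(0))

  fates <- factor(runs$fate, levels = seq_len(n))
  counts <- table(fates)
  n_diff <- sum(!is.na(runs$fate))
  props <- if (n_diff > 0) as.numeric(counts) / n_diff else rep(NA_real_, n)
  ci <- t(vapply(seq_len(n), function(k) {
    if (n_diff == 0) return(c(NA_real_, NA_real_))
    as.numeric(stats::binom.test(as.integer(counts[k]), n_diff)$conf.int)
  }, numeric(2)))
  chisq_p <- if (n_diff > 0)
    suppressWarnings(stats::chisq.test(as.numeric(counts))$p.value)
    else NA_real_
  agree <- if (n_diff > 0)
    mean(runs$predicted[!is.na(runs$fate)] == runs$fate[!is.na(runs$fate)])
    else NA_real_

  structure(
    list(runs = runs, counts = as.numeric(counts), proportions = props,
         conf_int = ci, chisq_uniform_p = chisq_p,
         predictor_agreement = agree,
         n_undetermined = sum(is.na(runs$fate)),
         cycling_order = ord, period = period,
         g_lower = g_lower, g_exit = g_exit, g_upper = exit$g_upper,
         g_cross = g_cross, t_cross = t_cross,
         ramp = ramp, seed = seed, n_runs = n_runs),
    class = "cfr_ensemble"
  )
}

# internal: first time from which top/second dominance >= R holds for a
# contiguous stretch of at least 5% of the horizon
commitment_time <- function(times, ratio, R) {
  ok <- ratio >= R
  if (!any(ok)) return(NA_real_)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  span <- 0.05 * (times[length(times)] - times[1])
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && times[ends[k]] - times[starts[k]] >= span) {
      return(times[starts[k]])
    }
  }
  NA_real_
}

#' @export
print.cfr_ensemble <- function(x, ...) {
  cat(sprintf("<cfr_ensemble> %d runs (%d undetermined), seed %d\n",
              x$n_runs, x$n_undetermined, x$seed))
  cat("  fate proportions:",
      paste(sprintf("%d=%.3f", seq_along(x$proportions), x$proportions),
            collapse = " "), "\n")
  cat(sprintf("  predictor agreement %.3f | chi-square uniformity p = %.3g\n",
              x$predictor_agreement, x$chisq_uniform_p))
  cat("  cycling order:", paste(x$cycling_order, collapse = " -> "), "\n")
  invisible(x)
}

#' Fate-specific signal-driven exit from the oscillatory regime
#'
#' With the coupling held constant inside the oscillatory window, a
#' fate-specific production boost is applied to one gene, starting at a set
#' of onset phases spread over one oscillation period. Above a threshold
#' amplitude the boost captures the cycle and commits every phase to the
#' target fate; below it the oscillation persists. The threshold is bracketed
#' by bisection between the largest all-persist and smallest all-commit
#' amplitudes tested.
#'
#' @param net a `cfr_network`.
#' @param g constant coupling inside the oscillatory window (verified).
#' @param target index of the signalled gene (default 1).
#' @param n_phases onset phases tested, spread over one period (default 20).
#' @param amp_range initial amplitude search range (default `c(0.05, 2) *`
#'   max production).
#' @param seed seed for the reference oscillation (default 1).
#' @param horizon post-onset integration horizon (default 150).
#' @param thresholds classification thresholds.
#' @return A `cfr_signal_exit`: list with the threshold `bracket`, the
#'   commit-fraction `table` over tested amplitudes, the zero-amplitude
#'   label, and protocol metadata.
#' @export
signal_exit <- function(net, g, target = 1, n_phases = 20,
                        amp_range = NULL, seed = 1, horizon = 150,
                        thresholds = cfr_thresholds()) {
  ref <- simulate_network(net, coupling_schedule("constant", g),
                          perturbed_start(net, g, seed), t_max = 400,
                          n_out = 4000)
  base <- classify_regime(ref, thresholds = thresholds)
  if (base$label != "oscillatory") {
    stop("the unsignalled system is not oscillatory at g = ", g,
         " (label: ", base$label, ")", call. = FALSE)
  }
  period <- base$period
  t_ref <- max(ref$times) * 0.75
  phases <- seq(0, period, length.out = n_phases + 1)[seq_len(n_phases)]
  x_at <- function(tq) apply(ref$x, 2, function(v)
    stats::approx(ref$times, v, tq)$y)

  commit_frac <- function(amp) {
    if (amp == 0) return(0)
    ok <- 0
    for (ph in phases) {
      x0 <- x_at(t_ref + ph)
      tr <- simulate_network(net, coupling_schedule("constant", g), x0,
                             t_max = horizon,
                             signals = signal_protocol(target, amp),
                             n_out = 1200)
      r <- classify_regime(tr, transient_fraction = 0.6,
                           thresholds = thresholds)
      if (r$label == "differentiated" && target %in% r$dominant) ok <- ok + 1
    }
    ok / n_phases
  }

  if (is.null(amp_range)) amp_range <- c(0.05, 2) * max(net$production_max)
  amps <- exp(seq(log(amp_range[1]), log(amp_range[2]), length.out = 7))
  fracs <- vapply(amps, commit_frac, numeric(1))
  tested <- data.frame(amplitude = amps, commit_fraction = fracs)
  if (!any(fracs == 1)) {
    stop("no amplitude in range committed all phases; widen amp_range",
         call. = FALSE)
  }
  k <- which(fracs == 1)[1]
  if (k == 1L) {
    lo <- amp_range[1] / 4; hi <- amps[1]
  } else {
    lo <- amps[k - 1]; hi <- amps[k]
  }
  for (it in 1:8) {
    mid <- sqrt(lo * hi)
    fm <- commit_frac(mid)
    tested <- rbind(tested, data.frame(amplitude = mid, commit_fraction = fm))
    if (fm == 1) hi <- mid else lo <- mid
  }

  zero_traj <- simulate_network(net, coupling_schedule("constant", g),
                                x_at(t_ref), t_max = horizon,
                                signals = signal_protocol(target, 0),
                                n_out = 1200)
  zero_label <- classify_regime(zero_traj, transient_fraction = 0.6,
                                thresholds = thresholds)$label

  structure(
    list(bracket = c(lo, hi), tested = tested[order(tested$amplitude), ],
         zero_label = zero_label, g = g, target = target,
         n_phases = n_phases, period = period, seed = seed,
         horizon = horizon),
    class = "cfr_signal_exit"
  )
}

#' @export
print.cfr_signal_exit <- function(x, ...) {
  cat(sprintf("<cfr_signal_exit> target gene %d at g = %.4g\n", x$target, x$g))
  cat(sprintf("  commitment threshold in (%.4g, %.4g] over %d phases\n",
              x$bracket[1], x$bracket[2], x$n_phases))
  cat(sprintf("  amplitude 0 -> %s\n", x$zero_label))
  invisible(x)
}

#' In-silico knockout experiment
#'
#' Compares wild-type and null-allele mutant behaviour in one of two
#' contexts, with seed-paired initial conditions:
#' \describe{
#'   \item{`"dwell"`}{at constant coupling in the wild-type oscillatory
#'     window, compares sub-state dwell fractions. The prediction tested is
#'     that the mutant lingers in the sub-state *preceding* the knocked-out
#'     gene's sub-state in the empirically measured wild-type cycling order,
#'     and — in networks whose remaining repression web still contains an
#'     effective cycle — keeps cycling through the remaining sub-states
#'     rather than freezing. If the mutant is no longer oscillatory, the
#'     regime change is reported rather than hidden.}
#'   \item{`"ramp"`}{paired coupling-ramp ensembles ([ramp_ensemble()] with
#'     identical seeds). The mutant's commitment to the knocked-out fate and
#'     the reallocation of that fate's share across the remaining fates are
#'     summarized.}
#' }
#'
#' @param net the wild-type `cfr_network` (rotationally symmetric).
#' @param gene gene index to knock out.
#' @param context `"dwell"` or `"ramp"`.
#' @param g constant coupling for the dwell context (default: geometric
#'   mid-window from the boundary analysis).
#' @param seed master seed.
#' @param n_runs ensemble size for the ramp context (default 100).
#' @param t_max horizon for the dwell context (default 600).
#' @param thresholds classification thresholds.
#' @return A `cfr_knockout` report; its fields depend on context. Both
#'   contexts include the wild-type cycling order and the index of the
#'   preceding gene. The dwell context reports paired dwell fractions,
#'   `lingers` (mutant preceding-fraction strictly above wild-type) and
#'   `cycling_continues`; the ramp context reports paired fate proportions,
#'   the mutant share of the knocked-out fate, and the per-fate reallocation.
#' @export
knockout_experiment <- function(net, gene, context = c("dwell", "ramp"),
                                g = NULL, seed = 1, n_runs = 100,
                                t_max = 600, thresholds = cfr_thresholds()) {
  context <- match.arg(context)
  if (any(net$knockout)) {
    stop("`net` must be the wild-type network", call. = FALSE)
  }
  mut <- knockout_genes(net, gene)

  if (context == "dwell") {
    if (is.null(g)) {
      bd <- regime_boundaries(net)
      g <- if (!is.na(bd$g_upper) && bd$g_upper > bd$g_lower) {
        sqrt(bd$g_lower * bd$g_upper)
      } else {
        2 * bd$g_lower
      }
    }
    x0 <- perturbed_start(net, g, seed)
    sch <- coupling_schedule("constant", g)
    wt_traj <- simulate_network(net, sch, x0, t_max = t_max, n_out = 5000)
    wt_rep <- classify_regime(wt_traj, thresholds = thresholds)
    if (wt_rep$label != "oscillatory") {
      stop("wild-type is not oscillatory at g = ", g, call. = FALSE)
    }
    ord <- cycling_order(net, g, seed = seed, t_max = t_max)
    succ <- successor_map(ord)
    preceding <- as.integer(names(succ)[succ == gene])

    mut_traj <- simulate_network(mut, sch, x0, t_max = t_max, n_out = 5000)
    mut_rep <- classify_regime(mut_traj, thresholds = thresholds)
    wt_fr <- attr(wt_rep$dwell, "fractions")
    frac_of <- function(fr, idx) {
      v <- fr[as.character(idx)]
      if (is.na(v)) 0 else unname(v)
    }
    if (mut_rep$label != "oscillatory") {
      return(structure(
        list(context = "dwell", gene = gene, g = g, seed = seed,
             regime_change = mut_rep$label, wt_label = "oscillatory",
             cycling_order = ord, preceding = preceding,
             wt_fractions = wt_fr, mut_fractions = NULL,
             mut_dominant = mut_rep$dominant,
             lingers = NA, cycling_continues = FALSE),
        class = "cfr_knockout"
      ))
    }
    mut_dw <- mut_rep$dwell
    mut_fr <- attr(mut_dw, "fractions")
    mut_seq <- unique(mut_dw$substate)
    structure(
      list(context = "dwell", gene = gene, g = g, seed = seed,
           regime_change = NULL, wt_label = "oscillatory",
           cycling_order = ord, preceding = preceding,
           wt_fractions = wt_fr, mut_fractions = mut_fr,
           wt_preceding_fraction = frac_of(wt_fr, preceding),
           mut_preceding_fraction = frac_of(mut_fr, preceding),
           mut_ko_fraction = frac_of(mut_fr, gene),
           lingers = frac_of(mut_fr, preceding) > frac_of(wt_fr, preceding),
           cycling_continues = nrow(mut_dw) >= 6,
           mutant_order = mut_seq),
      class = "cfr_knockout"
    )
  } else {
    bd <- regime_boundaries(net)
    ex <- oscillation_end(net, bd, seed = seed)
    wt_ens <- ramp_ensemble(net, n_runs = n_runs, seed = seed,
                            thresholds = thresholds, boundaries = bd,
                            exit = ex)
    mut_ens <- ramp_ensemble(mut, ramp = wt_ens$ramp, n_runs = n_runs,
                             seed = seed, thresholds = thresholds,
                             ic_net = net, boundaries = bd, exit = ex)
    ord <- wt_ens$cycling_order
    succ <- successor_map(ord)
    preceding <- as.integer(names(succ)[succ == gene])
    realloc <- mut_ens$proportions - wt_ens$proportions
    structure(
      list(context = "ramp", gene = gene, seed = seed,
           cycling_order = ord, preceding = preceding,
           wt_proportions = wt_ens$proportions,
           mut_proportions = mut_ens$proportions,
           mut_ko_share = mut_ens$proportions[gene],
           reallocation = realloc,
           preceding_gains_most =
             which.max(replace(realloc, gene, -Inf)) == preceding,
           wt_ensemble = wt_ens, mut_ensemble = mut_ens),
      class = "cfr_knockout"
    )
  }
}

#' @export
print.cfr_knockout <- function(x, ...) {
  cat(sprintf("<cfr_knockout> gene %d, %s context\n", x$gene, x$context))
  cat("  wild-type cycling order:",
      paste(x$cycling_order, collapse = " -> "),
      sprintf("(preceding: %d)\n", x$preceding))
  if (x$context == "dwell") {
    if (!is.null(x$regime_change)) {
      cat("  mutant regime change:", x$regime_change)
      if (!is.null(x$mut_dominant)) {
        cat(" (dominant:", paste(x$mut_dominant, collapse = "+"), ")")
      }
      cat("\n")
    } else {
      cat(sprintf("  preceding dwell fraction: wt %.3f -> mutant %.3f (lingers: %s)\n",
                  x$wt_preceding_fraction, x$mut_preceding_fraction,
                  x$lingers))
      cat("  mutant keeps cycling:", x$cycling_continues, "\n")
    }
  } else {
    cat("  wt fate proportions: ",
        paste(sprintf("%.3f", x$wt_proportions), collapse = " "), "\n")
    cat("  mut fate proportions:",
        paste(sprintf("%.3f", x$mut_proportions), collapse = " "), "\n")
    cat(sprintf("  knocked-out fate share in mutant: %.3f; preceding fate gains most: %s\n",
                x$mut_ko_share, x$preceding_gains_most))
  }
  invisible(x)
}

#' Oscillation across network sizes and topologies
#'
#' Scans (network size, topology) cells over a grid of coupling values and
#' several seeded initial conditions, and reports whether sustained
#' oscillation was found anywhere on the grid. Reproduces the parity rule:
#' odd-size nearest-neighbour rings oscillate, even-size rings do not unless
#' repression also acts between non-neighbours.
#'
#' @param n_genes integer vector of network sizes (default `c(3, 4, 5)`).
#' @param topologies character vector among `"cyclic"`, `"ring_neighbors"`,
#'   `"all_pairs"`.
#' @param gate `"OR"` or `"AND"`.
#' @param g_grid coupling grid; defaults to a log grid suited to the gate
#'   (AND windows sit at much smaller g).
#' @param seeds initial-condition seeds per cell (default `1:2`).
#' @param coupling_reverse,coupling_extra strengths passed to
#'   [cfr_network()].
#' @param t_max horizon per run (default 400).
#' @return data frame with columns `n_genes`, `topology`, `gate`,
#'   `oscillates`, and `g_support` (comma-separated supporting couplings).
#' @export
topology_scan <- function(n_genes = c(3, 4, 5),
                          topologies = c("ring_neighbors", "all_pairs"),
                          gate = "OR", g_grid = NULL, seeds = 1:2,
                          coupling_reverse = 0.1, coupling_extra = 1,
                          t_max = 400) {
  if (is.null(g_grid)) {
    g_grid <- if (gate == "OR") {
      exp(seq(log(0.02), log(2), length.out = 8))
    } else {
      exp(seq(log(1e-5), log(0.1), length.out = 8))
    }
  }
  rows <- list()
  for (n in n_genes) {
    for (tp in topologies) {
      net <- try(cfr_network(n, tp, gate,
                             coupling_reverse = coupling_reverse,
                             coupling_extra =
                               if (tp == "all_pairs") coupling_extra else 0),
                 silent = TRUE)
      if (inherits(net, "try-error")) next
      support <- numeric(0)
      for (g in g_grid) {
        found <- FALSE
        for (s in seeds) {
          x0 <- perturbed_start(net, g, s)
          tr <- simulate_network(net, coupling_schedule("constant", g), x0,
                                 t_max = t_max, n_out = 2000)
          if (classify_regime(tr)$label == "oscillatory") {
            found <- TRUE
            break
          }
        }
        if (found) support <- c(support, g)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        n_genes = n, topology = tp, gate = gate,
        oscillates = length(support) > 0,
        g_support = paste(signif(support, 3), collapse = ",")
      )
    }
  }
  do.call(rbind, rows)
}

#' Serialize an ensemble summary to JSON, and its runs to CSV
#'
#' @param ens a `cfr_ensemble`.
#' @param path output path (`.json` for the summary, any for the CSV).
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(ens, path) {
  stopifnot(inherits(ens, "cfr_ensemble"))
  obj <- list(
    n_runs = ens$n_runs, seed = ens$seed,
    counts = ens$counts, proportions = ens$proportions,
    conf_int = ens$conf_int, chisq_uniform_p = ens$chisq_uniform_p,
    predictor_agreement = ens$predictor_agreement,
    n_undetermined = ens$n_undetermined,
    cycling_order = ens$cycling_order, period = ens$period,
    g_lower = ens$g_lower, g_exit = ens$g_exit, g_upper = ens$g_upper,
    g_cross = ens$g_cross,
    ramp = unclass(ens$ramp)[c("kind", "g_start", "g_end",
                               "t_start", "t_end")],
    seeds = ens$runs$seed
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              null = "null", na = "null"), path)
  invisible(path)
}

#' @rdname write_ensemble_json
#' @export
write_ensemble_csv <- function(ens, path) {
  stopifnot(inherits(ens, "cfr_ensemble"))
  utils::write.csv(ens$runs, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a knockout report to JSON
#'
#' @param rep a `cfr_knockout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_knockout_json <- function(rep, path) {
  stopifnot(inherits(rep, "cfr_knockout"))
  obj <- unclass(rep)
  obj$wt_ensemble <- NULL
  obj$mut_ensemble <- NULL
  if (!is.null(rep$wt_ensemble)) {
    obj$paired_runs <- data.frame(
      seed = rep$wt_ensemble$runs$seed,
      wt_fate = rep$wt_ensemble$runs$fate,
      mut_fate = rep$mut_ensemble$runs$fate
    )
  }
  if (!is.null(obj$wt_fractions)) obj$wt_fractions <- as.list(obj$wt_fractions)
  if (!is.null(obj$mut_fractions)) {
    obj$mut_fractions <- as.list(obj$mut_fractions)
  }
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              null = "null", na = "null"), path)
  invisible(path)
}
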