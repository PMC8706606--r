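#' Mutual-repression network specification
#'
#' Constructs and validates the specification of a mutual-repression
#' transcription-factor network: the generalized repressilator family used to
#' model cyclical fate restriction. Gene `i` is repressed by its upstream
#' neighbour `i-1` with per-edge strength `coupling_forward[i]`, and (for
#' topologies other than `"cyclic"`) by its downstream neighbour `i+1` with
#' strength `coupling_reverse[i]`. Under `"all_pairs"` every remaining gene
#' pair is connected with strength `coupling_extra`.
#'
#' All strengths are *relative*: the dynamical repression strength of edge
#' `j -> i` at time `t` is `g(t) * W[i, j]`, where `g(t)` comes from a
#' [coupling_schedule()] and `W` is the relative coupling matrix
#' (see [coupling_matrix()]).
#'
#' @param n_genes integer number of transcription-factor genes (>= 2).
#' @param topology one of `"cyclic"` (classic repressilator: single upstream
#'   repressor per gene), `"ring_neighbors"` (upstream and downstream
#'   neighbours), `"all_pairs"` (every other gene).
#' @param gate `"OR"` (any single high repressor inhibits) or `"AND"` (all
#'   repressors must be high). `"AND"` requires at least two repressors per
#'   gene and is therefore rejected for `topology = "cyclic"`.
#' @param coupling_forward scalar or length-`n_genes` vector of nonnegative
#'   strengths for the clockwise edges `i-1 -> i`.
#' @param coupling_reverse scalar or vector of strengths for the anticlockwise
#'   edges `i+1 -> i`; must be zero/absent for `"cyclic"`. Default 0.1 for
#'   non-cyclic topologies (a directional asymmetry; see Details).
#' @param coupling_extra strengths for non-neighbour pairs, indexed by cyclic
#'   distance: element `d - 1` is the strength of edges `j -> i` with
#'   `(i - j) mod n_genes == d`, for `d = 2 .. n_genes - 2`. A scalar is
#'   recycled over all distances. Required nonzero only for `"all_pairs"`
#'   with `n_genes > 3`. Default 1.
#' @param hill_coefficient Hill cooperativity exponent h > 0 (default 3).
#' @param production_max scalar or per-gene maximal production rate beta
#'   (expression units per time unit, default 10).
#' @param production_basal scalar or per-gene basal leak alpha0 >= 0
#'   (default 0.05).
#' @param degradation scalar or per-gene first-order decay rate (default 1;
#'   the model's time unit is one protein half-life over log(2)).
#' @param knockout logical vector marking null-allele genes whose production
#'   (both `production_max` and `production_basal`) is forced to zero.
#'
#' @details
#' The default `coupling_reverse = 0.1` encodes the directional asymmetry
#' between the two superimposed repression circuits of the double
#' repressilator. A perfectly bidirectionally symmetric coupling matrix makes
#' the Jacobian at any uniform state a symmetric matrix, whose real spectrum
#' forbids a Hopf bifurcation: such a network is multistable but cannot
#' oscillate. Unequal clockwise/anticlockwise strengths restore the rotating
#' instability while keeping the cyclic (rotational) symmetry that makes the
#' three fate sub-states equivalent.
#'
#' @return An object of class `cfr_network`.
#' @seealso [build_network()], [coupling_schedule()], [knockout_genes()],
#'   [cfr_preset()]
#' @examples
#' net <- cfr_network(3, "cyclic", "OR")
#' dbl <- cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1)
#' @export
cfr_network <- function(n_genes,
                        topology = c("cyclic", "ring_neighbors", "all_pairs"),
                        gate = c("OR", "AND"),
                        coupling_forward = 1,
                        coupling_reverse = NULL,
                        coupling_extra = NULL,
                        hill_coefficient = 3,
                        production_max = 10,
                        production_basal = 0.05,
                        degradation = 1,
                        knockout = NULL) {
  topology <- match.arg(topology)
  gate <- match.arg(gate)
  if (length(n_genes) != 1L || !is.finite(n_genes) || n_genes < 2 ||
      n_genes != round(n_genes)) {
    stop("`n_genes` must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n_genes)
  if (gate == "AND" && topology == "cyclic") {
    stop("gate = \"AND\" requires >= 2 repressors per gene; ",
         "topology = \"cyclic\" provides only one", call. = FALSE)
  }

  expand <- function(x, name, allow_zero = TRUE) {
    if (length(x) == 1L) x <- rep(as.numeric(x), n)
    if (length(x) != n) {
      stop(sprintf("`%s` must be a scalar or length-%d vector", name, n),
           call. = FALSE)
    }
    if (any(!is.finite(x)) || any(x < 0)) {
      stop(sprintf("`%s` must be finite and nonnegative", name), call. = FALSE)
    }
    if (!allow_zero && any(x == 0)) {
      stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
    }
    x
  }

  cf <- expand(coupling_forward, "coupling_forward")
  if (is.null(coupling_reverse)) {
    coupling_reverse <- if (topology == "cyclic") 0 else 0.1
  }
  cr <- expand(coupling_reverse, "coupling_reverse")
  if (topology == "cyclic" && any(cr > 0)) {
    stop("topology = \"cyclic\" requires all coupling_reverse == 0",
         call. = FALSE)
  }
  n_extra <- max(n - 3L, 0L)  # cyclic distances 2 .. n-2
  if (is.null(coupling_extra)) {
    coupling_extra <- if (topology == "all_pairs") 1 else 0
  }
  if (any(!is.finite(coupling_extra)) || any(coupling_extra < 0)) {
    stop("`coupling_extra` must be finite and nonnegative", call. = FALSE)
  }
  if (length(coupling_extra) == 1L) {
    cx <- rep(as.numeric(coupling_extra), max(n_extra, 1L))
  } else if (length(coupling_extra) == n_extra) {
    cx <- as.numeric(coupling_extra)
  } else {
    stop(sprintf(paste0("`coupling_extra` must be a scalar or a length-%d ",
                        "vector (one strength per cyclic distance 2..%d)"),
                 n_extra, n - 2L), call. = FALSE)
  }
  if (topology != "all_pairs" && any(cx > 0)) {
    stop("`coupling_extra` is only meaningful for topology = \"all_pairs\"",
         call. = FALSE)
  }
  if (topology == "all_pairs" && n > 3 && all(cx == 0)) {
    stop("topology = \"all_pairs\" with n_genes > 3 requires ",
         "nonzero `coupling_extra`", call. = FALSE)
  }

  if (length(hill_coefficient) != 1L || !is.finite(hill_coefficient) ||
      hill_coefficient <= 0) {
    stop("`hill_coefficient` must be a single positive number", call. = FALSE)
  }
  beta <- expand(production_max, "production_max")
  alpha0 <- expand(production_basal, "production_basal")
  delta <- expand(degradation, "degradation", allow_zero = FALSE)
  if (is.null(knockout)) knockout <- rep(FALSE, n)
  if (!is.logical(knockout) || length(knockout) != n || anyNA(knockout)) {
    stop(sprintf("`knockout` must be a logical vector of length %d", n),
         call. = FALSE)
  }

  net <- structure(
    list(
      n_genes = n,
      topology = topology,
      gate = gate,
      coupling_forward = cf,
      coupling_reverse = cr,
      coupling_extra = cx,
      hill_coefficient = as.numeric(hill_coefficient),
      production_max = beta,
      production_basal = alpha0,
      degradation = delta,
      knockout = knockout
    ),
    class = "cfr_network"
  )
  net
}

#' Build a network specification from a configuration mapping
#'
#' Accepts a named list (or a path to a YAML/JSON file) whose keys are exactly
#' the arguments of [cfr_network()]. Unknown keys are an error, listed by
#' name, so that typos in configuration files cannot silently change a model.
#'
#' @param config named list, or path to a `.yaml`/`.yml`/`.json` file
#'   containing one.
#' @return A `cfr_network`.
#' @examples
#' build_network(list(n_genes = 3, topology = "cyclic", gate = "OR"))
#' @export
build_network <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_structured_file(config)
  }
  if (!is.list(config) || is.null(names(config)) || any(names(config) == "")) {
    stop("`config` must be a fully named list", call. = FALSE)
  }
  allowed <- names(formals(cfr_network))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown network configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$knockout)) config$knockout <- as.logical(config$knockout)
  do.call(cfr_network, config)
}

#' Relative coupling matrix of a network
#'
#' Returns the `n_genes x n_genes` matrix `W` with `W[i, j]` the relative
#' strength of the repression `j -> i` (zero where no edge). The dynamical
#' strength at time `t` is `g(t) * W` (see [effective_coupling()]).
#'
#' @param net a `cfr_network`.
#' @return numeric matrix.
#' @export
coupling_matrix <- function(net) {
  stopifnot(inherits(net, "cfr_network"))
  n <- net$n_genes
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    up <- ((i - 2L) %% n) + 1L
    dn <- (i %% n) + 1L
    W[i, up] <- net$coupling_forward[i]
    if (net$topology != "cyclic") W[i, dn] <- net$coupling_reverse[i]
    if (net$topology == "all_pairs") {
      for (j in setdiff(seq_len(n), c(i, up, dn))) {
        d <- (i - j) %% n  # cyclic distance in 2 .. n-2
        W[i, j] <- net$coupling_extra[d - 1L]
      }
    }
  }
  W
}

#' Null-allele knockout
#'
#' Marks genes as loss-of-function mutants: their maximal and basal production
#' are forced to zero, so expression decays to zero and, dynamically, their
#' repressive output on other genes vanishes. The coupling matrix itself is
#' unchanged (knockout acts on production, not on edges).
#'
#' @param net a `cfr_network`.
#' @param genes integer indices of genes to knock out.
#' @return A new `cfr_network` with the knockout mask set.
#' @export
knockout_genes <- function(net, genes) {
  stopifnot(inherits(net, "cfr_network"))
  genes <- as.integer(genes)
  if (any(genes < 1L | genes > net$n_genes)) {
    stop("gene index out of range", call. = FALSE)
  }
  mask <- net$knockout
  mask[genes] <- TRUE
  if (all(mask)) stop("refusing to knock out every gene", call. = FALSE)
  net$knockout <- mask
  net
}

#' Cyclic relabeling of genes
#'
#' Rotates gene labels by `shift` positions (gene `i` becomes gene
#' `i + shift`, modulo `n_genes`). For rotationally symmetric specifications
#' this is an exact symmetry of the dynamics; it is used to test permutation
#' equivariance.
#'
#' @param net a `cfr_network`.
#' @param shift integer rotation.
#' @return The relabeled `cfr_network`.
#' @export
rotate_network <- function(net, shift = 1L) {
  stopifnot(inherits(net, "cfr_network"))
  n <- net$n_genes
  perm <- ((seq_len(n) - 1L - shift) %% n) + 1L  # new index i held old perm[i]
  for (f in c("coupling_forward", "coupling_reverse", "production_max",
              "production_basal", "degradation", "knockout")) {
    net[[f]] <- net[[f]][perm]
  }
  net
}

#' Global coupling schedule g(t)
#'
#' The control parameter of the model: a nonnegative multiplier applied to all
#' relative repression strengths. `"constant"` reproduces the autonomous
#' system; `"linear_ramp"` interpolates linearly from `g_start` at `t_start`
#' to `g_end` at `t_end` and holds the endpoint values outside the window;
#' `"piecewise_linear"` interpolates through arbitrary (times, values) knots.
#'
#' @param kind `"constant"`, `"linear_ramp"`, or `"piecewise_linear"`.
#' @param g_start,g_end nonnegative coupling values (for `"constant"` only
#'   `g_start` is used).
#' @param t_start,t_end ramp window in model time units.
#' @param times,values knot vectors for `"piecewise_linear"`.
#' @return An object of class `cfr_schedule`.
#' @examples
#' coupling_schedule("constant", 5)
#' coupling_schedule("linear_ramp", 0, 0.5, t_start = 0, t_end = 400)
#' @export
coupling_schedule <- function(kind = c("constant", "linear_ramp",
                                       "piecewise_linear"),
                              g_start = 1, g_end = g_start,
                              t_start = 0, t_end = 1,
                              times = NULL, values = NULL) {
  kind <- match.arg(kind)
  if (kind == "piecewise_linear") {
    if (is.null(times) || is.null(values) || length(times) != length(values) ||
        length(times) < 2L) {
      stop("piecewise_linear requires `times` and `values` of equal length >= 2",
           call. = FALSE)
    }
    if (is.unsorted(times, strictly = TRUE)) {
      stop("`times` must be strictly increasing", call. = FALSE)
    }
    if (any(!is.finite(values)) || any(values < 0)) {
      stop("schedule values must be finite and nonnegative", call. = FALSE)
    }
  } else {
    if (any(!is.finite(c(g_start, g_end))) || g_start < 0 || g_end < 0) {
      stop("g_start and g_end must be finite and nonnegative", call. = FALSE)
    }
    if (kind == "linear_ramp") {
      if (!is.finite(t_start) || !is.finite(t_end) || t_end <= t_start) {
        stop("linear_ramp requires finite t_start < t_end", call. = FALSE)
      }
      if (g_end < g_start) {
        stop("linear_ramp must be nondecreasing (g_end >= g_start)",
             call. = FALSE)
      }
    }
  }
  structure(
    list(kind = kind, g_start = g_start, g_end = g_end,
         t_start = t_start, t_end = t_end, times = times, values = values),
    class = "cfr_schedule"
  )
}

#' Evaluate a coupling schedule
#'
#' @param schedule a `cfr_schedule`.
#' @param t numeric vector of times.
#' @return `g(t)`, same length as `t`.
#' @export
g_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "cfr_schedule"))
  switch(schedule$kind,
    constant = rep(schedule$g_start, length(t)),
    linear_ramp = {
      frac <- (t - schedule$t_start) / (schedule$t_end - schedule$t_start)
      frac <- pmin(pmax(frac, 0), 1)
      schedule$g_start + frac * (schedule$g_end - schedule$g_start)
    },
    piecewise_linear = stats::approx(schedule$times, schedule$values, xout = t,
                                     rule = 2)$y
  )
}

#' First time at which a ramp reaches a coupling value
#'
#' Inverts a nondecreasing schedule; returns `NA` if the value is never
#' reached on the schedule's range.
#'
#' @param schedule a `cfr_schedule`.
#' @param g target coupling value.
#' @return time, or `NA_real_`.
#' @export
time_of_g <- function(schedule, g) {
  stopifnot(inherits(schedule, "cfr_schedule"))
  switch(schedule$kind,
    constant = if (schedule$g_start >= g) schedule$t_start else NA_real_,
    linear_ramp = {
      if (g <= schedule$g_start) return(schedule$t_start)
      if (g > schedule$g_end) return(NA_real_)
      schedule$t_start + (g - schedule$g_start) /
        (schedule$g_end - schedule$g_start) *
        (schedule$t_end - schedule$t_start)
    },
    piecewise_linear = {
      v <- schedule$values
      if (all(v < g)) return(NA_real_)
      if (v[1] >= g) return(schedule$times[1])
      k <- which(v >= g)[1]
      t0 <- schedule$times[k - 1]; t1 <- schedule$times[k]
      v0 <- v[k - 1]; v1 <- v[k]
      t0 + (g - v0) / (v1 - v0) * (t1 - t0)
    }
  )
}

#' Fate-specific external signal
#'
#' An additive production boost delivered to one gene over a time window,
#' modelling a fate-specific signalling input (e.g. a receptor pathway active
#' only in one biased sub-state). Amplitude zero leaves the dynamics
#' bit-identical to the unsignalled system.
#'
#' @param target_gene index of the signalled gene.
#' @param amplitude additive production rate s >= 0.
#' @param t_on,t_off activation window (default: always on).
#' @return An object of class `cfr_signal`.
#' @export
signal_protocol <- function(target_gene, amplitude, t_on = 0, t_off = Inf) {
  if (length(target_gene) != 1L || target_gene < 1 ||
      target_gene != round(target_gene)) {
    stop("`target_gene` must be a single positive integer", call. = FALSE)
  }
  if (length(amplitude) != 1L || !is.finite(amplitude) || amplitude < 0) {
    stop("`amplitude` must be a single finite nonnegative number",
         call. = FALSE)
  }
  if (t_off <= t_on) stop("`t_off` must exceed `t_on`", call. = FALSE)
  structure(
    list(target_gene = as.integer(target_gene), amplitude = amplitude,
         t_on = t_on, t_off = t_off),
    class = "cfr_signal"
  )
}

#' Evaluate signal protocols at a time point
#'
#' @param signals a `cfr_signal`, a list of them, or `NULL`.
#' @param t a single time.
#' @param n_genes number of genes.
#' @return per-gene additive production vector `s(t)`.
#' @export
signal_at <- function(signals, t, n_genes) {
  s <- numeric(n_genes)
  if (is.null(signals)) return(s)
  if (inherits(signals, "cfr_signal")) signals <- list(signals)
  for (sig in signals) {
    if (sig$target_gene > n_genes) {
      stop("signal target_gene exceeds n_genes", call. = FALSE)
    }
    if (t >= sig$t_on && t < sig$t_off) {
      s[sig$target_gene] <- s[sig$target_gene] + sig$amplitude
    }
  }
  s
}

#' Effective pairwise repression strengths at time t
#'
#' `w_ij(t) = g(t) * W[i, j]` where `W` is the relative coupling matrix.
#' Knockouts do not alter this matrix: a null allele acts on production, and
#' its repressive output disappears dynamically because its expression decays
#' to zero.
#'
#' @param net a `cfr_network`.
#' @param schedule a `cfr_schedule`.
#' @param t a single time.
#' @return numeric matrix of effective strengths.
#' @export
effective_coupling <- function(net, schedule, t) {
  stopifnot(length(t) == 1L)
  g_at(schedule, t) * coupling_matrix(net)
}

#' @export
print.cfr_network <- function(x, ...) {
  cat(sprintf("<cfr_network> %d genes, %s topology, %s gate\n",
              x$n_genes, x$topology, x$gate))
  cat(sprintf("  forward %s | reverse %s | extra %s | h = %.3g\n",
              paste(signif(x$coupling_forward, 3), collapse = ","),
              paste(signif(x$coupling_reverse, 3), collapse = ","),
              paste(signif(x$coupling_extra, 3), collapse = ","),
              x$hill_coefficient))
  cat(sprintf("  beta %s | alpha0 %s | delta %s\n",
              paste(signif(x$production_max, 3), collapse = ","),
              paste(signif(x$production_basal, 3), collapse = ","),
              paste(signif(x$degradation, 3), collapse = ",")))
  if (any(x$knockout)) {
    cat("  knockout:", paste(which(x$knockout), collapse = ","), "\n")
  }
  invisible(x)
}

#' @export
print.cfr_schedule <- function(x, ...) {
  cat(sprintf("<cfr_schedule> %s", x$kind))
  if (x$kind == "constant") {
    cat(sprintf(" g = %.4g\n", x$g_start))
  } else if (x$kind == "linear_ramp") {
    cat(sprintf(" g: %.4g -> %.4g over t in [%.4g, %.4g]\n",
                x$g_start, x$g_end, x$t_start, x$t_end))
  } else {
    cat(sprintf(" %d knots on [%.4g, %.4g]\n", length(x$times),
                min(x$times), max(x$times)))
  }
  invisible(x)
}

# internal: read a YAML or JSON mapping from disk
read_structured_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml, or .json", call. = FALSE)
  }
}
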