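#' Named model presets
#'
#' Versioned parameter presets for the canonical model variants. Each preset
#' bundles a network, a coupling schedule, and (where relevant) the coupling
#' value or window it is meant to illustrate. The kinetic baseline throughout
#' is alpha0 = 0.05, beta = 10, h = 3, delta = 1: nondimensionalized rates
#' that place the interesting coupling windows at convenient g values and
#' give the repression enough cooperativity for the ring to oscillate (a
#' protein-only repression loop needs h > 2).
#'
#' Available presets:
#' \describe{
#'   \item{`"repressilator"`}{classic 3-gene cyclic OR loop at constant g = 5
#'     (well inside its oscillatory range).}
#'   \item{`"double-or"`}{3-gene double repressilator, OR gate, forward 1 /
#'     reverse 0.1, at a constant mid-window g. Shows all three response
#'     modes as g varies.}
#'   \item{`"double-or-ramp"`}{same network under a slow linear ramp of g
#'     crossing the whole oscillatory window, then held; reproduces the
#'     multipotent -> oscillatory -> differentiated sequence.}
#'   \item{`"double-or-biased"`}{double repressilator with the two edges
#'     *into* gene 1 strengthened 2:1 relative to baseline, breaking
#'     rotational symmetry and biasing the dwell-time distribution.}
#'   \item{`"double-and"`}{3-gene all-pairs AND-gate model at constant g in
#'     its oscillatory range; cycles between two-gene co-expressed
#'     sub-states. AND windows sit at much smaller g because the repression
#'     term is of order x^(2h).}
#'   \item{`"ring5-or"`}{5-gene nearest-neighbour ring, OR gate.}
#'   \item{`"ring5-and"`}{5-gene nearest-neighbour ring, AND gate;
#'     co-expressed pairs are non-adjacent in the ring.}
#'   \item{`"ring4"`}{4-gene nearest-neighbour ring, OR gate (does not
#'     oscillate at any coupling).}
#'   \item{`"ring4-allpairs"`}{4-gene all-pairs OR network, whose
#'     non-neighbour edges restore oscillation.}
#' }
#'
#' @param name preset name.
#' @return list with elements `network` (`cfr_network`), `schedule`
#'   (`cfr_schedule`), and `description`.
#' @examples
#' p <- cfr_preset("repressilator")
#' p$network
#' @export
cfr_preset <- function(name) {
  presets <- list(
    "repressilator" = function() list(
      network = cfr_network(3, "cyclic", "OR"),
      schedule = coupling_schedule("constant", 5),
      description = "classic 3-gene repressilator, constant g = 5"
    ),
    "double-or" = function() list(
      network = cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1),
      schedule = coupling_schedule("constant", 0.15),
      description = "double repressilator (OR), constant mid-window g"
    ),
    "double-or-ramp" = function() list(
      network = cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1),
      schedule = coupling_schedule("linear_ramp", 0.005, 0.5,
                                   t_start = 0, t_end = 600),
      description = "double repressilator (OR) under a slow coupling ramp"
    ),
    "double-or-biased" = function() list(
      network = cfr_network(3, "all_pairs", "OR",
                            coupling_forward = c(2, 1, 1),
                            coupling_reverse = c(0.2, 0.1, 0.1)),
      schedule = coupling_schedule("constant", 0.08),
      description = "double repressilator with edges into gene 1 doubled"
    ),
    "double-and" = function() list(
      network = cfr_network(3, "all_pairs", "AND", coupling_reverse = 0.3),
      schedule = coupling_schedule("constant", 1e-3),
      description = "3-gene AND-gate model, oscillatory g"
    ),
    "ring5-or" = function() list(
      network = cfr_network(5, "ring_neighbors", "OR", coupling_reverse = 0.1),
      schedule = coupling_schedule("constant", 0.15),
      description = "5-gene ring, OR gate"
    ),
    "ring5-and" = function() list(
      network = cfr_network(5, "ring_neighbors", "AND", coupling_reverse = 0.3),
      schedule = coupling_schedule("constant", 1e-3),
      description = "5-gene ring, AND gate; non-adjacent pair co-expression"
    ),
    "penta-graded" = function() list(
      network = cfr_network(5, "all_pairs", "OR",
                            coupling_forward = 0.4,
                            coupling_reverse = 0.1,
                            coupling_extra = c(1, 0.1)),
      schedule = coupling_schedule("constant", 0.15),
      description = paste("5-gene network with repression graded by cyclic",
                          "distance (0.4, 1, 0.1, 0.1): every gene keeps a",
                          "strong repressor after any single knockout, and a",
                          "strong odd repression loop survives, so mutants",
                          "keep cycling through the remaining sub-states")
    ),
    "ring4" = function() list(
      network = cfr_network(4, "ring_neighbors", "OR", coupling_reverse = 0.1),
      schedule = coupling_schedule("constant", 0.15),
      description = "4-gene ring, OR gate (non-oscillatory at all g)"
    ),
    "ring4-allpairs" = function() list(
      network = cfr_network(4, "all_pairs", "OR", coupling_reverse = 0.1,
                            coupling_extra = 1),
      schedule = coupling_schedule("constant", 0.15),
      description = "4-gene all-pairs OR network"
    )
  )
  if (!name %in% names(presets)) {
    stop("unknown preset \"", name, "\"; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]()
}

#' @rdname cfr_preset
#' @export
preset_names <- function() {
  c("repressilator", "double-or", "double-or-ramp", "double-or-biased",
    "double-and", "ring5-or", "ring5-and", "penta-graded", "ring4",
    "ring4-allpairs")
}
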