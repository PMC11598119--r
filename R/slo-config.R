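#' Configure a snow leopard optimization run
#'
#' Collects the control parameters of the optimizer. The defaults are the
#' published settings: step constant 0.5 for the exploratory phases
#' (delineation, relocation), 0.05 for disputes, temperature threshold 0.8
#' separating the delineation phase from the later phases, and gate threshold
#' 0.4 deciding relocation versus dispute from a fresh uniform draw times the
#' behavioral-control value.
#'
#' `ratio_mode` selects the reading of the fitness-ratio factors in the
#' delineation and dispute-rival moves: `"divide"` (default) uses
#' `1/(r + 1)^2` resp. `1/(q + 1)`, which bounds the step factor in (0, 1]
#' for non-negative fitness; `"multiply"` uses `(r + 1)^2` resp. `(q + 1)`
#' and is retained for sensitivity analysis.
#'
#' @param pop_size Population size (>= 4 so that all four gender x
#'   living-arrangement roles can be populated). 100 is typical for benchmark
#'   functions; 20 for feature selection.
#' @param max_iter Number of iterations (the schedule's MAX_T).
#' @param c1_explore Step constant of the delineation and relocation moves.
#' @param c1_dispute Step constant of the dispute moves.
#' @param temp_threshold Temperature above which delineation runs (in (0,1)).
#' @param gate_threshold Threshold on `uniform * BC` choosing relocation
#'   (below) versus dispute (at or above), in `[0, 1]`.
#' @param ratio_mode `"divide"` or `"multiply"`, see Details.
#' @param eps Small positive guard added to ratio denominators.
#' @param seed Integer seed; every random draw of a run flows from it.
#' @return An object of class `slo_config`.
#' @export
slo_config <- function(pop_size = 100L, max_iter = 1000L,
                       c1_explore = 0.5, c1_dispute = 0.05,
                       temp_threshold = 0.8, gate_threshold = 0.4,
                       ratio_mode = c("divide", "multiply"),
                       eps = 1e-12, seed = 1L) {
  ratio_mode <- match.arg(ratio_mode)
  pop_size <- as.integer(pop_size)
  max_iter <- as.integer(max_iter)
  if (pop_size < 4L)
    stop("`pop_size` must be >= 4 so all four roles can be populated")
  if (max_iter < 1L) stop("`max_iter` must be a positive integer")
  if (temp_threshold <= 0 || temp_threshold >= 1)
    stop("`temp_threshold` must lie strictly in (0, 1)")
  if (gate_threshold < 0 || gate_threshold > 1)
    stop("`gate_threshold` must lie in [0, 1]")
  if (c1_explore <= 0 || c1_dispute <= 0) stop("c1 constants must be positive")
  if (eps <= 0) stop("`eps` must be positive")
  structure(
    list(pop_size = pop_size, max_iter = max_iter,
         c1_explore = c1_explore, c1_dispute = c1_dispute,
         temp_threshold = temp_threshold, gate_threshold = gate_threshold,
         ratio_mode = ratio_mode, eps = eps, seed = as.integer(seed)),
    class = "slo_config"
  )
}
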