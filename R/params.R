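#' Simulation parameters for a surface patch
#'
#' Bundles the physical, physiological and numerical parameters of the
#' agent-based model. Defaults are plausible magnitudes for fast-growing
#' rod-shaped bacteria (roughly E. coli scale) and a desk-scale patch; every
#' value can be overridden per call.
#'
#' @param k_max Maximum specific growth rate (1/h).
#' @param V_0 Birth volume (µm³).
#' @param R_cell Capsule radius (µm).
#' @param eta_division Division-size noise amplitude (µm³). Each cell draws a
#'   personal division target `2*V_0 + Uniform[0, eta_division)` at birth.
#' @param eta_orientations Daughter-axis perturbation half-range (radians).
#' @param dt Timestep (h). Must satisfy `dt * k_max < 0.1`.
#' @param E_0 Patch resource quota, in units of biovolume (µm³) that can be
#'   produced before depletion.
#' @param L_needle T6SS needle length (µm).
#' @param L_penetration Hit tolerance depth (µm), strictly less than `R_cell`.
#' @param N_hits Toxin translocations that trigger lysis; `Inf` means immune.
#' @param k_lysis Lysis rate (1/h); a lysing cell is removed after `1/k_lysis`.
#' @param c_upfront Growth-rate fraction paid for carrying T6SS genes.
#' @param c Pro-rata cost per firing rate unit (h per firing).
#' @param alpha Regularization weight of the relaxation solver.
#' @param drag_coeff Per-cell drag scale; drag grows with cell length.
#' @param relax_tol Maximum residual overlap accepted by [relax()] (µm).
#' @param relax_max_iter Iteration cap of the relaxation loop.
#' @param max_steps Hard stop for [run_patch()].
#' @param arena_radius Radius of the disc used for initial placement (µm).
#'   The arena is fixed, so initial density scales with the cell counts.
#'
#' @return An object of class `t6_params` (a validated named list).
#' @examples
#' p <- sim_params(N_hits = 1, E_0 = 500)
#' p$N_hits
#' @export
sim_params <- function(k_max = 2.08, V_0 = 1.57, R_cell = 0.5,
                       eta_division = 0.3, eta_orientations = 0.1,
                       dt = 0.005, E_0 = 4700, L_needle = 1.0,
                       L_penetration = 0.05, N_hits = 2, k_lysis = 20,
                       c_upfront = 0.05, c = 0.001, alpha = 0.01,
                       drag_coeff = 1.0, relax_tol = 0.02,
                       relax_max_iter = 50, max_steps = 20000,
                       arena_radius = 20) {
  p <- list(k_max = k_max, V_0 = V_0, R_cell = R_cell,
            eta_division = eta_division, eta_orientations = eta_orientations,
            dt = dt, E_0 = E_0, L_needle = L_needle,
            L_penetration = L_penetration, N_hits = N_hits, k_lysis = k_lysis,
            c_upfront = c_upfront, c = c, alpha = alpha,
            drag_coeff = drag_coeff, relax_tol = relax_tol,
            relax_max_iter = relax_max_iter, max_steps = max_steps,
            arena_radius = arena_radius)
  validate_params(p)
  structure(p, class = "t6_params")
}

validate_params <- function(p) {
  pos <- c("k_max", "V_0", "R_cell", "dt", "L_needle", "k_lysis",
           "drag_coeff", "relax_tol", "arena_radius")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a single strictly positive number", nm))
  }
  nonneg <- c("eta_division", "eta_orientations", "E_0", "L_penetration",
              "c", "alpha")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm))
  }
  if (p$dt * p$k_max >= 0.1)
    stop("timestep too coarse: need dt * k_max < 0.1")
  if (p$L_penetration >= p$R_cell)
    stop("L_penetration must be smaller than R_cell")
  if (p$c_upfront < 0 || p$c_upfront >= 1)
    stop("c_upfront must lie in [0, 1)")
  if (!(is.infinite(p$N_hits) || (p$N_hits >= 1 && p$N_hits == round(p$N_hits))))
    stop("N_hits must be an integer >= 1, or Inf for an immune strain")
  if (p$relax_max_iter < 1 || p$max_steps < 1)
    stop("iteration caps must be at least 1")
  invisible(p)
}

#' @export
print.t6_params <- function(x, ...) {
  cat("T6SS patch simulation parameters\n")
  cat(sprintf("  growth: k_max = %.3g /h, V_0 = %.3g um^3, dt = %.3g h\n",
              x$k_max, x$V_0, x$dt))
  cat(sprintf("  patch:  E_0 = %.3g um^3, arena radius = %.3g um\n",
              x$E_0, x$arena_radius))
  cat(sprintf("  T6SS:   L_needle = %.3g um, N_hits = %s, k_lysis = %.3g /h\n",
              x$L_needle, format(x$N_hits), x$k_lysis))
  cat(sprintf("  costs:  c_upfront = %.3g, c = %.3g\n", x$c_upfront, x$c))
  invisible(x)
}
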