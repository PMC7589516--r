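# Growth, division and resource depletion.

#' Update per-cell growth rates from weapon costs
#'
#' T6SS-negative cells grow at `k_max`. T6SS-positive cells pay a total cost
#' fraction `c_total = c_upfront + c * N_firings/dt` (cost-saving
#' strategists, charged per realized firing) or
#' `c_total = c_upfront + c * k_fire_ref` (cost-saving knockouts, charged
#' like a reference random firer regardless of actual firings), clamped to
#' `[0, 1]`; their growth rate is `k_max * (1 - c_total)`. Lysing cells do
#' not grow.
#'
#' @param patch A `t6_patch` whose `firings` counts reflect the current step
#'   (set by [schedule_firings()]).
#' @return The patch with updated `k_grow` values.
#' @export
update_growth_rates <- function(patch) {
  stopifnot(inherits(patch, "t6_patch"))
  update_growth_rates_impl(patch)
}

update_growth_rates_impl <- function(patch) {
  p <- patch$params
  cs <- patch$cells
  g <- cs$genotype
  st <- patch$strat
  cost <- ifelse(st$carries[g],
                 p$c_upfront + ifelse(st$cost_saving[g],
                                      p$c * cs$firings / p$dt,
                                      p$c * st$k_fire_ref[g]),
                 0)
  cost <- pmin(pmax(cost, 0), 1)
  kg <- p$k_max * (1 - cost)
  kg[cs$lysing] <- 0
  patch$cells$kgrow <- kg
  patch
}

#' Grow cells exponentially and divide those past their size target
#'
#' Each non-lysing cell's volume is multiplied by `exp(k_grow * dt)` (the
#' exact one-step integral of `dV/dt = k_grow V`), elongating at fixed
#' radius. A cell whose volume reaches its personal division target
#' `2 V_0 + eta` (eta drawn once at birth from `Uniform[0, eta_division)`)
#' splits lengthwise into two daughters of half its volume placed end to end
#' along the parent axis, each daughter axis perturbed in-plane by an angle
#' drawn from `Uniform(-eta_orientations, eta_orientations)`. Daughters
#' inherit genotype, strategy and translocation count; retaliation queues
#' are not inherited.
#'
#' @param patch A `t6_patch`.
#' @return The patch after one growth/division phase.
#' @export
grow_and_divide <- function(patch) {
  stopifnot(inherits(patch, "t6_patch"))
  res <- with_rng_state(patch$rng, function() grow_and_divide_impl(patch))
  out <- res$value
  out$rng <- res$rng
  out
}

grow_and_divide_impl <- function(patch) {
  p <- patch$params
  cs <- patch$cells
  grow <- !cs$lysing
  cs$vol[grow] <- cs$vol[grow] * exp(cs$kgrow[grow] * p$dt)
  cs$seg <- capsule_seg_length(cs$vol, p$R_cell)

  div <- which(cs$vol >= cs$eta_target & !cs$lysing)
  if (length(div)) {
    gnames <- patch$strat$name
    for (i in div) {
      vd <- cs$vol[i] / 2
      segd <- capsule_seg_length(vd, p$R_cell)
      off <- (segd + 2 * p$R_cell) / 2
      ang <- runif(2, -p$eta_orientations, p$eta_orientations)
      etas <- 2 * p$V_0 + runif(2, 0, p$eta_division)
      axp <- c(cs$ax[i], cs$ay[i])
      rot <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                               sin(th) * v[1] + cos(th) * v[2])
      a1 <- rot(axp, ang[1]); a2 <- rot(axp, ang[2])
      # daughter 1 replaces the parent slot
      cx <- cs$x[i]; cy <- cs$y[i]
      cs$x[i] <- cx - axp[1] * off; cs$y[i] <- cy - axp[2] * off
      cs$ax[i] <- a1[1]; cs$ay[i] <- a1[2]
      cs$vol[i] <- vd; cs$seg[i] <- segd
      cs$eta_target[i] <- etas[1]
      # daughter 2 appended
      cs$id <- c(cs$id, patch$next_id)
      cs$genotype <- c(cs$genotype, cs$genotype[i])
      cs$x <- c(cs$x, cx + axp[1] * off); cs$y <- c(cs$y, cy + axp[2] * off)
      cs$ax <- c(cs$ax, a2[1]); cs$ay <- c(cs$ay, a2[2])
      cs$seg <- c(cs$seg, segd); cs$vol <- c(cs$vol, vd)
      cs$kgrow <- c(cs$kgrow, cs$kgrow[i])
      cs$trans <- c(cs$trans, cs$trans[i])
      cs$lysing <- c(cs$lysing, FALSE)
      cs$deadline <- c(cs$deadline, Inf)
      cs$eta_target <- c(cs$eta_target, etas[2])
      cs$firings <- c(cs$firings, 0)
      patch$next_id <- patch$next_id + 1L
      g <- gnames[cs$genotype[i]]
      patch$births[g] <- patch$births[g] + 1L
    }
  }
  patch$cells <- cs
  patch
}

#' Deplete patch resources
#'
#' Living, non-lysing cells consume the shared resource at a rate
#' proportional to their current volume and independent of how much resource
#' remains (zeroth-order kinetics): `E <- E - k_max * sum(V_i) * dt`,
#' floored at zero. `E = 0` terminates a [run_patch()] simulation.
#'
#' @param patch A `t6_patch`.
#' @return The patch with updated `E`.
#' @export
deplete_resources <- function(patch) {
  stopifnot(inherits(patch, "t6_patch"))
  deplete_resources_impl(patch)
}

deplete_resources_impl <- function(patch) {
  cs <- patch$cells
  use <- sum(cs$vol[!cs$lysing])
  patch$E <- max(0, patch$E - patch$params$k_max * use * patch$params$dt)
  patch
}
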