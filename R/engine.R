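# Per-step update loop and replicate orchestration.

#' Advance a patch by one timestep
#'
#' Applies, in order: (1) firing scheduling (retaliations queued last step
#' fire now), (2) hit detection, (3) intoxication and lysis bookkeeping,
#' (4) removal of cells past their lysis deadline, (5) growth-rate update
#' from this step's firing counts, (6) exponential growth and noisy
#' division, (7) resource depletion, (8) mechanical relaxation, then
#' advances the clock. Identical input patches give identical outputs (the
#' patch carries its own RNG stream).
#'
#' @param patch A `t6_patch` with `E > 0`.
#' @return The advanced patch.
#' @export
step_patch <- function(patch) {
  stopifnot(inherits(patch, "t6_patch"))
  if (patch$E <= 0) stop("patch is already depleted (E = 0)")
  res <- with_rng_state(patch$rng, function() step_impl(patch))
  out <- res$value
  out$rng <- res$rng
  out
}

step_impl <- function(patch) {
  patch$step_count <- patch$step_count + 1L
  sf <- schedule_firings_impl(patch)
  patch <- sf$patch
  if (nrow(sf$needles))
    patch$log$fires[[length(patch$log$fires) + 1L]] <-
      cbind(step = patch$step_count,
            source_id = sf$needles$source_id,
            genotype = patch$cells$genotype[sf$needles$source_idx])
  hits <- detect_hits_impl(sf$needles, patch)
  patch <- apply_intoxication_impl(hits, patch)
  patch <- remove_lysed_impl(patch)
  patch <- update_growth_rates_impl(patch)
  patch <- grow_and_divide_impl(patch)
  patch <- deplete_resources_impl(patch)
  patch <- relax_impl(patch)
  patch$t <- patch$t + patch$params$dt
  patch
}

#' Run a patch competition to resource depletion
#'
#' Builds a seeded initial patch (unless one is supplied) and iterates
#' [step_patch()] until the resource quota is exhausted or `max_steps` is
#' reached (in which case the run is flagged censored). Per-genotype counts
#' and biovolumes are recorded at snapshot intervals.
#'
#' @param params A [sim_params()] object.
#' @param strategies List of [strategy_spec()] objects.
#' @param counts Initial cells per strategy.
#' @param seed Integer seed.
#' @param mutual_immunity Passed to [make_initial_patch()].
#' @param snapshot_every Record a population snapshot every this many steps
#'   (0 disables intermediate snapshots).
#' @param patch Optionally, a ready-made initial patch (then `params`,
#'   `strategies`, `counts`, `seed` are ignored).
#' @return An object of class `t6_run`: the final patch, a per-genotype
#'   summary (initial/final counts and biovolumes, births, deaths), the
#'   snapshot trajectory, end time and censoring flag.
#' @examples
#' \donttest{
#' run <- run_patch(sim_params(E_0 = 300), list(strategy_unarmed()), 20, seed = 1)
#' run$summary
#' }
#' @export
run_patch <- function(params = sim_params(), strategies, counts, seed,
                      mutual_immunity = FALSE, snapshot_every = 20,
                      patch = NULL) {
  if (is.null(patch))
    patch <- make_initial_patch(params, strategies, counts, seed,
                                mutual_immunity = mutual_immunity)
  stopifnot(inherits(patch, "t6_patch"))
  p <- patch$params
  snaps <- list(genotype_snapshot(patch))
  while (patch$E > 0 && patch$step_count < p$max_steps) {
    patch <- step_patch(patch)
    if (snapshot_every > 0 && patch$step_count %% snapshot_every == 0)
      snaps[[length(snaps) + 1L]] <- genotype_snapshot(patch)
  }
  snaps[[length(snaps) + 1L]] <- genotype_snapshot(patch)
  censored <- patch$E > 0
  if (censored)
    warning("run censored: max_steps reached before resource depletion")

  init <- patch$initial
  cs <- patch$cells
  G <- nrow(init)
  summary <- data.frame(
    genotype = init$genotype, name = init$name,
    n0 = init$n0, v0 = init$v0,
    n_end = vapply(init$genotype, function(g) sum(cs$genotype == g), 0L),
    v_end = vapply(init$genotype, function(g) sum(cs$vol[cs$genotype == g]), 0),
    births = as.integer(patch$births[init$name]),
    deaths = as.integer(patch$deaths[init$name]))

  structure(list(patch = patch, summary = summary,
                 trajectory = do.call(rbind, snaps),
                 t_end = patch$t, steps = patch$step_count,
                 censored = censored, seed = patch$seed),
            class = "t6_run")
}

genotype_snapshot <- function(patch) {
  cs <- patch$cells
  init <- patch$initial
  data.frame(step = patch$step_count, t = patch$t, E = patch$E,
             genotype = init$genotype, name = init$name,
             n = vapply(init$genotype, function(g) sum(cs$genotype == g), 0L),
             biovolume = vapply(init$genotype,
                                function(g) sum(cs$vol[cs$genotype == g]), 0))
}

#' @export
print.t6_run <- function(x, ...) {
  cat(sprintf("T6SS competition run: %d steps, t_end = %.3f h%s\n",
              x$steps, x$t_end, if (x$censored) " (censored)" else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Event log of a run or patch
#'
#' Collates the firing, hit, lysis-onset and death events recorded during a
#' simulation into one tidy data frame (columns: step, type, source_id,
#' target_id, genotype fields and entry-point coordinates where relevant).
#'
#' @param x A `t6_run` or `t6_patch`.
#' @return A data frame, one row per event.
#' @export
event_log <- function(x) {
  patch <- if (inherits(x, "t6_run")) x$patch else x
  stopifnot(inherits(patch, "t6_patch"))
  blocks <- list()
  bind <- function(lst) if (length(lst)) as.data.frame(do.call(rbind, lst)) else NULL
  f <- bind(patch$log$fires)
  if (!is.null(f))
    blocks$fire <- data.frame(step = f$step, type = "fire", source_id = f$source_id,
                              target_id = NA, genotype = f$genotype,
                              x = NA_real_, y = NA_real_)
  h <- bind(patch$log$hits)
  if (!is.null(h))
    blocks$hit <- data.frame(step = h$step,
                             type = ifelse(h$intoxicating > 0, "intox", "hit"),
                             source_id = h$source_id, target_id = h$target_id,
                             genotype = h$source_genotype, x = h$ex, y = h$ey)
  l <- bind(patch$log$lysis)
  if (!is.null(l))
    blocks$lyse <- data.frame(step = l$step, type = "lyse", source_id = NA,
                              target_id = l$id, genotype = l$genotype,
                              x = NA_real_, y = NA_real_)
  d <- bind(patch$log$deaths)
  if (!is.null(d))
    blocks$death <- data.frame(step = d$step, type = "death", source_id = NA,
                               target_id = d$id, genotype = d$genotype,
                               x = NA_real_, y = NA_real_)
  out <- do.call(rbind, blocks)
  if (is.null(out))
    out <- data.frame(step = integer(0), type = character(0),
                      source_id = integer(0), target_id = integer(0),
                      genotype = integer(0), x = numeric(0), y = numeric(0))
  rownames(out) <- NULL
  out[order(out$step), , drop = FALSE]
}

#' Head-to-head competition between two strategies
#'
#' Convenience wrapper: builds a 1:1 (or custom) mixed patch of two
#' strategies and runs it to depletion.
#'
#' @param strategy_a,strategy_b [strategy_spec()] objects.
#' @param params A [sim_params()] object.
#' @param n_each Initial cells per strategy (length 1 or 2).
#' @param seed Integer seed.
#' @param mutual_immunity Make the two strains mutually immune (the
#'   "primed" pairing of the fitness table).
#' @param ... Passed to [run_patch()].
#' @return A `t6_run`.
#' @export
compete <- function(strategy_a, strategy_b, params = sim_params(),
                    n_each = 100, seed = 1, mutual_immunity = FALSE, ...) {
  if (strategy_a$name == strategy_b$name) {
    strategy_b$name <- paste0(strategy_b$name, "'")
  }
  counts <- if (length(n_each) == 2) n_each else rep(n_each, 2)
  run_patch(params, list(strategy_a, strategy_b), counts, seed,
            mutual_immunity = mutual_immunity, ...)
}
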