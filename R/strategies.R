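#' Define a T6SS firing phenotype
#'
#' A strategy bundles everything the combat module needs to know about a
#' genotype: whether it carries the weapon, how often it fires spontaneously,
#' how many counterattacks it launches per hit sustained, whether those
#' counterattacks are aimed back along the incoming needle, and how firing
#' costs are charged.
#'
#' Built-in phenotypes:
#' * [strategy_random()] — constitutive random firer ("R"): Poisson firings
#'   from random surface points along the outward normal.
#' * [strategy_unarmed()] — T6SS-negative ("U"): never fires, pays no costs,
#'   can be killed.
#' * [strategy_retaliator()] — tit-for-tat family ("TFT", "2TFT", ...): fires
#'   `multiplicity` needles per hit sustained, by default from the impact
#'   point, reversed along the incoming needle.
#' * [strategy_cheater()] — carries T6SS genes (pays `c_upfront`, can share
#'   immunity) but never fires ("Rc").
#'
#' @param name Label used in summaries and fitness tables.
#' @param carries_t6ss Does the genotype carry (and pay for) T6SS genes?
#' @param k_fire Constitutive firing rate (firings / cell / h); 0 for
#'   unarmed cells and pure retaliators.
#' @param retaliation_multiplicity Counterattacks fired per hit sustained.
#' @param aiming If `TRUE`, counterattacks are launched from the recorded
#'   entry point, reversed along the incoming needle; if `FALSE`, from random
#'   surface points along the outward normal (aiming knockout).
#' @param cost_saving If `TRUE` the pro-rata cost is charged per realized
#'   firing, `c * N_firings / dt`; if `FALSE` the cell pays like a reference
#'   random firer, `c * k_fire_ref`, regardless of actual firings
#'   (cost-saving knockout).
#' @param k_fire_ref Reference firing rate used when `cost_saving = FALSE`.
#' @param immune_to Character vector of strategy names whose toxins this
#'   strategy resists (clonemates are always immune to each other).
#'
#' @return An object of class `t6_strategy`.
#' @examples
#' strategy_retaliator(multiplicity = 2)          # the "2TFT" strong retaliator
#' strategy_retaliator(aiming = FALSE, k_fire_ref = 50, cost_saving = FALSE)
#' @export
strategy_spec <- function(name, carries_t6ss = TRUE, k_fire = 0,
                          retaliation_multiplicity = 0, aiming = TRUE,
                          cost_saving = TRUE, k_fire_ref = 0,
                          immune_to = character()) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!carries_t6ss && (k_fire != 0 || retaliation_multiplicity != 0))
    stop("a T6SS-negative strategy cannot fire or retaliate")
  if (k_fire < 0 || retaliation_multiplicity < 0 || k_fire_ref < 0)
    stop("rates and multiplicities must be non-negative")
  if (retaliation_multiplicity != round(retaliation_multiplicity))
    stop("retaliation_multiplicity must be an integer")
  if (!cost_saving && carries_t6ss && k_fire_ref <= 0 && k_fire <= 0)
    stop("cost_saving = FALSE needs a positive k_fire_ref (or k_fire)")
  structure(list(name = name, carries_t6ss = carries_t6ss, k_fire = k_fire,
                 retaliation_multiplicity = as.integer(retaliation_multiplicity),
                 aiming = aiming, cost_saving = cost_saving,
                 k_fire_ref = if (!cost_saving && k_fire_ref <= 0) k_fire else k_fire_ref,
                 immune_to = unique(as.character(immune_to))),
            class = "t6_strategy")
}

#' @rdname strategy_spec
#' @param ... Passed on to [strategy_spec()].
#' @export
strategy_random <- function(k_fire = 50, name = "R", ...) {
  strategy_spec(name = name, carries_t6ss = TRUE, k_fire = k_fire, ...)
}

#' @rdname strategy_spec
#' @export
strategy_unarmed <- function(name = "U", ...) {
  strategy_spec(name = name, carries_t6ss = FALSE, ...)
}

#' @rdname strategy_spec
#' @param multiplicity Counterattacks per hit sustained (1 = TFT, 2 = 2TFT).
#' @export
strategy_retaliator <- function(multiplicity = 1,
                                name = if (multiplicity == 1) "TFT"
                                       else paste0(multiplicity, "TFT"),
                                aiming = TRUE, cost_saving = TRUE,
                                k_fire_ref = 0, ...) {
  strategy_spec(name = name, carries_t6ss = TRUE, k_fire = 0,
                retaliation_multiplicity = multiplicity, aiming = aiming,
                cost_saving = cost_saving, k_fire_ref = k_fire_ref, ...)
}

#' @rdname strategy_spec
#' @export
strategy_cheater <- function(name = "Rc", ...) {
  strategy_spec(name = name, carries_t6ss = TRUE, k_fire = 0,
                retaliation_multiplicity = 0, ...)
}

#' @export
print.t6_strategy <- function(x, ...) {
  cat(sprintf("T6SS strategy '%s': %s", x$name,
              if (!x$carries_t6ss) "unarmed"
              else if (x$k_fire > 0) sprintf("random firer, k_fire = %g /h", x$k_fire)
              else if (x$retaliation_multiplicity > 0)
                sprintf("retaliator, %d counterattack(s) per hit%s",
                        x$retaliation_multiplicity,
                        if (x$aiming) ", aimed" else ", unaimed")
              else "armed but silent (cheater)"), "\n")
  if (!x$cost_saving)
    cat(sprintf("  cost-saving knockout: pays c * %g regardless of firings\n",
                x$k_fire_ref))
  if (length(x$immune_to))
    cat("  immune to:", paste(x$immune_to, collapse = ", "), "\n")
  invisible(x)
}
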