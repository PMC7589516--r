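# Adaptive-dynamics layer: fitness tables and invasion indices.
#
# A fitness table stores per-replicate invasion fitnesses
# omega_focal(focal | partner): the focal strategist's log biovolume ratio in
# a 1:1 mixed patch with the partner. "primed" pairings are re-run with the
# two strains mutually immune.

#' Build a fitness table
#'
#' @param df Data frame with columns `focal`, `partner` (strategy names),
#'   `primed` (logical), `replicate` (integer) and `omega`.
#' @return The validated data frame with class `t6_fitness_table`.
#' @export
fitness_table <- function(df) {
  need <- c("focal", "partner", "primed", "replicate", "omega")
  if (!all(need %in% names(df)))
    stop("fitness table needs columns: ", paste(need, collapse = ", "))
  df$primed <- as.logical(df$primed)
  structure(as.data.frame(df), class = c("t6_fitness_table", "data.frame"))
}

#' Mean fitness entry of a table
#'
#' @param tab A [fitness_table()].
#' @param focal,partner Strategy names.
#' @param primed Use the mutually immune pairing?
#' @param fallback For primed self-pairings of strategists that never fire
#'   at each other anyway (unarmed cells, pure retaliators), fall back to
#'   the unprimed entry when the primed one is absent.
#' @return Mean omega over replicates.
#' @export
omega_mean <- function(tab, focal, partner, primed = FALSE, fallback = FALSE) {
  rows <- tab$focal == focal & tab$partner == partner & tab$primed == primed
  if (!any(rows)) {
    if (primed && fallback)
      return(omega_mean(tab, focal, partner, primed = FALSE))
    stop(sprintf("fitness table has no entry omega_%s(%s|%s%s)",
                 focal, focal, partner, if (primed) "'" else ""))
  }
  mean(tab$omega[rows])
}

# ratio with the extinction sentinels: invader extinct -> 0 (cannot invade);
# non-positive resident fitness -> +Inf (invader wins trivially).
invasion_ratio <- function(num, den) {
  if (is.infinite(num) && num < 0) return(0)
  if (den <= 0 || (is.infinite(den) && den < 0)) return(Inf)
  num / den
}

classify_entry <- function(I1, I2, guard_geq = TRUE, tol = 0) {
  resists <- if (guard_geq) I2 >= 1 - tol else I2 <= 1 + tol
  if (I1 > 1 + tol) {
    if (resists) "invades_and_resists" else "invades_only"
  } else if (abs(I1 - 1) <= tol || I1 == 1) "neutral_boundary"
  else "cannot_invade"
}

#' Local invasion index
#'
#' Ratio of the invader's to the resident's fitness within the mixed patch:
#' the invader spreads when the index exceeds 1.
#'
#' @param tab A [fitness_table()].
#' @param invader,resident Strategy names.
#' @return A single number (with `0` / `Inf` extinction sentinels).
#' @export
local_invasion_index <- function(tab, invader, resident) {
  invasion_ratio(omega_mean(tab, invader, resident),
                 omega_mean(tab, resident, invader))
}

#' Global (metapopulation) invasion check
#'
#' A rare invader in a resident-dominated metapopulation grows at its
#' fitness against the resident, while residents mostly meet residents:
#' entry requires `I1 = omega_inv(inv|res) / omega_res(res|res) > 1`. Once
#' common, the invader resists re-invasion when
#' `I2 = omega_inv(inv|inv) / omega_res(inv|res) >= 1`.
#'
#' @inheritParams local_invasion_index
#' @param tol Two-sided neutral band around 1 used for classification
#'   (e.g. a multiple of the replicate standard error).
#' @return List with `I1`, `I2` and the `verdict`
#'   (`invades_and_resists`, `invades_only`, `neutral_boundary`,
#'   `cannot_invade`).
#' @export
global_invasion_check <- function(tab, invader, resident, tol = 0) {
  I1 <- invasion_ratio(omega_mean(tab, invader, resident),
                       omega_mean(tab, resident, resident))
  I2 <- invasion_ratio(omega_mean(tab, invader, invader),
                       omega_mean(tab, resident, invader))
  list(I1 = I1, I2 = I2, scale = "global",
       verdict = classify_entry(I1, I2, guard_geq = TRUE, tol = tol))
}

#' Global invasion indices under partial mutual immunity
#'
#' With probability `p_s` two T6SS-carrying strains share effector-immunity
#' pairs, so a strategist's effective fitness is the `p_s`-weighted sum of
#' its fitness against the mutually immune (primed) and vulnerable
#' pairings. T6SS carriage is a prerequisite for immunity: pairings
#' involving an unarmed strain are never primed. The entry index divides
#' the invader's weighted mixed-patch fitness by the resident's
#' self-pairing fitness (unweighted, as the resident monoculture entry);
#' the guard index `I2` is the resident's weighted mixed fitness over the
#' invader's weighted self fitness, and blocks re-invasion when `<= 1`.
#'
#' @inheritParams global_invasion_check
#' @param p_s Probability that two T6SS-positive strains are mutually
#'   immune, in `[0, 1]`.
#' @param carries Named logical vector: does each strategy carry T6SS genes?
#' @return List with `I1`, `I2` (guard direction `<= 1`) and `verdict`.
#' @export
mutual_immunity_indices <- function(tab, p_s, invader, resident, carries,
                                    tol = 0) {
  stopifnot(p_s >= 0, p_s <= 1)
  ps_pair <- if (isTRUE(carries[[invader]]) && isTRUE(carries[[resident]])) p_s else 0
  ps_inv <- if (isTRUE(carries[[invader]])) p_s else 0
  w_mix <- function(focal, partner, ps) {
    if (ps == 0) return(omega_mean(tab, focal, partner))
    ps * omega_mean(tab, focal, partner, primed = TRUE) +
      (1 - ps) * omega_mean(tab, focal, partner)
  }
  I1 <- invasion_ratio(w_mix(invader, resident, ps_pair),
                       omega_mean(tab, resident, resident))
  I2 <- invasion_ratio(w_mix(resident, invader, ps_pair),
                       w_mix(invader, invader, ps_inv))
  resists <- I2 <= 1 + tol
  verdict <- if (I1 > 1 + tol) {
    if (resists) "invades_and_resists" else "invades_only"
  } else if (abs(I1 - 1) <= tol || I1 == 1) "neutral_boundary"
  else "cannot_invade"
  list(I1 = I1, I2 = I2, p_s = p_s, scale = "global", verdict = verdict)
}

#' Invasion indices under within-patch relatedness
#'
#' With probability `I_weight` a strategist finds itself in a perfectly
#' segregated patch, i.e. paired with mutually immune clonemates; with
#' probability `1 - I_weight` it competes with the other strategist. The
#' invader's effective fitness is
#' `I * omega_inv(inv|inv') + (1 - I) * omega_inv(inv|res)`.
#' Locally this is compared against the resident's analogous weighting; for
#' the global scale the entry denominator is the resident's self fitness
#' (residents only meet residents, and unarmed strains and pure retaliators
#' undertake no firing against themselves, so their primed and unprimed
#' self-pairings coincide) and the guard `I2` (resident weighted over
#' invader weighted-self, re-invasion blocked when `<= 1`).
#'
#' @inheritParams global_invasion_check
#' @param I_weight Probability of perfect strategist segregation, `[0, 1]`.
#' @param scale `"local"` or `"global"`.
#' @return For `"local"`: list with `I` and `verdict`-style comparison.
#'   For `"global"`: list with `I1`, `I2` and `verdict`.
#' @export
relatedness_indices <- function(tab, I_weight, invader, resident,
                                scale = c("local", "global"), tol = 0) {
  stopifnot(I_weight >= 0, I_weight <= 1)
  scale <- match.arg(scale)
  Iw <- I_weight
  self_primed <- function(focal)
    omega_mean(tab, focal, focal, primed = TRUE, fallback = TRUE)
  w_inv <- if (Iw == 0) omega_mean(tab, invader, resident)
           else Iw * self_primed(invader) + (1 - Iw) * omega_mean(tab, invader, resident)
  if (scale == "local") {
    w_res <- if (Iw == 0) omega_mean(tab, resident, invader)
             else Iw * self_primed(resident) + (1 - Iw) * omega_mean(tab, resident, invader)
    I <- invasion_ratio(w_inv, w_res)
    return(list(I = I, I_weight = Iw, scale = "local",
                verdict = if (I > 1 + tol) "invades"
                          else if (abs(I - 1) <= tol || I == 1) "neutral_boundary"
                          else "cannot_invade"))
  }
  I1 <- invasion_ratio(w_inv, omega_mean(tab, resident, resident))
  w_res_rare <- if (Iw == 0) omega_mean(tab, resident, invader)
                else Iw * self_primed(resident) + (1 - Iw) * omega_mean(tab, resident, invader)
  w_inv_common <- if (Iw == 0) omega_mean(tab, invader, invader)
                  else Iw * self_primed(invader) + (1 - Iw) * omega_mean(tab, invader, invader)
  I2 <- invasion_ratio(w_res_rare, w_inv_common)
  resists <- I2 <= 1 + tol
  verdict <- if (I1 > 1 + tol) {
    if (resists) "invades_and_resists" else "invades_only"
  } else if (abs(I1 - 1) <= tol || I1 == 1) "neutral_boundary"
  else "cannot_invade"
  list(I1 = I1, I2 = I2, I_weight = Iw, scale = "global", verdict = verdict)
}

#' Six-index summary of a cheater triplet
#'
#' A cheater strain carries its parent's T6SS genes (paying the carriage
#' cost and possibly sharing immunity) but never fires. The invasion
#' behaviour of the grouping \{parent, partner, cheater\} is summarized by
#' the two mutual-immunity invasion indices of each ordered pairing:
#' parent vs partner, cheater vs parent, cheater vs partner.
#'
#' @param tab A [fitness_table()] containing all required pairings.
#' @param parent,partner,cheater Strategy names.
#' @inheritParams mutual_immunity_indices
#' @return A data frame with one row per pairing: `invader`, `resident`,
#'   `I1`, `I2`, `verdict`.
#' @export
cheater_triplet <- function(tab, parent, partner, cheater = "Rc", p_s,
                            carries, tol = 0) {
  pairs <- list(c(parent, partner), c(cheater, parent), c(cheater, partner))
  rows <- lapply(pairs, function(pr) {
    idx <- mutual_immunity_indices(tab, p_s, pr[1], pr[2], carries, tol = tol)
    data.frame(invader = pr[1], resident = pr[2],
               I1 = idx$I1, I2 = idx$I2, verdict = idx$verdict)
  })
  do.call(rbind, rows)
}

#' Simulate a fitness table from patch competitions
#'
#' Runs replicated 1:1 patch competitions for the requested pairings and
#' collects both strategists' invasion fitnesses. Self-pairings are run as
#' two genotype copies of the same strategy (mutually toxic unless primed).
#'
#' @param strategies Named list of [strategy_spec()] objects.
#' @param pairings List of pairings, each a list/vector
#'   `(a, b)` of strategy names, optionally with a `primed` attribute, or a
#'   data frame with columns `a`, `b`, `primed`.
#' @param params A [sim_params()] object.
#' @param n_each Initial cells per strategist.
#' @param replicates Replicate competitions per pairing.
#' @param seed Base seed; replicate `r` of pairing `k` uses
#'   `seed + 1000 * k + r`.
#' @return A [fitness_table()].
#' @export
simulate_fitness_table <- function(strategies, pairings, params = sim_params(),
                                   n_each = 100, replicates = 5, seed = 1) {
  if (is.data.frame(pairings))
    pairings <- lapply(seq_len(nrow(pairings)), function(i)
      list(a = pairings$a[i], b = pairings$b[i], primed = isTRUE(pairings$primed[i])))
  rows <- list()
  for (k in seq_along(pairings)) {
    pr <- pairings[[k]]
    a <- if (!is.null(pr$a)) pr$a else pr[[1]]
    b <- if (!is.null(pr$b)) pr$b else pr[[2]]
    primed <- isTRUE(pr$primed)
    sa <- strategies[[a]]; sb <- strategies[[b]]
    if (is.null(sa) || is.null(sb)) stop("unknown strategy in pairing ", k)
    for (r in seq_len(replicates)) {
      run <- compete(sa, sb, params = params, n_each = n_each,
                     seed = seed + 1000L * k + r,
                     mutual_immunity = primed, snapshot_every = 0)
      nm <- run$summary$name
      rows[[length(rows) + 1L]] <- data.frame(
        focal = c(a, b), partner = c(b, a), primed = primed, replicate = r,
        omega = c(omega_of(run, nm[1]), omega_of(run, nm[2])))
    }
  }
  fitness_table(do.call(rbind, rows))
}

omega_of <- function(run, name) {
  s <- run$summary[run$summary$name == name, ]
  if (s$v_end <= 0) -Inf else log(s$v_end / s$v0)
}
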