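# Competition outcome measures, the static hit assay, comparative statistics.

#' Final cell-count proportion of a genotype
#'
#' @param run A `t6_run`.
#' @param genotype Strategy name or genotype id.
#' @return Final cells of the genotype divided by total final cells
#'   (0 if extinct). Errors if the patch ended empty.
#' @export
final_proportion <- function(run, genotype) {
  s <- summary_row(run, genotype)
  tot <- sum(run$summary$n_end)
  if (tot == 0) stop("empty patch: final proportion undefined")
  s$n_end / tot
}

#' Invasion fitness of a strategist in a patch competition
#'
#' The natural log of the final-to-initial biovolume ratio,
#' `omega = log(sum V(t_end) / sum V(t_start))`. Extinction gives `-Inf`,
#' which downstream invasion indices treat as "cannot invade".
#'
#' @inheritParams final_proportion
#' @return A single number (possibly `-Inf`).
#' @export
strategist_fitness <- function(run, genotype) {
  s <- summary_row(run, genotype)
  if (s$v0 <= 0) stop("genotype absent at start: fitness undefined")
  if (s$v_end <= 0) return(-Inf)
  log(s$v_end / s$v0)
}

summary_row <- function(run, genotype) {
  stopifnot(inherits(run, "t6_run"))
  s <- run$summary
  row <- if (is.character(genotype)) s[s$name == genotype, , drop = FALSE]
         else s[s$genotype == genotype, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown genotype: ", genotype)
  row
}

#' Per-cell growth rates of a genotype
#'
#' @param patch A `t6_patch` (e.g. `run$patch` at the end of a competition).
#' @param genotype Strategy name or genotype id.
#' @return A list with the per-cell `values`, `label`, `n`, `mean` and `sd`.
#' @export
growth_rate_summary <- function(patch, genotype) {
  stopifnot(inherits(patch, "t6_patch"))
  g <- if (is.character(genotype)) match(genotype, patch$strat$name) else genotype
  if (is.na(g) || g < 1 || g > length(patch$strat$name))
    stop("unknown genotype: ", genotype)
  v <- patch$cells$kgrow[patch$cells$genotype == g & !patch$cells$lysing]
  if (length(v) == 0) stop("no live cells of genotype ", genotype)
  list(values = v, label = patch$strat$name[g], n = length(v),
       mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
}

#' Pooled-variance two-sample t test and Cohen's d
#'
#' Computed from the textbook formulas: pooled two-sample t with
#' `n1 + n2 - 2` degrees of freedom, two-sided p value, and effect size
#' `d = (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`. Signs follow
#' sample1 minus sample2. With zero pooled variance, equal means give
#' `t = 0`; unequal means give infinite sentinels.
#'
#' @param sample1,sample2 Numeric vectors of length at least 2.
#' @return `two_sample_t`: list with `t`, `dof`, `p`. `cohens_d`: a number.
#' @examples
#' two_sample_t(rnorm(20, 1), rnorm(20))
#' cohens_d(c(1, 2, 3), c(0, 1, 2))
#' @export
two_sample_t <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 observations")
  m1 <- mean(sample1); m2 <- mean(sample2)
  sp2 <- ((n1 - 1) * stats::var(sample1) + (n2 - 1) * stats::var(sample2)) /
    (n1 + n2 - 2)
  dof <- n1 + n2 - 2
  if (sp2 <= 0) {
    tval <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tval, dof = dof, p = 2 * pt(-abs(tval), dof))
}

#' @rdname two_sample_t
#' @export
cohens_d <- function(sample1, sample2) {
  s1 <- sd(sample1); s2 <- sd(sample2)
  denom <- sqrt((s1^2 + s2^2) / 2)
  m <- mean(sample1) - mean(sample2)
  if (denom == 0) return(if (m == 0) 0 else sign(m) * Inf)
  m / denom
}

#' Static T6SS hit-probability assay
#'
#' Measures hit:miss ratios in a frozen cell configuration (no growth,
#' death or movement). For a random-firing strategy, each event fires one
#' needle from a random surface point of a random cell of that genotype.
#' For a retaliator, focal cells are first exposed to random incoming
#' needles from non-clonemate cells; each incoming hit is answered with
#' `retaliation_multiplicity` counterattacks (reversed along the incoming
#' needle, or from random surface points for aiming knockouts), and every
#' counterattack is one event. Each event records whether it struck any
#' cell and whether it struck a non-clonemate.
#'
#' @param patch A frozen `t6_patch` containing the strategies of interest.
#' @param strategy_pair Character vector of strategy names to assay.
#' @param n_events Firing events per strategy.
#' @param seed Integer seed (assay-local; the patch is not modified).
#' @return A list per strategy with the per-event 0/1 `samples` data frame
#'   and the `absolute_hit_prob` and `nonclonemate_hit_prob` estimates.
#' @export
static_hit_assay <- function(patch, strategy_pair, n_events, seed = 1) {
  stopifnot(inherits(patch, "t6_patch"))
  if (n_events <= 0) stop("n_events must be positive")
  res <- with_rng_state(rng_state_from_seed(seed), function() {
    out <- list()
    for (nm in strategy_pair) out[[nm]] <- assay_one_strategy(patch, nm, n_events)
    out
  })
  res$value
}

assay_one_strategy <- function(patch, name, n_events) {
  g <- match(name, patch$strat$name)
  if (is.na(g)) stop("unknown strategy: ", name)
  cs <- patch$cells
  p <- patch$params
  focal <- which(cs$genotype == g & !cs$lysing)
  if (length(focal) == 0) stop("no live cells of strategy ", name)
  mult <- patch$strat$mult[g]

  hit_any <- hit_noncl <- logical(0)
  if (mult == 0) {
    idx <- focal[sample.int(length(focal), n_events, replace = TRUE)]
    sp <- sample_capsule_perimeter(cs$x[idx], cs$y[idx], cs$ax[idx],
                                   cs$ay[idx], cs$seg[idx], p$R_cell)
    needles <- data.frame(ox = sp$ox, oy = sp$oy, dx = sp$dx, dy = sp$dy,
                          len = p$L_needle, source_idx = idx)
    hits <- detect_hits_impl(needles, patch)
    hit_any <- seq_len(n_events) %in% hits$needle
    noncl <- hits$needle[hits$target_genotype != g]
    hit_noncl <- seq_len(n_events) %in% noncl
  } else {
    attackers <- which(cs$genotype != g & !cs$lysing)
    if (length(attackers) == 0)
      stop("retaliator assay needs non-clonemate cells in the patch")
    guard <- 0L
    while (length(hit_any) < n_events && guard < 10000L) {
      guard <- guard + 1L
      bn <- 256L
      idx <- attackers[sample.int(length(attackers), bn, replace = TRUE)]
      sp <- sample_capsule_perimeter(cs$x[idx], cs$y[idx], cs$ax[idx],
                                     cs$ay[idx], cs$seg[idx], p$R_cell)
      incoming <- data.frame(ox = sp$ox, oy = sp$oy, dx = sp$dx, dy = sp$dy,
                             len = p$L_needle, source_idx = idx)
      inc_hits <- detect_hits_impl(incoming, patch)
      inc_hits <- inc_hits[inc_hits$target_genotype == g, , drop = FALSE]
      if (nrow(inc_hits) == 0) next
      rep_idx <- rep(seq_len(nrow(inc_hits)), each = mult)
      if (patch$strat$aiming[g]) {
        counter <- data.frame(ox = inc_hits$ex[rep_idx], oy = inc_hits$ey[rep_idx],
                              dx = -inc_hits$dx[rep_idx], dy = -inc_hits$dy[rep_idx],
                              len = p$L_needle,
                              source_idx = inc_hits$target_idx[rep_idx])
      } else {
        ci <- inc_hits$target_idx[rep_idx]
        sp2 <- sample_capsule_perimeter(cs$x[ci], cs$y[ci], cs$ax[ci],
                                        cs$ay[ci], cs$seg[ci], p$R_cell)
        counter <- data.frame(ox = sp2$ox, oy = sp2$oy, dx = sp2$dx, dy = sp2$dy,
                              len = p$L_needle, source_idx = ci)
      }
      chits <- detect_hits_impl(counter, patch)
      ha <- seq_len(nrow(counter)) %in% chits$needle
      hn <- seq_len(nrow(counter)) %in% chits$needle[chits$target_genotype != g]
      hit_any <- c(hit_any, ha)
      hit_noncl <- c(hit_noncl, hn)
    }
    if (length(hit_any) < n_events)
      stop("assay could not generate enough retaliation events")
    hit_any <- hit_any[seq_len(n_events)]
    hit_noncl <- hit_noncl[seq_len(n_events)]
  }
  list(samples = data.frame(event = seq_len(n_events),
                            hit_any = as.numeric(hit_any),
                            hit_nonclonemate = as.numeric(hit_noncl)),
       label = name, n = n_events,
       absolute_hit_prob = mean(hit_any),
       nonclonemate_hit_prob = mean(hit_noncl))
}

#' Spatial segregation index
#'
#' Mean over cells of the fraction of same-genotype neighbours within a
#' given radius (centre-to-centre). Random 50:50 labels give about 0.5;
#' fully demixed populations give 1.
#'
#' @param patch A `t6_patch` with at least two genotypes present.
#' @param radius Neighbourhood radius (µm), positive.
#' @return A fraction in `[0, 1]` (cells without neighbours are ignored).
#' @export
segregation_index <- function(patch, radius) {
  stopifnot(inherits(patch, "t6_patch"))
  if (radius <= 0) stop("radius must be positive")
  cs <- patch$cells
  if (length(unique(cs$genotype)) < 2)
    stop("segregation index needs at least two genotypes present")
  n <- length(cs$id)
  dmat <- as.matrix(stats::dist(cbind(cs$x, cs$y)))
  same <- outer(cs$genotype, cs$genotype, "==")
  neigh <- dmat <= radius & !diag(n)
  k <- rowSums(neigh)
  frac <- rowSums(neigh & same)[k > 0] / k[k > 0]
  if (length(frac) == 0) {
    warning("no cell has neighbours within the given radius")
    return(NA_real_)
  }
  mean(frac)
}
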