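# T6SS firing, hit detection, intoxication, lysis bookkeeping.

#' Schedule this step's T6SS firings
#'
#' Random firers draw `Poisson(k_fire * dt)` needle counts, with origins
#' uniform on the capsule perimeter and directions along the outward surface
#' normal. Retaliators answer every hit queued during the previous step with
#' `retaliation_multiplicity` needles each: aimed retaliators fire from the
#' recorded entry point, reversed along the incoming needle; aiming
#' knockouts fire the same number from random surface points. Unarmed cells
#' and cheaters never fire; lysing cells fire nothing and their queues are
#' discarded. Per-cell firing counts are stored for the cost model and the
#' consumed retaliation queue is cleared.
#'
#' @param patch A `t6_patch`.
#' @return A list with `patch` (updated RNG stream, firing counts, cleared
#'   queue) and `needles`, a data frame with origin, direction, length and
#'   source of every needle fired this step.
#' @export
schedule_firings <- function(patch) {
  stopifnot(inherits(patch, "t6_patch"))
  res <- with_rng_state(patch$rng, function() schedule_firings_impl(patch))
  out <- res$value
  out$patch$rng <- res$rng
  out
}

schedule_firings_impl <- function(patch) {
  p <- patch$params
  cs <- patch$cells
  st <- patch$strat
  g <- cs$genotype
  n <- length(cs$id)
  firings <- rep(0, n)

  ox <- oy <- dx <- dy <- numeric(0)
  src <- integer(0)

  # constitutive random firers, in cell order
  rf <- which(st$k_fire[g] > 0 & !cs$lysing)
  if (length(rf)) {
    counts <- rpois(length(rf), st$k_fire[g[rf]] * p$dt)
    firings[rf] <- counts
    rep_idx <- rep(rf, counts)
    if (length(rep_idx)) {
      sp <- sample_capsule_perimeter(cs$x[rep_idx], cs$y[rep_idx],
                                     cs$ax[rep_idx], cs$ay[rep_idx],
                                     cs$seg[rep_idx], p$R_cell)
      ox <- c(ox, sp$ox); oy <- c(oy, sp$oy)
      dx <- c(dx, sp$dx); dy <- c(dy, sp$dy)
      src <- c(src, rep_idx)
    }
  }

  # retaliators answer hits queued last step
  if (nrow(patch$retal)) {
    q <- patch$retal
    qidx <- match(q[, "cell_id"], cs$id)
    live <- !is.na(qidx) & !cs$lysing[pmax(qidx, 1)]
    q <- q[live, , drop = FALSE]
    qidx <- qidx[live]
    if (length(qidx)) {
      mult <- st$mult[g[qidx]]
      keep <- mult > 0
      q <- q[keep, , drop = FALSE]; qidx <- qidx[keep]; mult <- mult[keep]
      if (length(qidx)) {
        aimed <- st$aiming[g[qidx]]
        rep_q <- rep(seq_along(qidx), mult)
        cell_of <- qidx[rep_q]
        is_aimed <- aimed[rep_q]
        if (any(is_aimed)) {
          rows <- rep_q[is_aimed]
          ox <- c(ox, q[rows, "ex"]); oy <- c(oy, q[rows, "ey"])
          dx <- c(dx, -q[rows, "dx"]); dy <- c(dy, -q[rows, "dy"])
          src <- c(src, cell_of[is_aimed])
        }
        if (any(!is_aimed)) {
          ci <- cell_of[!is_aimed]
          sp <- sample_capsule_perimeter(cs$x[ci], cs$y[ci], cs$ax[ci],
                                         cs$ay[ci], cs$seg[ci], p$R_cell)
          ox <- c(ox, sp$ox); oy <- c(oy, sp$oy)
          dx <- c(dx, sp$dx); dy <- c(dy, sp$dy)
          src <- c(src, ci)
        }
        cnt <- tabulate(cell_of, nbins = n)
        firings <- firings + cnt
      }
    }
  }

  patch$retal <- patch$retal[0, , drop = FALSE]
  patch$cells$firings <- firings
  patch$n_needles_total <- patch$n_needles_total + length(src)
  list(patch = patch,
       needles = data.frame(ox = ox, oy = oy, dx = dx, dy = dy,
                            len = rep(p$L_needle, length(src)),
                            source_idx = src,
                            source_id = cs$id[src]))
}

#' Resolve needle hits against the cell population
#'
#' Two-step hit detection: a cell (other than the source) is a candidate if
#' the minimum distance between the needle segment and the cell's axis
#' segment is below `R_cell - L_penetration`; for each candidate the entry
#' point is the nearest crossing of the capsule surface along the needle,
#' and the needle strikes only the candidate whose entry point lies closest
#' to its origin (needles stop at the first cell). At most one hit per
#' needle; misses yield no record.
#'
#' @param needles Data frame from [schedule_firings()] (columns `ox, oy, dx,
#'   dy, len, source_idx`).
#' @param patch A `t6_patch`.
#' @return A data frame of hit records: needle index, source and target ids
#'   and genotypes, entry point, `clonemate` and `intoxicating` flags.
#' @export
detect_hits <- function(needles, patch) {
  stopifnot(inherits(patch, "t6_patch"))
  detect_hits_impl(needles, patch)
}

detect_hits_impl <- function(needles, patch) {
  cs <- patch$cells
  empty <- data.frame(needle = integer(0), source_idx = integer(0),
                      source_id = integer(0), target_idx = integer(0),
                      target_id = integer(0), source_genotype = integer(0),
                      target_genotype = integer(0), ex = numeric(0),
                      ey = numeric(0), dx = numeric(0), dy = numeric(0),
                      clonemate = logical(0), intoxicating = logical(0))
  if (is.null(needles) || nrow(needles) == 0 || length(cs$id) == 0)
    return(empty)
  m <- detect_hits_cpp(cbind(needles$ox, needles$oy),
                       cbind(needles$dx, needles$dy),
                       needles$len, as.integer(needles$source_idx),
                       cs$x, cs$y, cs$ax, cs$ay, half_lengths(patch),
                       patch$params$R_cell, patch$params$L_penetration)
  if (nrow(m) == 0) return(empty)
  ni <- as.integer(m[, 1]); ti <- as.integer(m[, 2])
  si <- as.integer(needles$source_idx[ni])
  gs <- cs$genotype[si]; gt <- cs$genotype[ti]
  clone <- gs == gt
  immune <- patch$strat$immunity[cbind(gt, gs)]
  data.frame(needle = ni, source_idx = si, source_id = cs$id[si],
             target_idx = ti, target_id = cs$id[ti],
             source_genotype = gs, target_genotype = gt,
             ex = m[, 3], ey = m[, 4],
             dx = needles$dx[ni], dy = needles$dy[ni],
             clonemate = clone,
             intoxicating = !clone & !immune & !cs$lysing[ti])
}

#' Apply intoxication and queue retaliations
#'
#' Every intoxicating hit (non-clonemate, not covered by an immunity
#' relation, target not already lysing) increments the target's cumulative
#' translocation count; a cell whose count reaches `N_hits` commits to lysis
#' with removal deadline `t + 1/k_lysis` (step-like dose response). Every
#' non-clonemate hit on a live retaliator — including hits from mutually
#' immune strains, which perturb the membrane without intoxicating — queues
#' an (entry point, incoming direction) pair to be answered next step. A hit
#' that pushes a cell over the lysis threshold does not queue a
#' counterattack. Clonemate hits have no effect at all.
#'
#' @param hits Data frame from [detect_hits()].
#' @param patch A `t6_patch`.
#' @return The updated patch.
#' @export
apply_intoxication <- function(hits, patch) {
  stopifnot(inherits(patch, "t6_patch"))
  apply_intoxication_impl(hits, patch)
}

apply_intoxication_impl <- function(hits, patch) {
  if (is.null(hits) || nrow(hits) == 0) return(patch)
  p <- patch$params
  cs <- patch$cells
  st <- patch$strat

  tox <- hits[hits$intoxicating, , drop = FALSE]
  newly <- integer(0)
  if (nrow(tox)) {
    inc <- tabulate(tox$target_idx, nbins = length(cs$id))
    cs$trans <- cs$trans + inc
    newly <- which(cs$trans >= p$N_hits & !cs$lysing & inc > 0)
    if (length(newly)) {
      cs$lysing[newly] <- TRUE
      cs$deadline[newly] <- patch$t + 1 / p$k_lysis
      cs$kgrow[newly] <- 0
      patch$log$lysis[[length(patch$log$lysis) + 1L]] <-
        cbind(step = patch$step_count, id = cs$id[newly],
              genotype = cs$genotype[newly])
    }
  }

  # retaliation: any non-clonemate hit on a live retaliator
  retal_ok <- !hits$clonemate &
    st$mult[hits$target_genotype] > 0 &
    !cs$lysing[hits$target_idx]
  if (any(retal_ok)) {
    h <- hits[retal_ok, , drop = FALSE]
    patch$retal <- rbind(patch$retal,
                         cbind(cell_id = h$target_id, ex = h$ex, ey = h$ey,
                               dx = h$dx, dy = h$dy))
  }

  patch$log$hits[[length(patch$log$hits) + 1L]] <-
    cbind(step = patch$step_count, source_id = hits$source_id,
          target_id = hits$target_id, source_genotype = hits$source_genotype,
          target_genotype = hits$target_genotype, ex = hits$ex, ey = hits$ey,
          intoxicating = as.numeric(hits$intoxicating))
  patch$cells <- cs
  patch
}

#' Remove cells whose lysis delay has elapsed
#'
#' Lysing cells are deleted once `lysis_deadline <= t` (they were mechanical
#' obstacles until now); deaths are logged per genotype.
#'
#' @param patch A `t6_patch`.
#' @return The updated patch.
#' @export
remove_lysed <- function(patch) {
  stopifnot(inherits(patch, "t6_patch"))
  remove_lysed_impl(patch)
}

remove_lysed_impl <- function(patch) {
  cs <- patch$cells
  gone <- which(cs$lysing & cs$deadline <= patch$t)
  if (length(gone) == 0) return(patch)
  patch$log$deaths[[length(patch$log$deaths) + 1L]] <-
    cbind(step = patch$step_count, id = cs$id[gone], genotype = cs$genotype[gone])
  g <- patch$strat$name[cs$genotype[gone]]
  for (nm in g) patch$deaths[nm] <- patch$deaths[nm] + 1L
  keep <- setdiff(seq_along(cs$id), gone)
  patch$cells <- lapply(cs, function(v) v[keep])
  # queued retaliations of removed cells die with them
  if (nrow(patch$retal))
    patch$retal <- patch$retal[patch$retal[, "cell_id"] %in% patch$cells$id, ,
                               drop = FALSE]
  patch
}
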