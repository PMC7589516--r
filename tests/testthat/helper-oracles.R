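# Independent oracles and small fixtures shared across test files.
# Oracles are deliberately naive (marching, gridding, brute force) and do not
# reuse any code path they are checking.

# Small, fast parameter sets used throughout the tests.
tiny_params <- function(...) {
  sim_params(E_0 = 300, arena_radius = 12, ...)
}

# Brute-force distance between two capsule axes by two-stage grid refinement
# over both segment parameters (coarse global grid, then a fine local grid
# around the coarse minimum). Independent of the closest-point algebra.
grid_capsule_gap <- function(a, b, radius, n1 = 120, n2 = 200) {
  ends <- function(cell) {
    hx <- cell$axis[1] * cell$seg_length / 2
    hy <- cell$axis[2] * cell$seg_length / 2
    list(p0 = cell$center[1:2] - c(hx, hy), p1 = cell$center[1:2] + c(hx, hy))
  }
  ea <- ends(a); eb <- ends(b)
  eval_grid <- function(s, t) {
    pa_x <- outer(ea$p0[1] + s * (ea$p1[1] - ea$p0[1]), rep(1, length(t)))
    pa_y <- outer(ea$p0[2] + s * (ea$p1[2] - ea$p0[2]), rep(1, length(t)))
    pb_x <- outer(rep(1, length(s)), eb$p0[1] + t * (eb$p1[1] - eb$p0[1]))
    pb_y <- outer(rep(1, length(s)), eb$p0[2] + t * (eb$p1[2] - eb$p0[2]))
    sqrt((pa_x - pb_x)^2 + (pa_y - pb_y)^2)
  }
  s <- seq(0, 1, length.out = n1); t <- seq(0, 1, length.out = n1)
  d <- eval_grid(s, t)
  ij <- which(d == min(d), arr.ind = TRUE)[1, ]
  w <- 1.5 / n1
  s2 <- seq(max(0, s[ij[1]] - w), min(1, s[ij[1]] + w), length.out = n2)
  t2 <- seq(max(0, t[ij[2]] - w), min(1, t[ij[2]] + w), length.out = n2)
  min(eval_grid(s2, t2)) - 2 * radius
}

# Ray-marching needle oracle: walk the needle in small steps; a cell is a
# candidate when the walked distance to its axis drops below R - Lpen; the
# struck cell is the candidate whose radius-R crossing happens first. For
# near-threshold grazing passes the coarse minimum is re-marched on a fine
# local grid so that candidacy does not depend on the coarse step landing
# inside a sub-step-wide dip.
march_needle <- function(ox, oy, dx, dy, len, cells, R, Lpen, step = 1e-3,
                         exclude = 0L) {
  walk_dist <- function(s, q0x, q0y, q1x, q1y) {
    px <- ox + s * dx; py <- oy + s * dy
    vx <- q1x - q0x; vy <- q1y - q0y
    c2 <- vx * vx + vy * vy
    tt <- if (c2 > 0) pmin(1, pmax(0, ((px - q0x) * vx + (py - q0y) * vy) / c2)) else 0
    sqrt((px - (q0x + tt * vx))^2 + (py - (q0y + tt * vy))^2)
  }
  s <- seq(0, len, by = step)
  best <- list(target = 0L, s_entry = Inf)
  for (j in seq_along(cells$x)) {
    if (j == exclude) next
    q0x <- cells$x[j] - cells$ax[j] * cells$h[j]
    q0y <- cells$y[j] - cells$ay[j] * cells$h[j]
    q1x <- cells$x[j] + cells$ax[j] * cells$h[j]
    q1y <- cells$y[j] + cells$ay[j] * cells$h[j]
    dd <- walk_dist(s, q0x, q0y, q1x, q1y)
    dmin <- min(dd)
    if (dmin >= R - Lpen && dmin < R - Lpen + 2 * step) {
      # grazing pass: refine the minimum by marching finer around it
      k0 <- which.min(dd)
      sfine <- seq(max(0, s[k0] - step), min(len, s[k0] + step), by = step / 1000)
      dmin <- min(walk_dist(sfine, q0x, q0y, q1x, q1y))
    }
    if (dmin < R - Lpen) {
      k <- which(dd <= R)[1]           # first walked point inside radius R
      s_entry <- s[k]
      if (k > 1) {
        # refine the crossing on a fine local grid so that near-ties between
        # candidate cells are ordered correctly
        sfine <- seq(s[k - 1], s[k], by = step / 1000)
        dfine <- walk_dist(sfine, q0x, q0y, q1x, q1y)
        s_entry <- sfine[which(dfine <= R)[1]]
      }
      if (s_entry < best$s_entry) best <- list(target = j, s_entry = s_entry)
    }
  }
  best
}

cells_from_patch <- function(patch) {
  list(x = patch$cells$x, y = patch$cells$y, ax = patch$cells$ax,
       ay = patch$cells$ay, h = patch$cells$seg / 2)
}

# random fitness table over the given strategy names, with primed variants
random_fitness_table <- function(names, seed) {
  set.seed(seed)
  rows <- expand.grid(focal = names, partner = names,
                      primed = c(FALSE, TRUE), stringsAsFactors = FALSE)
  rows$replicate <- 1L
  rows$omega <- runif(nrow(rows), 0.2, 3)
  fitness_table(rows)
}

# Build a small patch with hand-set poses (for combat unit tests).
# `poses` is a data frame with columns genotype (sorted ascending), x, y,
# ax, ay and optionally seg; cells are stored in genotype order.
posed_patch <- function(params, strategies, poses, mutual_immunity = FALSE,
                        seed = 42) {
  stopifnot(!is.unsorted(poses$genotype))
  counts <- vapply(seq_along(strategies), function(i)
    sum(poses$genotype == i), 0L)
  big <- params
  big$arena_radius <- 1000    # placement always succeeds; poses overwritten
  patch <- make_initial_patch(big, strategies, counts, seed = seed,
                              mutual_immunity = mutual_immunity)
  stopifnot(identical(patch$cells$genotype, as.integer(poses$genotype)))
  patch$cells$x <- poses$x
  patch$cells$y <- poses$y
  nrm <- sqrt(poses$ax^2 + poses$ay^2)
  patch$cells$ax <- poses$ax / nrm
  patch$cells$ay <- poses$ay / nrm
  if (!is.null(poses$seg)) {
    patch$cells$seg <- poses$seg
    patch$cells$vol <- capsule_volume(poses$seg, params$R_cell)
  }
  patch$params <- params
  patch
}

# cross-block scratch space for the acceptance checks (e.g. comparing the
# resilient and fragile retaliator contrasts)
.acceptance_cache <- new.env(parent = emptyenv())

# Plain-arithmetic fitness-table lookup used by the index oracles.
om <- function(tab, focal, partner, primed = FALSE) {
  mean(tab$omega[tab$focal == focal & tab$partner == partner &
                   tab$primed == primed])
}
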