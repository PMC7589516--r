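# Patch state: one simulation arena. Cells are stored as parallel vectors in
# patch$cells for speed; strategy attributes are cached per genotype so hot
# loops never touch the strategy objects.

# --- RNG plumbing -----------------------------------------------------------
# Each patch carries its own RNG state so that step_patch(patch) is a pure
# function of its argument; the caller's global RNG is left untouched.

rng_state_from_seed <- function(seed) {
  force(seed)   # evaluate caller expressions before snapshotting the RNG
  old <- get_global_rng()
  on.exit(set_global_rng(old))
  set.seed(seed)
  get_global_rng()
}

get_global_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_global_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# Run fn() with the patch's RNG stream active; return list(value, rng).
with_rng_state <- function(state, fn) {
  force(state)  # evaluate caller expressions before snapshotting the RNG
  old <- get_global_rng()
  on.exit(set_global_rng(old))
  set_global_rng(state)
  value <- fn()
  list(value = value, rng = get_global_rng())
}

# --- construction -----------------------------------------------------------

#' Generate a seeded initial patch
#'
#' Places the requested numbers of cells of each strategy uniformly at random
#' (position and in-plane orientation) in a disc of radius
#' `params$arena_radius`, by rejection sampling until no two capsules overlap.
#' Initial volumes receive a uniform jitter in `[0, eta_division)` so that
#' division times desynchronize. Identical inputs and seed give bit-identical
#' patches.
#'
#' @param params A [sim_params()] object.
#' @param strategies List of [strategy_spec()] objects; genotype ids are
#'   assigned in order (1, 2, ...).
#' @param counts Integer vector, cells per strategy.
#' @param seed Integer seed for the patch's private RNG stream.
#' @param mutual_immunity If `TRUE`, all pairs of T6SS-carrying strategies
#'   are mutually immune (hits still trigger retaliation but never
#'   intoxicate). Used for the "primed" fitness entries.
#' @return An object of class `t6_patch`.
#' @examples
#' p <- make_initial_patch(sim_params(), list(strategy_random(), strategy_unarmed()),
#'                         counts = c(10, 10), seed = 1)
#' table(cell_table(p)$genotype)
#' @export
make_initial_patch <- function(params, strategies, counts, seed,
                               mutual_immunity = FALSE) {
  stopifnot(inherits(params, "t6_params"))
  if (inherits(strategies, "t6_strategy")) strategies <- list(strategies)
  if (!all(vapply(strategies, inherits, TRUE, "t6_strategy")))
    stop("'strategies' must be a list of strategy_spec objects")
  if (length(counts) != length(strategies))
    stop("'counts' must have one entry per strategy")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  nms <- vapply(strategies, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("strategy names must be unique")

  G <- length(strategies)
  ntot <- sum(counts)
  res <- with_rng_state(rng_state_from_seed(seed), function() {
    place_cells(params, counts)
  })
  placed <- res$value

  genotype <- rep(seq_len(G), counts)
  vol <- placed$vol
  seg <- capsule_seg_length(vol, params$R_cell)

  carries <- vapply(strategies, `[[`, TRUE, "carries_t6ss")
  imm <- diag(G) > 0                      # imm[target, shooter]
  if (mutual_immunity && G > 1) {
    for (a in seq_len(G)) for (b in seq_len(G))
      if (a != b && carries[a] && carries[b]) imm[a, b] <- TRUE
  }
  for (g in seq_len(G)) {
    hits_from <- match(strategies[[g]]$immune_to, nms)
    hits_from <- hits_from[!is.na(hits_from)]
    imm[g, hits_from] <- TRUE
  }

  strat <- list(
    name = nms,
    carries = carries,
    k_fire = vapply(strategies, `[[`, 0, "k_fire"),
    mult = vapply(strategies, `[[`, 0L, "retaliation_multiplicity"),
    aiming = vapply(strategies, `[[`, TRUE, "aiming"),
    cost_saving = vapply(strategies, `[[`, TRUE, "cost_saving"),
    k_fire_ref = vapply(strategies, `[[`, 0, "k_fire_ref"),
    immunity = imm)

  kgrow0 <- params$k_max * (1 - ifelse(strat$carries[genotype],
                                       pmin(1, params$c_upfront +
                                              ifelse(strat$cost_saving[genotype], 0,
                                                     params$c * strat$k_fire_ref[genotype])),
                                       0))
  cells <- list(
    id = seq_len(ntot), genotype = genotype,
    x = placed$x, y = placed$y, ax = placed$ax, ay = placed$ay,
    seg = seg, vol = vol, kgrow = kgrow0,
    trans = rep(0, ntot), lysing = rep(FALSE, ntot),
    deadline = rep(Inf, ntot),
    eta_target = placed$eta_target,
    firings = rep(0, ntot))

  init <- data.frame(
    genotype = seq_len(G), name = nms,
    n0 = as.integer(counts),
    v0 = vapply(seq_len(G), function(g) sum(vol[genotype == g]), 0))

  structure(list(
    t = 0, E = params$E_0, step_count = 0L,
    params = params, strategies = strategies, strat = strat,
    cells = cells, next_id = ntot + 1L,
    retal = matrix(numeric(0), ncol = 5,
                   dimnames = list(NULL, c("cell_id", "ex", "ey", "dx", "dy"))),
    initial = init,
    births = setNames(rep(0L, G), nms), deaths = setNames(rep(0L, G), nms),
    log = list(hits = list(), lysis = list(), deaths = list(), fires = list()),
    n_needles_total = 0,
    rng = res$rng,
    seed = seed), class = "t6_patch")
}

# Sequential rejection-sampling placement; errors if the arena is too dense.
place_cells <- function(params, counts) {
  ntot <- sum(counts)
  R <- params$R_cell
  x <- y <- ax <- ay <- h <- numeric(0)
  vol <- eta_target <- numeric(ntot)
  segs <- numeric(ntot)
  if (ntot == 0)
    return(list(x = x, y = y, ax = ax, ay = ay, vol = vol, eta_target = eta_target))
  max_attempts <- 5000L
  for (i in seq_len(ntot)) {
    vol[i] <- params$V_0 + runif(1, 0, params$eta_division)
    eta_target[i] <- 2 * params$V_0 + runif(1, 0, params$eta_division)
    segs[i] <- capsule_seg_length(vol[i], R)
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- params$arena_radius * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      cx <- r * cos(th); cy <- r * sin(th)
      phi <- runif(1, 0, 2 * pi)
      cax <- cos(phi); cay <- sin(phi)
      if (i == 1 || min_gap_cpp(x, y, ax, ay, h, R, cx, cy, cax, cay, segs[i] / 2) >= 0) {
        x <- c(x, cx); y <- c(y, cy); ax <- c(ax, cax); ay <- c(ay, cay)
        h <- c(h, segs[i] / 2)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("initial density too high: could not place cell ", i,
           " after ", max_attempts, " attempts; enlarge arena_radius or reduce counts")
  }
  list(x = x, y = y, ax = ax, ay = ay, vol = vol, eta_target = eta_target)
}

# --- accessors --------------------------------------------------------------

#' Cells of a patch as a data frame
#'
#' One row per cell: pose, size, growth rate, intoxication state.
#' @param patch A `t6_patch`.
#' @return A data frame.
#' @export
cell_table <- function(patch) {
  stopifnot(inherits(patch, "t6_patch"))
  cs <- patch$cells
  data.frame(id = cs$id, genotype = cs$genotype,
             name = patch$strat$name[cs$genotype],
             x = cs$x, y = cs$y, z = 0,
             ax = cs$ax, ay = cs$ay, az = 0,
             seg_length = cs$seg, volume = cs$vol,
             k_grow = cs$kgrow, translocations = cs$trans,
             lysing = cs$lysing)
}

#' @rdname cell_table
#' @export
n_cells <- function(patch) length(patch$cells$id)

#' Export a patch's cell table as CSV
#' @param patch A `t6_patch`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_patch_csv <- function(patch, path) {
  write.csv(cell_table(patch), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.t6_patch <- function(x, ...) {
  tab <- table(factor(x$strat$name[x$cells$genotype], levels = x$strat$name))
  cat(sprintf("T6SS patch: t = %.3f h, E = %.1f / %.1f, %d cells\n",
              x$t, x$E, x$params$E_0, n_cells(x)))
  for (nm in names(tab)) cat(sprintf("  %-6s %d\n", nm, tab[[nm]]))
  invisible(x)
}

half_lengths <- function(patch) patch$cells$seg / 2

# per-cell drags: translation ~ length, rotation ~ length^3 / 12
cell_drags <- function(patch) {
  len <- patch$cells$seg + 2 * patch$params$R_cell
  list(t = patch$params$drag_coeff * len,
       r = patch$params$drag_coeff * len^3 / 12)
}
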