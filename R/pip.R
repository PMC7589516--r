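# Invasion traces along a firing-rate grid, pairwise invasibility plots,
# and ESS detection.

#' Classify invasion outcomes along a firing-rate grid
#'
#' Takes the four fitness entries needed by the local and global invasion
#' constraints at each firing rate, inserts one linearly interpolated value
#' between each pair of adjacent grid points, and classifies every original
#' and interpolated rate under both competition scales.
#'
#' @param k_grid Sorted firing-rate grid (ascending, length >= 2).
#' @param omega_sweep Data frame with one row per grid point and columns
#'   `w_inv_mixed` (invader's fitness in the mixed patch), `w_res_mixed`
#'   (resident's fitness in the mixed patch), `w_inv_self`, `w_res_self`
#'   (self-pairing fitnesses).
#' @param tol Neutral band for classification.
#' @return A data frame with the densified grid, an `interpolated` flag,
#'   the local index and global `I1`, `I2`, and both verdicts.
#' @export
build_invasion_trace <- function(k_grid, omega_sweep, tol = 0) {
  if (length(k_grid) < 2) stop("k_grid needs at least 2 points")
  if (is.unsorted(k_grid, strictly = TRUE)) stop("k_grid must be sorted ascending")
  if (nrow(omega_sweep) != length(k_grid))
    stop("omega_sweep must have one row per grid point")
  need <- c("w_inv_mixed", "w_res_mixed", "w_inv_self", "w_res_self")
  if (!all(need %in% names(omega_sweep)))
    stop("omega_sweep needs columns: ", paste(need, collapse = ", "))

  mid_k <- (head(k_grid, -1) + tail(k_grid, -1)) / 2
  dense_k <- sort(c(k_grid, mid_k))
  interp <- !(dense_k %in% k_grid)
  cols <- lapply(omega_sweep[need], function(v)
    approx(k_grid, v, xout = dense_k)$y)

  n <- length(dense_k)
  I_local <- I1 <- I2 <- numeric(n)
  v_local <- v_global <- character(n)
  for (i in seq_len(n)) {
    I_local[i] <- invasion_ratio(cols$w_inv_mixed[i], cols$w_res_mixed[i])
    I1[i] <- invasion_ratio(cols$w_inv_mixed[i], cols$w_res_self[i])
    I2[i] <- invasion_ratio(cols$w_inv_self[i], cols$w_res_mixed[i])
    v_local[i] <- if (I_local[i] > 1 + tol) "invades"
                  else if (abs(I_local[i] - 1) <= tol || I_local[i] == 1) "neutral_boundary"
                  else "cannot_invade"
    v_global[i] <- classify_entry(I1[i], I2[i], guard_geq = TRUE, tol = tol)
  }
  data.frame(k = dense_k, interpolated = interp, I_local = I_local,
             I1_global = I1, I2_global = I2,
             verdict_local = v_local, verdict_global = v_global)
}

#' Pairwise invasibility plot over a firing-rate grid
#'
#' For every (resident rate, mutant rate) pair, runs replicated mixed
#' competitions of two random-firing strategists (plus the resident's
#' self-pairings for the global scale), averages the invasion fitnesses
#' over replicates, and fills the invasion-index matrix
#' `I[resident, mutant]`. Values above 1 mean the mutant invades.
#'
#' @param k_res_grid,k_mut_grid Firing-rate grids (resident rows, mutant
#'   columns).
#' @param simulator Function `(k_focal, k_partner, seed)` returning a
#'   length-2 numeric `c(omega_focal, omega_partner)` for one mixed run of
#'   rates `k_focal` vs `k_partner`. Lets tests substitute a deterministic
#'   stub for the full agent-based simulation.
#' @param scale `"local"` (ratio of the two mixed-patch fitnesses) or
#'   `"global"` (mutant mixed fitness over resident self fitness).
#' @param replicates Replicates per matrix entry.
#' @param seed Base seed; entry seeds are derived deterministically.
#' @return An object of class `t6_pip`: the index matrix `I`, the grids,
#'   the scale, and a matrix `missing` flagging failed entries.
#' @export
pairwise_invasion_plot <- function(k_res_grid, k_mut_grid, simulator,
                                   scale = c("local", "global"),
                                   replicates = 1, seed = 1) {
  scale <- match.arg(scale)
  stopifnot(replicates >= 1, length(k_res_grid) >= 1, length(k_mut_grid) >= 1)
  nr <- length(k_res_grid); nc <- length(k_mut_grid)
  I <- matrix(NA_real_, nr, nc)
  miss <- matrix(FALSE, nr, nc)
  self_cache <- rep(NA_real_, nr)

  entry_seed <- function(i, j, r)
    (seed * 7919L + i * 1009L + j * 101L + r) %% 2147483587L

  for (i in seq_len(nr)) {
    if (scale == "global") {
      vals <- numeric(0)
      for (r in seq_len(replicates)) {
        res <- try(simulator(k_res_grid[i], k_res_grid[i],
                             entry_seed(i, 0L, r)), silent = TRUE)
        if (!inherits(res, "try-error")) vals <- c(vals, res)
      }
      self_cache[i] <- if (length(vals)) mean(vals) else NA_real_
    }
    for (j in seq_len(nc)) {
      wm <- wr <- numeric(0)
      for (r in seq_len(replicates)) {
        res <- try(simulator(k_mut_grid[j], k_res_grid[i],
                             entry_seed(i, j, r)), silent = TRUE)
        if (inherits(res, "try-error")) next
        wm <- c(wm, res[1]); wr <- c(wr, res[2])
      }
      if (length(wm) == 0 || (scale == "global" && is.na(self_cache[i]))) {
        miss[i, j] <- TRUE
        next
      }
      I[i, j] <- if (scale == "local") invasion_ratio(mean(wm), mean(wr))
                 else invasion_ratio(mean(wm), self_cache[i])
    }
  }
  structure(list(I = I, k_res_grid = k_res_grid, k_mut_grid = k_mut_grid,
                 scale = scale, replicates = replicates, seed = seed,
                 missing = miss),
            class = "t6_pip")
}

#' Locate evolutionarily stable firing rates on a PIP
#'
#' A resident rate is an ESS when no mutant rate on the grid can invade it
#' (all invasion indices along its row are `<= 1` within the stated noise
#' tolerance). Also runs the incremental-mutation walk: starting from a
#' grid end, the resident is repeatedly replaced by an adjacent mutant that
#' invades it, which traces the expected convergence of successive
#' invasions towards the ESS.
#'
#' Uninvadable rates on the grid boundary are reported separately as
#' `boundary_candidates`: with selection pointing towards (or beyond) a grid
#' edge, stability there cannot be distinguished from grid truncation —
#' re-grid over a wider range to resolve them.
#'
#' @param pip A `t6_pip`, or a plain invasion-index matrix.
#' @param k_grid Needed when `pip` is a plain matrix; the shared
#'   resident/mutant grid.
#' @param tol Noise tolerance around 1.
#' @return List with `ess` (interior grid rates, possibly empty),
#'   `boundary_candidates`, the two walk trajectories (`walk_from_low`,
#'   `walk_from_high`, as rate vectors), `converged` (both walks end on an
#'   ESS) and a `diagnostic` string.
#' @export
find_ess <- function(pip, k_grid = NULL, tol = 1e-9) {
  if (inherits(pip, "t6_pip")) {
    if (!identical(pip$k_res_grid, pip$k_mut_grid))
      stop("ESS search needs matching resident and mutant grids")
    I <- pip$I; k_grid <- pip$k_res_grid
  } else {
    I <- as.matrix(pip)
    if (is.null(k_grid)) stop("supply k_grid with a plain matrix")
  }
  n <- length(k_grid)
  stopifnot(nrow(I) == n, ncol(I) == n)

  uninvadable <- which(vapply(seq_len(n), function(i)
    all(I[i, -i] <= 1 + tol, na.rm = FALSE), TRUE))
  ess_idx <- setdiff(uninvadable, c(1L, n))
  boundary_idx <- intersect(uninvadable, c(1L, n))

  walk <- function(start) {
    i <- start
    path <- k_grid[i]
    for (itc in seq_len(n * n)) {
      up <- i < n && !is.na(I[i, i + 1]) && I[i, i + 1] > 1 + tol
      dn <- i > 1 && !is.na(I[i, i - 1]) && I[i, i - 1] > 1 + tol
      nxt <- if (up) i + 1L else if (dn) i - 1L else break
      i <- nxt
      path <- c(path, k_grid[i])
    }
    list(path = path, end = i)
  }
  lo <- walk(1L); hi <- walk(n)
  converged <- length(ess_idx) > 0 && lo$end %in% ess_idx && hi$end %in% ess_idx
  diagnostic <- if (length(ess_idx) > 0) "ok"
  else if (length(boundary_idx) > 0)
    "no interior ESS: selection is monotone up to a grid edge; re-grid wider"
  else
    "no resident rate on the grid is uninvadable (no sign change in selection)"
  list(ess = k_grid[ess_idx], boundary_candidates = k_grid[boundary_idx],
       walk_from_low = lo$path, walk_from_high = hi$path,
       walk_ends = k_grid[c(lo$end, hi$end)],
       converged = converged, diagnostic = diagnostic)
}

#' Simulator factory for R-vs-R pairwise invasibility plots
#'
#' Returns a closure suitable for [pairwise_invasion_plot()]: given two
#' firing rates and a seed it runs one mixed patch competition between two
#' random-firing strategists at those rates and returns their invasion
#' fitnesses.
#'
#' @param params A [sim_params()] object.
#' @param n_each Initial cells per strategist.
#' @return A function `(k_focal, k_partner, seed) -> c(omega_focal,
#'   omega_partner)`.
#' @export
make_r_vs_r_simulator <- function(params = sim_params(), n_each = 50) {
  function(k_focal, k_partner, seed) {
    run <- compete(strategy_random(k_focal, name = "R1"),
                   strategy_random(k_partner, name = "R2"),
                   params = params, n_each = n_each, seed = seed,
                   snapshot_every = 0)
    c(omega_of(run, "R1"), omega_of(run, "R2"))
  }
}
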