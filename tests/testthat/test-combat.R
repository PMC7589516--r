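two_cell_patch <- function(par, strat_a, strat_b, gap = 0.2,
                           mutual_immunity = FALSE) {
  # two parallel cells side by side, separated by `gap` between surfaces
  poses <- data.frame(genotype = c(1, 2), x = 0,
                      y = c(0, 2 * par$R_cell + gap),
                      ax = 1, ay = 0, seg = c(1.4, 1.4))
  posed_patch(par, list(strat_a, strat_b), poses,
              mutual_immunity = mutual_immunity)
}

test_that("unarmed cells and cheaters never fire", {
  par <- sim_params()
  patch <- two_cell_patch(par, strategy_unarmed(), strategy_cheater())
  for (k in 1:50) {
    sf <- schedule_firings(patch)
    patch <- sf$patch
    expect_equal(nrow(sf$needles), 0)
  }
})

test_that("random firing counts are Poisson with mean k_fire * dt", {
  par <- sim_params(arena_radius = 60)
  patch <- make_initial_patch(par, list(strategy_random(50)), 500, seed = 8)
  draws <- numeric(0)
  for (k in 1:200) {
    sf <- schedule_firings(patch)
    patch <- sf$patch
    draws <- c(draws, patch$cells$firings)
  }
  n <- length(draws)                       # 1e5 draws
  lambda <- 50 * par$dt
  se_mean <- sqrt(lambda / n)
  expect_lt(abs(mean(draws) - lambda), 3 * se_mean)
  # variance check with an empirical standard error for s^2
  s2 <- stats::var(draws)
  m4 <- mean((draws - mean(draws))^4)
  se_var <- sqrt((m4 - s2^2) / n)
  expect_lt(abs(s2 - lambda), 3 * se_var)
})

test_that("needle origins lie on the source surface with outward normals", {
  par <- sim_params(arena_radius = 40)
  patch <- make_initial_patch(par, list(strategy_random(5000)), 30, seed = 9)
  sf <- schedule_firings(patch)
  nd <- sf$needles
  expect_gt(nrow(nd), 0)
  cs <- patch$cells
  for (k in seq_len(nrow(nd))) {
    i <- nd$source_idx[k]
    a <- list(center = c(cs$x[i], cs$y[i]), axis = c(cs$ax[i], cs$ay[i]),
              seg_length = cs$seg[i])
    pt <- list(center = c(nd$ox[k], nd$oy[k]), axis = c(1, 0), seg_length = 0)
    d <- capsule_capsule_distance(a, pt, radius = par$R_cell / 2)$d
    # distance from origin to the axis segment equals R (surface point)
    expect_equal(d + par$R_cell, par$R_cell, tolerance = 1e-6)
    expect_equal(sqrt(nd$dx[k]^2 + nd$dy[k]^2), 1, tolerance = 1e-12)
  }
})

test_that("retaliators answer queued hits with the right multiplicity and geometry", {
  par <- sim_params()
  patch <- two_cell_patch(par, strategy_random(50), strategy_retaliator(2))
  id2 <- patch$cells$id[2]
  queue <- cbind(cell_id = rep(id2, 3),
                 ex = c(0.1, -0.3, 0.5), ey = rep(0.7, 3),
                 dx = c(0, 0.6, 0), dy = c(1, 0.8, 1))
  patch$retal <- queue
  patch$cells$firings <- c(0, 0)
  sf <- schedule_firings(patch)
  ret <- sf$needles[sf$needles$source_idx == 2, ]
  expect_equal(nrow(ret), 6)               # 2 counterattacks per queued hit
  expect_equal(sort(rep(queue[, "ex"], 2)), sort(ret$ox))
  expect_equal(ret$dx, -queue[rep(1:3, each = 2), "dx"])
  expect_equal(ret$dy, -queue[rep(1:3, each = 2), "dy"])
  expect_equal(sf$patch$cells$firings[2], 6)
  expect_equal(nrow(sf$patch$retal), 0)    # queue consumed

  # aiming knockout: same count, random surface origins
  patch2 <- two_cell_patch(par, strategy_random(50),
                           strategy_retaliator(2, aiming = FALSE))
  patch2$retal <- queue
  patch2$retal[, "cell_id"] <- patch2$cells$id[2]
  sf2 <- schedule_firings(patch2)
  ret2 <- sf2$needles[sf2$needles$source_idx == 2, ]
  expect_equal(nrow(ret2), 6)
  expect_false(any(ret2$ox %in% queue[, "ex"]))

  # lysing retaliators stay silent and lose their queue
  patch3 <- two_cell_patch(par, strategy_random(50), strategy_retaliator(2))
  patch3$retal <- queue
  patch3$retal[, "cell_id"] <- patch3$cells$id[2]
  patch3$cells$lysing[2] <- TRUE
  sf3 <- schedule_firings(patch3)
  expect_equal(sum(sf3$needles$source_idx == 2), 0)
  expect_equal(nrow(sf3$patch$retal), 0)
})

test_that("point-blank needles hit and needles fired away miss", {
  par <- sim_params()
  patch <- two_cell_patch(par, strategy_random(50), strategy_unarmed(),
                          gap = 0.1)
  # needle from cell 1's surface straight at cell 2
  toward <- data.frame(ox = 0, oy = par$R_cell, dx = 0, dy = 1,
                       len = par$L_needle, source_idx = 1)
  hit <- detect_hits(toward, patch)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$target_idx, 2)
  expect_false(hit$clonemate)
  # entry point on the target surface within L_penetration
  cs <- patch$cells
  tgt <- list(center = c(cs$x[2], cs$y[2]), axis = c(cs$ax[2], cs$ay[2]),
              seg_length = cs$seg[2])
  ent <- list(center = c(hit$ex, hit$ey), axis = c(1, 0), seg_length = 0)
  dist_to_axis <- capsule_capsule_distance(tgt, ent, radius = 1e-9)$d
  expect_lt(abs(dist_to_axis - par$R_cell), par$L_penetration)

  away <- data.frame(ox = 0, oy = -par$R_cell, dx = 0, dy = -1,
                     len = par$L_needle, source_idx = 1)
  expect_equal(nrow(detect_hits(away, patch)), 0)
})

test_that("hit detection matches the ray-marching oracle on random configurations", {
  par <- sim_params()
  set.seed(33)
  n_pairs <- 800
  mismatches <- 0
  worst_entry <- 0
  for (k in seq_len(n_pairs)) {
    n_targets <- sample(1:3, 1)
    cells <- list(x = runif(n_targets, -1.5, 1.5),
                  y = runif(n_targets, -1.5, 1.5),
                  ax = numeric(n_targets), ay = numeric(n_targets),
                  h = runif(n_targets, 0.3, 1.2))
    th <- runif(n_targets, 0, 2 * pi)
    cells$ax <- cos(th); cells$ay <- sin(th)
    ox <- runif(1, -2, 2); oy <- runif(1, -2, 2)
    phi <- runif(1, 0, 2 * pi)
    got <- detect_hits_cpp(matrix(c(ox, oy), 1), matrix(c(cos(phi), sin(phi)), 1),
                           par$L_needle, 0L, cells$x, cells$y, cells$ax,
                           cells$ay, cells$h, par$R_cell, par$L_penetration)
    oracle <- march_needle(ox, oy, cos(phi), sin(phi), par$L_needle, cells,
                           par$R_cell, par$L_penetration)
    if ((nrow(got) > 0) != (oracle$target > 0)) {
      mismatches <- mismatches + 1
    } else if (nrow(got) > 0) {
      if (got[1, 2] != oracle$target) mismatches <- mismatches + 1
      worst_entry <- max(worst_entry, abs(got[1, 5] - oracle$s_entry))
    }
  }
  expect_equal(mismatches, 0)
  expect_lt(worst_entry, 2e-3)
})

test_that("intoxication thresholds, immunity and the lysis queue behave", {
  par <- sim_params(N_hits = 2, k_lysis = 20)
  patch <- two_cell_patch(par, strategy_random(50), strategy_retaliator(2),
                          gap = 0.1)
  needle <- data.frame(ox = 0, oy = par$R_cell, dx = 0, dy = 1,
                       len = par$L_needle, source_idx = 1)
  hits <- detect_hits(needle, patch)
  expect_true(hits$intoxicating)

  # first hit: intoxicated but not lysing; retaliation queued
  patch <- apply_intoxication(hits, patch)
  expect_equal(patch$cells$trans[2], 1)
  expect_false(patch$cells$lysing[2])
  expect_equal(nrow(patch$retal), 1)

  # second hit: lysing with deadline t + 1/k_lysis; no further retaliation
  patch$retal <- patch$retal[0, , drop = FALSE]
  patch <- apply_intoxication(detect_hits(needle, patch), patch)
  expect_true(patch$cells$lysing[2])
  expect_equal(patch$cells$deadline[2], patch$t + 1 / par$k_lysis)
  expect_equal(patch$cells$kgrow[2], 0)
  expect_equal(nrow(patch$retal), 0)

  # clonemate hits are inert
  mono <- two_cell_patch(par, strategy_random(50), strategy_random(50, name = "R2"))
  mono$cells$genotype <- c(1L, 1L)
  h2 <- detect_hits(needle, mono)
  expect_true(h2$clonemate)
  mono <- apply_intoxication(h2, mono)
  expect_equal(mono$cells$trans, c(0, 0))
  expect_equal(nrow(mono$retal), 0)

  # immune non-clonemate hits do not intoxicate but still provoke retaliation
  imm <- two_cell_patch(par, strategy_random(50), strategy_retaliator(2),
                        mutual_immunity = TRUE)
  h3 <- detect_hits(needle, imm)
  expect_false(h3$intoxicating)
  imm <- apply_intoxication(h3, imm)
  expect_equal(imm$cells$trans[2], 0)
  expect_equal(nrow(imm$retal), 1)

  # N_hits = Inf: translocations accumulate, lysis never triggers
  par_inf <- sim_params(N_hits = Inf)
  tough <- two_cell_patch(par_inf, strategy_random(50), strategy_unarmed(),
                          gap = 0.1)
  for (k in 1:5) tough <- apply_intoxication(detect_hits(needle, tough), tough)
  expect_equal(tough$cells$trans[2], 5)
  expect_false(tough$cells$lysing[2])
})

test_that("lysed cells are removed exactly at their deadline", {
  par <- sim_params()
  poses <- data.frame(genotype = c(1, 1), x = c(0, 5), y = 0, ax = 1, ay = 0)
  patch <- posed_patch(par, list(strategy_unarmed()), poses)
  patch$cells$lysing[1] <- TRUE
  patch$cells$deadline[1] <- patch$t          # boundary: deadline == t
  out <- remove_lysed(patch)
  expect_equal(n_cells(out), 1)
  expect_equal(out$deaths[["U"]], 1L)
  # nothing lysing: patch unchanged
  expect_identical(remove_lysed(out)$cells, out$cells)
})

test_that("monocultures of armed strategists never kill themselves", {
  par <- sim_params(E_0 = 250, arena_radius = 10)
  run <- run_patch(par, list(strategy_random(100)), 30, seed = 12,
                   snapshot_every = 0)
  expect_gt(run$patch$n_needles_total, 0)
  expect_equal(sum(run$summary$deaths), 0L)
  ev <- event_log(run)
  expect_equal(sum(ev$type %in% c("intox", "lyse", "death")), 0)
})

test_that("pure retaliators stay quiescent against unarmed opponents", {
  par <- sim_params(E_0 = 250, arena_radius = 10)
  for (mult in 1:2) {
    run <- run_patch(par, list(strategy_retaliator(mult), strategy_unarmed()),
                     c(15, 15), seed = 13, snapshot_every = 0)
    expect_equal(run$patch$n_needles_total, 0)
    expect_equal(sum(run$summary$deaths), 0L)
  }
})
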