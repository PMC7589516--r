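test_that("local and global indices: worked examples and sentinels", {
  tab <- fitness_table(data.frame(
    focal = c("R", "U", "R", "U"), partner = c("U", "R", "R", "U"),
    primed = FALSE, replicate = 1,
    omega = c(log(4), log(2), 1, 1)))
  expect_equal(local_invasion_index(tab, "R", "U"), 2)
  expect_equal(local_invasion_index(tab, "U", "R"), 0.5)

  tab2 <- fitness_table(data.frame(
    focal = c("R", "U", "R", "U"), partner = c("U", "U", "R", "R"),
    primed = FALSE, replicate = 1, omega = c(2, 1, 1, 0.5)))
  g <- global_invasion_check(tab2, "R", "U")
  expect_equal(g$I1, 2)
  expect_equal(g$I2, 2)
  expect_equal(g$verdict, "invades_and_resists")

  # symmetric table: neutral boundary, guard holds with equality
  tab3 <- fitness_table(expand.grid(focal = c("A", "B"), partner = c("A", "B"),
                                    primed = FALSE, replicate = 1,
                                    stringsAsFactors = FALSE) |>
                          transform(omega = 1))
  g3 <- global_invasion_check(tab3, "A", "B")
  expect_equal(g3$I1, 1)
  expect_equal(g3$verdict, "neutral_boundary")

  # extinction sentinels
  tab4 <- fitness_table(data.frame(
    focal = c("A", "B", "A", "B"), partner = c("B", "A", "A", "B"),
    primed = FALSE, replicate = 1, omega = c(-Inf, 1, 1, 1)))
  expect_equal(local_invasion_index(tab4, "A", "B"), 0)
  expect_equal(global_invasion_check(tab4, "A", "B")$verdict, "cannot_invade")
  tab5 <- fitness_table(data.frame(
    focal = c("A", "B", "A", "B"), partner = c("B", "A", "A", "B"),
    primed = FALSE, replicate = 1, omega = c(1, -Inf, 1, -Inf)))
  expect_equal(local_invasion_index(tab5, "A", "B"), Inf)
  expect_equal(global_invasion_check(tab5, "A", "B")$verdict,
               "invades_and_resists")
  expect_error(omega_mean(tab5, "A", "C"), "no entry")
})

test_that("global R1-vs-R2 antisymmetry: one invading precludes the other", {
  for (s in 1:25) {
    tab <- random_fitness_table(c("R1", "R2"), seed = 600 + s)
    a <- global_invasion_check(tab, "R2", "R1")
    b <- global_invasion_check(tab, "R1", "R2")
    # guard of one pairing is the reciprocal of the other's entry index
    expect_equal(a$I2, 1 / b$I1, tolerance = 1e-12)
    expect_equal(b$I2, 1 / a$I1, tolerance = 1e-12)
  }
})

test_that("invasion algebra matches plain arithmetic on randomized tables", {
  carries <- c(R = TRUE, Y = TRUE, U = FALSE, Rc = TRUE)
  for (s in 1:100) {
    tab <- random_fitness_table(c("R", "Y", "U", "Rc"), seed = s)
    ps <- runif(1)
    Iw <- runif(1)

    # local index (within mixed patch)
    expect_equal(local_invasion_index(tab, "R", "U"),
                 om(tab, "R", "U") / om(tab, "U", "R"), tolerance = 1e-12)

    # global entry and guard
    g <- global_invasion_check(tab, "R", "U")
    expect_equal(g$I1, om(tab, "R", "U") / om(tab, "U", "U"), tolerance = 1e-12)
    expect_equal(g$I2, om(tab, "R", "R") / om(tab, "U", "R"), tolerance = 1e-12)

    # mutual immunity, armed resident: weighted numerators as printed
    mi <- mutual_immunity_indices(tab, ps, "R", "Y", carries)
    expect_equal(mi$I1,
                 (ps * om(tab, "R", "Y", TRUE) + (1 - ps) * om(tab, "R", "Y")) /
                   om(tab, "Y", "Y"), tolerance = 1e-12)
    expect_equal(mi$I2,
                 (ps * om(tab, "Y", "R", TRUE) + (1 - ps) * om(tab, "Y", "R")) /
                   (ps * om(tab, "R", "R", TRUE) + (1 - ps) * om(tab, "R", "R")),
                 tolerance = 1e-12)

    # mutual immunity, unarmed resident: no weighting on the mixed entries
    mu <- mutual_immunity_indices(tab, ps, "R", "U", carries)
    expect_equal(mu$I1, om(tab, "R", "U") / om(tab, "U", "U"), tolerance = 1e-12)
    expect_equal(mu$I2,
                 om(tab, "U", "R") /
                   (ps * om(tab, "R", "R", TRUE) + (1 - ps) * om(tab, "R", "R")),
                 tolerance = 1e-12)

    # relatedness weighting, local and global
    rl <- relatedness_indices(tab, Iw, "R", "Y", scale = "local")
    expect_equal(rl$I,
                 (Iw * om(tab, "R", "R", TRUE) + (1 - Iw) * om(tab, "R", "Y")) /
                   (Iw * om(tab, "Y", "Y", TRUE) + (1 - Iw) * om(tab, "Y", "R")),
                 tolerance = 1e-12)
    rg <- relatedness_indices(tab, Iw, "R", "Y", scale = "global")
    expect_equal(rg$I1,
                 (Iw * om(tab, "R", "R", TRUE) + (1 - Iw) * om(tab, "R", "Y")) /
                   om(tab, "Y", "Y"), tolerance = 1e-12)
    expect_equal(rg$I2,
                 (Iw * om(tab, "Y", "Y", TRUE) + (1 - Iw) * om(tab, "Y", "R")) /
                   (Iw * om(tab, "R", "R", TRUE) + (1 - Iw) * om(tab, "R", "R")),
                 tolerance = 1e-12)
  }
})

test_that("weighted indices collapse to the baseline forms in the limits", {
  carries <- c(R = TRUE, Y = TRUE, U = FALSE)
  for (s in 1:20) {
    tab <- random_fitness_table(c("R", "Y", "U"), seed = 300 + s)
    base <- global_invasion_check(tab, "R", "Y")

    # p_s = 0: mutual-immunity indices lose all primed weight; the guard is
    # the printed reciprocal of the baseline guard
    mi0 <- mutual_immunity_indices(tab, 0, "R", "Y", carries)
    expect_equal(mi0$I1, base$I1, tolerance = 1e-12)
    expect_equal(mi0$I2, om(tab, "Y", "R") / om(tab, "R", "R"),
                 tolerance = 1e-12)
    expect_equal(mi0$I2, 1 / base$I2, tolerance = 1e-12)

    # p_s = 1: only the primed pairing contributes to the entry index
    mi1 <- mutual_immunity_indices(tab, 1, "R", "Y", carries)
    expect_equal(mi1$I1, om(tab, "R", "Y", TRUE) / om(tab, "Y", "Y"),
                 tolerance = 1e-12)

    # I_weight = 0: relatedness indices reduce to the unweighted ratios
    rl0 <- relatedness_indices(tab, 0, "R", "Y", scale = "local")
    expect_equal(rl0$I, local_invasion_index(tab, "R", "Y"), tolerance = 1e-12)
    rg0 <- relatedness_indices(tab, 0, "R", "Y", scale = "global")
    expect_equal(rg0$I1, base$I1, tolerance = 1e-12)
    expect_equal(rg0$I2, 1 / base$I2, tolerance = 1e-12)

    # I_weight = 1: pure self-pairing ratio
    rl1 <- relatedness_indices(tab, 1, "R", "Y", scale = "local")
    expect_equal(rl1$I, om(tab, "R", "R", TRUE) / om(tab, "Y", "Y", TRUE),
                 tolerance = 1e-12)
  }
})

test_that("identical strategists are neutral on noise-free tables", {
  nm <- c("A", "B")
  tab <- fitness_table(expand.grid(focal = nm, partner = nm,
                                   primed = c(FALSE, TRUE), replicate = 1,
                                   stringsAsFactors = FALSE) |>
                         transform(omega = 1.7))
  expect_equal(local_invasion_index(tab, "A", "B"), 1)
  g <- global_invasion_check(tab, "A", "B")
  expect_equal(c(g$I1, g$I2), c(1, 1))
  mi <- mutual_immunity_indices(tab, 0.4, "A", "B", c(A = TRUE, B = TRUE))
  expect_equal(c(mi$I1, mi$I2), c(1, 1))
  rg <- relatedness_indices(tab, 0.5, "A", "B", scale = "global")
  expect_equal(c(rg$I1, rg$I2), c(1, 1))
})

test_that("the six cheater-triplet indices are the pairwise weighted indices", {
  carries <- c(R = TRUE, U = FALSE, Rc = TRUE)
  tab <- random_fitness_table(c("R", "U", "Rc"), seed = 77)
  ps <- 0.37
  out <- cheater_triplet(tab, parent = "R", partner = "U", cheater = "Rc",
                         p_s = ps, carries = carries)
  expect_equal(nrow(out), 3)
  for (i in 1:3) {
    ref <- mutual_immunity_indices(tab, ps, out$invader[i], out$resident[i],
                                   carries)
    expect_equal(out$I1[i], ref$I1, tolerance = 1e-12)
    expect_equal(out$I2[i], ref$I2, tolerance = 1e-12)
    expect_equal(out$verdict[i], ref$verdict)
  }
  expect_error(cheater_triplet(tab, "R", "TFT", "Rc", p_s = 0.5,
                               carries = c(carries, TFT = TRUE)),
               "no entry")
})

test_that("invasion traces densify the grid by midpoints and classify each rate", {
  k <- c(0, 50)
  sweep <- data.frame(w_inv_mixed = c(1, 2), w_res_mixed = c(1, 1),
                      w_inv_self = c(1.5, 1.5), w_res_self = c(1, 1))
  tr <- build_invasion_trace(k, sweep)
  expect_equal(tr$k, c(0, 25, 50))
  expect_equal(tr$interpolated, c(FALSE, TRUE, FALSE))
  expect_equal(tr$I_local, c(1, 1.5, 2))       # linear interpolation of omega
  expect_equal(tr$verdict_local, c("neutral_boundary", "invades", "invades"))
  expect_equal(tr$verdict_global,
               c("neutral_boundary", "invades_and_resists", "invades_and_resists"))

  # constant fitnesses give a uniform classification
  sweep2 <- data.frame(w_inv_mixed = 2, w_res_mixed = 1, w_inv_self = 2,
                       w_res_self = 1)[rep(1, 3), ]
  tr2 <- build_invasion_trace(c(1, 2, 3), sweep2)
  expect_equal(unique(tr2$verdict_global), "invades_and_resists")
  expect_error(build_invasion_trace(c(2, 1), sweep), "sorted")
})

# analytic invasion-fitness stub with a known evolutionary optimum at K:
# selection favours higher rates below K and lower rates above it.
stub_simulator <- function(K) {
  function(k_focal, k_partner, seed) {
    w <- function(mut, res) 1 + (mut - res) * (K - res) / K^2
    c(w(k_focal, k_partner), w(k_partner, k_focal))
  }
}

test_that("PIP matrices reproduce the stub's closed form and a neutral diagonal", {
  K <- 100
  grid <- seq(0, 250, by = 25)
  pip <- pairwise_invasion_plot(grid, grid, stub_simulator(K),
                                scale = "local", replicates = 2, seed = 5)
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    expected <- (1 + (grid[j] - grid[i]) * (K - grid[i]) / K^2) /
      (1 + (grid[i] - grid[j]) * (K - grid[j]) / K^2)
    expect_equal(pip$I[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(diag(pip$I), rep(1, length(grid)))
  # failed simulations are flagged missing, never fabricated
  # (mixed runs are invoked as simulator(k_mutant, k_resident, seed))
  flaky <- function(k1, k2, seed) if (k1 == 25 && k2 == 50) stop("boom") else
    stub_simulator(K)(k1, k2, seed)
  pip2 <- pairwise_invasion_plot(c(25, 50), c(25, 50), flaky,
                                 scale = "local", replicates = 1, seed = 1)
  expect_true(pip2$missing[2, 1])
  expect_true(is.na(pip2$I[2, 1]))
})

test_that("ESS search finds the stub optimum and both walks converge to it", {
  K <- 100
  grid <- seq(0, 250, by = 25)
  # direct matrix of the stub's invasion index I(resident, mutant)
  I <- outer(grid, grid, function(res, mut) 1 + (mut - res) * (K - res) / K^2)
  out <- find_ess(I, k_grid = grid)
  expect_equal(out$ess, K)
  expect_equal(out$walk_ends, c(K, K))
  expect_true(out$converged)
  expect_equal(out$walk_from_low, seq(0, 100, by = 25))
  expect_equal(out$walk_from_high, seq(250, 100, by = -25))

  # monotone selection (faster always wins): no interior ESS; the top grid
  # edge is only a truncation artifact and is reported as such
  Imono <- outer(grid, grid, function(res, mut) 1 + (mut - res) / 1000)
  mono <- find_ess(Imono, k_grid = grid)
  expect_equal(length(mono$ess), 0)
  expect_equal(mono$boundary_candidates, max(grid))
  expect_false(mono$converged)
  expect_match(mono$diagnostic, "no interior ESS")
})

test_that("global competition on a group-penalized stub favours less aggression", {
  # adding a group-productivity penalty to the stub moves the global ESS
  # below the local one
  K <- 100
  grid <- seq(0, 250, by = 12.5)
  local_I <- outer(grid, grid, function(res, mut)
    1 + (mut - res) * (K - res) / K^2)
  global_I <- outer(grid, grid, function(res, mut)
    (1 + (mut - res) * (K - res) / K^2) * (1 - 0.001 * (mut - res)))
  ess_local <- find_ess(local_I, k_grid = grid)$ess
  ess_global <- find_ess(global_I, k_grid = grid, tol = 1e-9)$ess
  expect_true(length(ess_local) >= 1)
  if (length(ess_global) >= 1)
    expect_lte(max(ess_global), min(ess_local))
})

test_that("simulated fitness tables feed the index machinery end to end", {
  par <- sim_params(E_0 = 250, arena_radius = 10)
  strategies <- list(R = strategy_random(50), U = strategy_unarmed())
  pairs <- data.frame(a = c("R", "R", "U"), b = c("U", "R", "U"),
                      primed = FALSE)
  tab <- simulate_fitness_table(strategies, pairs, params = par, n_each = 15,
                                replicates = 2, seed = 3)
  expect_s3_class(tab, "t6_fitness_table")
  # all four entries of the R-vs-U constraint set are present
  for (pair in list(c("R", "U"), c("U", "R"), c("R", "R"), c("U", "U")))
    expect_true(is.finite(omega_mean(tab, pair[1], pair[2])))
  g <- global_invasion_check(tab, "R", "U")
  expect_true(is.finite(g$I1))
  # self-pairings carry both copies: 2 rows per replicate
  expect_equal(sum(tab$focal == "R" & tab$partner == "R"), 4)
})
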