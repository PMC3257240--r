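test_that("first_order_probability is exact", {
  expect_equal(first_order_probability(0, 0.1), 0)
  expect_equal(first_order_probability(1e9, 1), 1, tolerance = 1e-12)
  expect_equal(first_order_probability(0.1, 0.01), 1 - exp(-0.001))
  expect_equal(first_order_probability(0.1, 0.01), 9.995e-4, tolerance = 1e-4)
})

test_that("contact_rule realizes the reaction volume in both geometries", {
  # k = 0: no layer, no probability
  cr <- contact_rule(0.05, 0.05, 0, 0.1, overlap_allowed = FALSE)
  expect_equal(cr$delta, 0)
  expect_equal(cr$probability, 0)
  # non-overlap: the shell volume equals V_r exactly
  cr <- contact_rule(0.05, 0.4, 5e8, 0.1, overlap_allowed = FALSE)
  R <- 0.45
  shell <- 4 / 3 * pi * ((R + cr$delta)^3 - R^3)
  expect_equal(shell, cr$V_r, tolerance = 1e-9)
  expect_equal(cr$V_r, reaction_volume(5e8, 0.1))
  # overlap: P linear in dt below the clamp
  p1 <- contact_rule(0.1, 0.1, 1e7, 0.05, overlap_allowed = TRUE)$probability
  p2 <- contact_rule(0.1, 0.1, 1e7, 0.10, overlap_allowed = TRUE)$probability
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
  # clamp warns
  expect_warning(contact_rule(0.01, 0.01, 1e9, 1, overlap_allowed = TRUE),
                 "clamped")
})

test_that("reaction_volume conversion constant is right", {
  # 1e9 / (M s) over 1 s -> 1e9/NA litres -> x 1e15 um^3
  expect_equal(reaction_volume(1e9, 1), 1e9 / 6.02214076e23 * 1e15)
})

test_that("well-mixed A+B->C tracks the mass-action ODE (dilute)", {
  # particle simulation in a periodic-free box approximated by a large cell;
  # oracle: analytic solution of equal-concentration second-order kinetics
  set.seed(5)
  L <- 2                                   # box radius um
  V_um3 <- 4 / 3 * pi * L^3
  nA <- 250; nB <- 250
  k <- 2e6                                 # 1/(M s), reaction-limited regime
  dt <- 0.05
  agents <- list(pos = rbind(matrix(runif(3 * nA, -L, L), ncol = 3),
                             matrix(runif(3 * nB, -L, L), ncol = 3)),
                 species = c(rep("A", nA), rep("B", nB)),
                 radius = rep(0.05, nA + nB),
                 alive = rep(TRUE, nA + nB))
  keep_in <- function(pp) sqrt(rowSums(pp^2)) <= L
  rules <- list(reaction_rule(2L, c("A", "B"), "C", k, overlap_allowed = TRUE))
  times <- seq(0, 15, by = dt)
  na_t <- numeric(length(times)); na_t[1] <- nA
  for (i in seq_along(times)[-1]) {
    idx <- agents$alive
    agents$pos[idx, ] <- diffusion_step(agents$pos[idx, , drop = FALSE],
                                        1.0, dt, obstacle = keep_in)
    ev <- pair_reaction_sweep(agents, rules, dt)
    if (nrow(ev)) agents$alive[c(ev$i, ev$j)] <- FALSE
    na_t[i] <- sum(agents$alive & agents$species == "A")
  }
  # oracle: dA/dt = -k' A^2 with A in counts, k' = k/(NA V)
  kc <- k / (6.02214076e23 * V_um3 * 1e-15)
  a_ode <- nA / (1 + kc * nA * times)
  # compare the integrated trajectories (relative L1 error)
  rel <- sum(abs(na_t - a_ode)) / sum(a_ode)
  expect_lt(rel, 0.05)
})

test_that("pair sweep conserves partners and respects emptiness", {
  agents <- list(pos = rbind(c(0, 0, 0), c(0.005, 0, 0)),
                 species = c("A", "B"), radius = c(0.01, 0.01),
                 alive = c(TRUE, TRUE))
  rules <- list(reaction_rule(2L, c("A", "B"), "C", 1e12,
                              overlap_allowed = TRUE))
  set.seed(1)
  # the huge rate clamps the acceptance probability by design here
  ev <- suppressWarnings(pair_reaction_sweep(agents, rules, 0.1))
  expect_equal(nrow(ev), 1)                 # A consumed exactly once
  # out of range -> empty
  agents$pos[2, ] <- c(2, 0, 0)
  ev <- suppressWarnings(pair_reaction_sweep(agents, rules, 0.1))
  expect_equal(nrow(ev), 0)
})

test_that("first_order_sweep recovers the decay constant and branching", {
  set.seed(6)
  n <- 10000
  agents <- list(pos = matrix(0, n, 3), species = rep("A", n),
                 radius = rep(0.01, n), alive = rep(TRUE, n))
  rules <- list(reaction_rule(1L, "A", "B", k = 0.1))
  dt <- 0.05
  alive_t <- numeric(120)
  for (i in 1:120) {
    ev <- first_order_sweep(agents, rules, dt)
    if (nrow(ev)) agents$alive[ev$i] <- FALSE
    alive_t[i] <- sum(agents$alive)
  }
  # exponential fit via log-linear regression
  tt <- (1:120) * dt
  fit <- lm(log(alive_t) ~ tt)
  expect_equal(unname(-coef(fit)[2]), 0.1, tolerance = 0.02)

  # two equal competing channels split 50:50
  set.seed(7)
  n <- 4000
  agents <- list(pos = matrix(0, n, 3), species = rep("A", n),
                 radius = rep(0.01, n), alive = rep(TRUE, n))
  rules <- list(reaction_rule(1L, "A", "B", 0.5),
                reaction_rule(1L, "A", "C", 0.5))
  nb <- 0; nc <- 0
  for (i in 1:60) {
    ev <- first_order_sweep(agents, rules, 0.1)
    if (nrow(ev)) {
      agents$alive[ev$i] <- FALSE
      nb <- nb + sum(ev$rule == 1); nc <- nc + sum(ev$rule == 2)
    }
  }
  frac <- nb / (nb + nc)
  expect_equal(frac, 0.5, tolerance = 0.05)
  # k = 0: nothing fires
  agents$alive <- rep(TRUE, n)
  ev <- first_order_sweep(agents, list(reaction_rule(1L, "A", "B", 0)), 0.1)
  expect_equal(nrow(ev), 0)
})

test_that("halving dt leaves the well-mixed trajectory unchanged (robustness)", {
  run_decay <- function(dt, seed) {
    set.seed(seed)
    n <- 3000
    agents <- list(pos = matrix(0, n, 3), species = rep("A", n),
                   radius = rep(0.01, n), alive = rep(TRUE, n))
    rules <- list(reaction_rule(1L, "A", "B", 0.2))
    for (i in seq_len(round(5 / dt))) {
      ev <- first_order_sweep(agents, rules, dt)
      if (nrow(ev)) agents$alive[ev$i] <- FALSE
    }
    sum(agents$alive)
  }
  a <- mean(vapply(1:4, function(s) run_decay(0.1, s), 0))
  b <- mean(vapply(1:4, function(s) run_decay(0.05, 10 + s), 0))
  expected <- 3000 * exp(-0.2 * 5)
  mc_sd <- sqrt(3000 * exp(-1) * (1 - exp(-1)) / 4)
  expect_lt(abs(a - expected), 4 * mc_sd)
  expect_lt(abs(b - expected), 4 * mc_sd)
  expect_lt(abs(a - b), 6 * mc_sd)
})
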