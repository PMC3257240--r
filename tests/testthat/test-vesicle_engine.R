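test_that("catcher_binding_rate is linear and reaches two-state equilibrium", {
  expect_equal(catcher_binding_rate(1e6, 0), 0)
  expect_equal(catcher_binding_rate(1e6, 10), 1e7)
  expect_equal(catcher_binding_rate(1e6, 20), 2 * catcher_binding_rate(1e6, 10))

  # two-state Markov chain: bound/free ratio -> p_on/p_off (per-sweep
  # probabilities), oracle = closed-form stationary distribution
  set.seed(8)
  p_on <- 0.05; p_off <- 0.02
  state <- 0L; bound_time <- 0L; nstep <- 40000
  for (i in seq_len(nstep)) {
    if (state == 0L) { if (runif(1) < p_on) state <- 1L }
    else { if (runif(1) < p_off) state <- 0L }
    bound_time <- bound_time + state
  }
  frac <- bound_time / nstep
  expect_equal(frac, p_on / (p_on + p_off), tolerance = 0.03)
})

test_that("internal first-order chemistry matches the exponential decay", {
  set.seed(9)
  k <- 0.05; dt <- 0.1
  nrep <- 400
  final <- numeric(nrep)
  rules <- list(internal_reaction("A", "B", k))
  for (r in seq_len(nrep)) {
    v <- test_vesicle(counts = c(A = 40))
    for (i in 1:100) v <- internal_reaction_sweep(v, rules, dt)  # 10 s
    final[r] <- unname(v$counts[["A"]])
  }
  expected <- 40 * exp(-k * 10)
  se <- sd(final) / sqrt(nrep)
  expect_lt(abs(mean(final) - expected), 3 * se + 1e-9)
  # zero-rate: counts unchanged
  v <- test_vesicle(counts = c(A = 40))
  v2 <- internal_reaction_sweep(v, list(internal_reaction("A", "B", 0)), dt)
  expect_equal(v2$counts, v$counts)
})

test_that("internal A+B->C matches a Gillespie oracle (chi-square)", {
  set.seed(10)
  k <- 5e8                       # 1/(M s)
  t_end <- 4
  v0 <- c(A = 12, B = 9, C = 0)
  r_ves <- 0.4
  V_l <- 4 / 3 * pi * r_ves^3 * 1e-15
  kc <- k / (6.02214076e23 * V_l)      # per-pair propensity, 1/s
  # SSA oracle
  ssa_final <- function() {
    a <- 12L; b <- 9L; t <- 0
    repeat {
      prop <- kc * a * b
      if (prop <= 0) return(a)
      t <- t + rexp(1, prop)
      if (t > t_end) return(a)
      a <- a - 1L; b <- b - 1L
    }
  }
  nrep <- 300
  ssa <- vapply(seq_len(nrep), function(i) ssa_final(), 0L)
  rules <- list(internal_reaction(c("A", "B"), "C", k))
  sim <- vapply(seq_len(nrep), function(i) {
    v <- test_vesicle(radius = r_ves, counts = v0)
    for (s in seq_len(t_end / 0.05))
      v <- suppressWarnings(internal_reaction_sweep(v, rules, 0.05))
    unname(v$counts[["A"]])
  }, 0)
  # compare end-state distributions
  lev <- 3:12
  o <- table(factor(pmax(sim, 3), levels = lev))
  e <- table(factor(pmax(ssa, 3), levels = lev))
  keep <- (o + e) > 0
  chi <- suppressWarnings(chisq.test(rbind(o[keep], e[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("budding never initiates without cargo or without coat monomers", {
  kcc <- matrix(5e6, 1, 1, dimnames = list("coatA", "cargo1"))
  tb <- interaction_tables(k_coat_cargo = kcc, shell_size = 5, k_poly = 1)
  sp <- list(coatA = species_def("coatA", "coat", 0.02),
             cargo1 = species_def("cargo1", "cargo_membrane", 0.005))
  set.seed(11)
  v_nocargo <- test_vesicle(counts = c(coatA = 50, cargo1 = 0))
  v_nocoat <- test_vesicle(counts = c(coatA = 0, cargo1 = 50))
  for (i in 1:200) {
    v_nocargo <- initiate_budding(v_nocargo, sp, tb, 0.1)
    v_nocoat <- initiate_budding(v_nocoat, sp, tb, 0.1)
  }
  expect_null(v_nocargo$budding)
  expect_null(v_nocoat$budding)
})

test_that("initiation rate doubles with cargo count (dimer linearity)", {
  kcc <- matrix(2e4, 1, 1, dimnames = list("coatA", "cargo1"))
  tb <- interaction_tables(k_coat_cargo = kcc, shell_size = 5, k_poly = 1)
  sp <- list(coatA = species_def("coatA", "coat", 0.02),
             cargo1 = species_def("cargo1", "cargo_membrane", 0.005))
  time_to_start <- function(ncargo, seeds) {
    vapply(seeds, function(sd) {
      set.seed(sd)
      v <- test_vesicle(counts = c(coatA = 40, cargo1 = ncargo))
      t <- 0
      while (is.null(v$budding) && t < 2000) {
        v <- initiate_budding(v, sp, tb, 0.25); t <- t + 0.25
      }
      t
    }, 0)
  }
  t1 <- time_to_start(25, 1:160)
  t2 <- time_to_start(50, 201:360)
  ratio <- mean(t1) / mean(t2)
  se <- ratio * sqrt((sd(t1) / mean(t1))^2 / 160 + (sd(t2) / mean(t2))^2 / 160)
  expect_lt(abs(ratio - 2), 3.5 * se)
})

test_that("polymerization: shell completes, depletion stalls, timing matches a pure-death oracle", {
  sp <- list()
  set.seed(12)
  # shell_size 1 completes on the first firing
  tb1 <- interaction_tables(shell_size = 1, k_poly = 50)
  v <- test_vesicle(counts = c(coatA = 30))
  v$budding <- list(coat = "coatA", n_pol = 0L, t_bud = 0,
                    site_dir = c(1, 0, 0))
  v <- polymerize_coat_step(v, tb1, 0.1)
  expect_true(v$budding$complete)
  # k_poly = 0 never completes
  tb0 <- interaction_tables(shell_size = 2, k_poly = 0)
  v <- test_vesicle(counts = c(coatA = 30))
  v$budding <- list(coat = "coatA", n_pol = 0L, t_bud = 0,
                    site_dir = c(1, 0, 0))
  for (i in 1:100) v <- polymerize_coat_step(v, tb0, 0.1)
  expect_false(isTRUE(v$budding$complete))
  # no monomers: stalls
  v <- test_vesicle(counts = c(coatA = 0))
  v$budding <- list(coat = "coatA", n_pol = 0L, t_bud = 0,
                    site_dir = c(1, 0, 0))
  for (i in 1:50) v <- polymerize_coat_step(v, interaction_tables(
    shell_size = 5, k_poly = 1), 0.1)
  expect_equal(v$budding$n_pol, 0L)
  # mean t_bud ~ sum over the depletion sequence 1/(k n_m) (no resupply):
  # starting from n0 monomers, shell m: rate k * (n0 - m)
  k_poly <- 0.5; shell <- 6; n0 <- 12
  tb <- interaction_tables(shell_size = shell, k_poly = k_poly)
  tbud <- vapply(1:300, function(i) {
    v <- test_vesicle(counts = c(coatA = n0))
    v$budding <- list(coat = "coatA", n_pol = 0L, t_bud = 0,
                      site_dir = c(1, 0, 0))
    while (!isTRUE(v$budding$complete)) v <- polymerize_coat_step(v, tb, 0.02)
    v$budding$t_bud
  }, 0)
  oracle <- sum(1 / (k_poly * (n0 - (0:(shell - 1)))))
  se <- sd(tbud) / sqrt(length(tbud))
  expect_lt(abs(mean(tbud) - oracle), 3 * se + 0.05)
})

test_that("class saturation scales by largest remainder", {
  expect_equal(unname(apply_class_saturation(c(a = 10, b = 10), 20)),
               c(10, 10))                        # sum == L unchanged
  expect_equal(unname(apply_class_saturation(c(a = 30, b = 10), 20)),
               c(15, 5))                         # f = 0.5 exact
  expect_equal(unname(apply_class_saturation(c(a = 100), 7)), 7)
  out <- apply_class_saturation(c(a = 7, b = 5, c = 3), 10)
  expect_equal(sum(out), 10)
  expect_true(all(out <= c(7, 5, 3)))
  # property: never exceeds the limit, over random cases
  set.seed(13)
  for (i in 1:200) {
    x <- rpois(sample(1:5, 1), 20)
    L <- sample(0:30, 1)
    out <- apply_class_saturation(stats::setNames(x, paste0("s", seq_along(x))), L)
    expect_lte(sum(out), max(L, sum(round(x))))
    if (sum(x) > L) expect_equal(sum(out), floor(L))
  }
})

test_that("loading matches the binomial oracle and scales with donor cargo", {
  sp <- list(coatA = species_def("coatA", "coat", 0.02),
             cargo1 = species_def("cargo1", "cargo_lumen", 0.005))
  kcc <- matrix(1e5, 1, 1, dimnames = list("coatA", "cargo1"))
  tb <- interaction_tables(k_coat_cargo = kcc, shell_size = 10, k_poly = 1,
                           class_limits = list(cargo = 1e6, snare = 10,
                                               motor = 10))
  draw <- function(n_don, t_bud, seeds) {
    vapply(seeds, function(sd) {
      set.seed(sd)
      v <- test_vesicle(radius = 0.4, counts = c(cargo1 = n_don))
      v$budding <- list(coat = "coatA", n_pol = 10L, t_bud = t_bud,
                        site_dir = c(1, 0, 0), complete = TRUE)
      ld <- load_on_separation(v, sp, tb)
      sum(ld$transfer)
    }, 0)
  }
  n_don <- 200; t_bud <- 4
  V_l <- 4 / 3 * pi * 0.4^3 * 1e-15
  p <- 1 - exp(-1e5 * (10 / 2) * t_bud / (6.02214076e23 * V_l))
  m <- draw(n_don, t_bud, 1:300)
  se <- sqrt(n_don * p * (1 - p) / 300)
  expect_lt(abs(mean(m) - n_don * p), 3 * se)
  # doubling donor cargo doubles the mean transfer (sub-saturation)
  m2 <- draw(2 * n_don, t_bud, 301:600)
  expect_equal(mean(m2) / mean(m), 2, tolerance = 0.15)
  # zero rates -> empty vesicle
  tb0 <- interaction_tables(k_coat_cargo = kcc * 0, shell_size = 10)
  v <- test_vesicle(counts = c(cargo1 = 100))
  v$budding <- list(coat = "coatA", n_pol = 10L, t_bud = 5,
                    site_dir = c(1, 0, 0), complete = TRUE)
  expect_equal(sum(load_on_separation(v, sp, tb0)$transfer), 0)
})

test_that("depolymerization follows the lagged linear ramp", {
  tb <- interaction_tables(shell_size = 20)
  prm <- sim_params(depol_time = 2, depol_lag = 1)
  v <- test_vesicle()
  v$n_pol <- 20L; v$pol_species <- "coatA"; v$depol_clock <- 0
  # before the lag: unchanged
  r <- depolymerize_coat(v, tb, prm, 0.5)
  expect_equal(r$vesicle$n_pol, 20L)
  expect_equal(r$released, 0L)
  # at lag + depol_time: exactly zero, everything released
  v2 <- r$vesicle
  total_released <- r$released
  repeat {
    r <- depolymerize_coat(v2, tb, prm, 0.25)
    v2 <- r$vesicle; total_released <- total_released + r$released
    if (v2$n_pol == 0L) break
  }
  expect_equal(total_released, 20L)
  expect_lte(v2$depol_clock, 1 + 2 + 0.25 + 1e-9)
})

test_that("endocytic clustering: no coats -> no clusters; capture radius grows; bookkeeping exact", {
  cell <- build_cell(2.5)
  sp <- list(coatC = species_def("coatC", "coat", 0.02),
             cargoR = species_def("cargoR", "cargo_membrane", 0.005),
             snareP = species_def("snareP", "snare", 0.005))
  kcc <- matrix(5e7, 1, 1, dimnames = list("coatC", "cargoR"))
  tb <- interaction_tables(k_coat_cargo = kcc, shell_size = 3, k_poly = 1)
  set.seed(14)
  # no membrane coats: nothing can nucleate
  mem0 <- list(pos = vtsim:::.runit(30) * 2.5,
               species = rep("cargoR", 30), klass = rep("cargo_membrane", 30),
               alive = rep(TRUE, 30))
  r0 <- endocytosis_step(mem0, list(), sp, tb, cell, 0.1)
  expect_length(r0$clusters, 0)
  expect_length(r0$completed, 0)

  # dense coat+cargo patch: clusters form and complete; membrane cargo in
  # the completed vesicle equals cargo captured (no loss)
  n <- 60
  base <- vtsim:::.unit(c(1, 0, 0))
  jit <- vtsim:::.runit(n) * 0.15
  pos <- sweep(jit, 2, base * 2.5, "+")
  pos <- pos / sqrt(rowSums(pos^2)) * 2.5
  mem <- list(pos = pos,
              species = rep(c("coatC", "cargoR"), n / 2),
              klass = rep(c("coat", "cargo_membrane"), n / 2),
              alive = rep(TRUE, n))
  clusters <- list()
  completed <- list()
  for (i in 1:50) {
    r <- endocytosis_step(mem, clusters, sp, tb, cell, 0.1)
    mem <- r$mem; clusters <- r$clusters
    completed <- c(completed, r$completed)
    if (length(completed)) break
  }
  expect_gt(length(completed), 0)
  cl <- completed[[1]]
  n_captured <- sum(unlist(cl$counts))
  n_gone <- sum(!mem$alive) +
    sum(unlist(lapply(clusters, function(x) sum(unlist(x$counts)))))
  expect_equal(sum(unlist(lapply(c(clusters, completed), function(x)
    sum(unlist(x$counts))))), sum(!mem$alive))
})
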