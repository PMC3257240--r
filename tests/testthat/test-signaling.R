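test_that("zero receptors give an all-zero receptor series", {
  cfg <- preset_signaling(t_end = 6, t_ligand = 1)
  cfg$species$R$initial_counts$PM <- NULL
  cfg$scenario$compartments[[1]]$counts$R <- NULL
  run <- suppressWarnings(run_simulation(cfg, seed = 2, record_every = 1))
  rep <- receptor_flux_report(run)
  expect_true(all(rep$series$R_PM == 0))
  expect_true(all(rep$series$RL_PM == 0))
  expect_true(all(rep$series$RL_endosome == 0))
})

test_that("no ligand means no RL; receptors are conserved", {
  cfg <- preset_signaling(t_end = 8, t_ligand = 1e9)   # ligand never added
  run <- suppressWarnings(run_simulation(cfg, seed = 3, record_every = 1))
  rep <- receptor_flux_report(run)
  expect_true(all(rep$series$RL_PM == 0))
  tot <- species_totals(run$state)
  expect_equal(unname(tot["R"] + tot["RL"]), 150 + 30)  # PM + endosome
})

test_that("without endocytic coats RL(PM) is monotone non-decreasing", {
  cfg <- preset_signaling(t_end = 12, t_ligand = 2)
  # disable the endocytic route entirely: no coat C anywhere
  cfg$species$coatC$initial_counts <- list()
  run <- suppressWarnings(run_simulation(cfg, seed = 4, record_every = 0.5))
  rep <- receptor_flux_report(run)
  rl <- rep$series$RL_PM
  expect_true(all(diff(rl) >= 0))
  # active receptors never leave the PM (the recycling route may still
  # carry inactive R)
  expect_true(all(rep$series$RL_transit + rep$series$RL_endosome == 0))
})

test_that("closed well-mixed reduction matches the two-state ODE", {
  # transport off, all species co-located: one RL-bearing vesicle whose
  # contact sphere covers the whole cell; activation/deactivation is then a
  # linear two-state system with stationary MAPKp fraction a/(a+d)
  n_rl <- 40
  k_act <- 2e7; k_dephos <- 0.05
  cellR <- 1.0; r_ves <- 0.9
  cfg <- preset_signaling(t_end = 120, t_ligand = 1e9,
                          k_MAPK_act_vesicle = k_act,
                          k_dephos_cyt = k_dephos, k_dephos_nuc = k_dephos,
                          k_nuc_bind = 0)
  cfg$scenario$cell <- list(cell_radius = cellR, nucleus_radius = 0)
  cfg$scenario$plasma_membrane <- NULL
  cfg$scenario$cytoskeleton_style <- "none"
  cfg$scenario$compartments <- list(
    list(identity = "inert", position = c(0, 0, 0), radius = r_ves,
         counts = list(RL = n_rl)))
  for (s in names(cfg$species)) cfg$species[[s]]$initial_counts <- list()
  cfg$species$MAPK$initial_counts <- list(cytosol = 300)
  run <- suppressWarnings(run_simulation(cfg, seed = 5, record_every = 1))
  ts <- run$timeseries
  mapkp <- ts[["MAPKp@cytosol"]]
  # ODE oracle: per-MAPK activation rate a = P/dt with the overlap rule
  dt_r <- 0.1
  cr <- suppressWarnings(
    contact_rule(0.004, r_ves, k_act * n_rl, dt_r, overlap_allowed = TRUE))
  # molecules can sit anywhere in the cell; the fraction of the cell inside
  # the contact sphere is the geometric eligibility factor
  f_in <- min(1, (cr$critical_distance / cellR)^3)
  a <- -log(1 - cr$probability) / dt_r * f_in
  d <- k_dephos
  stat_frac <- a / (a + d)
  tail_frac <- mean(mapkp[ts$time > 60]) / 300
  expect_equal(tail_frac, stat_frac, tolerance = 0.05)
})

test_that("endosomal deactivation uses the enzymatic propensity", {
  # direct unit check of the r2 channel through one sweep
  cfg <- preset_signaling(t_end = 0)
  run <- run_simulation(cfg, seed = 1)
  st <- run$state
  endo <- st$ves[[1]]
  expect_match(endo$identity, "endosome")
  endo$counts[["RL"]] <- 200
  st$ves[[1]] <- endo
  sg <- st$signaling
  set.seed(42)
  nrep <- 300
  fired <- vapply(seq_len(nrep), function(i) {
    st$ves[[1]]$counts[["RL"]] <- 200
    signaling_sweep(st, 0.1)
    200 - st$ves[[1]]$counts[["RL"]]
  }, 0)
  a <- sg$k_cat * sg$enzyme_count * 200 / (sg$K_M + 200)
  expected <- 200 * min(1, a * 0.1 / 200)
  se <- sd(fired) / sqrt(nrep)
  expect_lt(abs(mean(fired) - expected), 3 * se + 0.05)
})
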