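# Scenario presets. All numeric rate values are provisional defaults chosen
# to give a functional machinery at desk scale (the source supplement with
# the original parameter file is not available); every one of them can be
# overridden through the config document.

.preset_params <- function(t_end, dt = 0.02, seed = 1L, ...) {
  sim_params(dt = dt, reaction_stride = 5L, t_end = t_end, seed = seed, ...)
}

#' Two-compartment transport scenario
#'
#' Two caged compartments exchange vesicles through an interchangeable
#' cytoskeleton architecture. Module 1 (coat A / cargo 1 / SNARE X-Y /
#' motor 1) ships vesicles from compartment 1 to 2; module 2 (coat B /
#' cargo 2 / SNARE U-V / motor 2) runs the reverse route. Each compartment
#' additionally holds the opposite-route SNAREs at lower enrichment,
#' emulating the steady-state mixing created by recycling traffic; these
#' stray SNAREs are what makes backward fusion possible at all.
#'
#' @param style cytoskeleton architecture: `"none"` (pure diffusion),
#'   `"random"`, `"direct"`, `"linear"` or `"dipole"`
#' @param D_set vesicle mobility: `"fast"` (reference D = 1 um^2/s for a
#'   50-nm-radius vesicle, crowded-cytoplasm scale) or `"slow"` (0.1 um^2/s)
#' @param t_end simulated time, s
#' @param seed RNG seed
#' @param depol_time coat depolymerization duration, s
#' @param n_filaments filament count for the architectures that use one
#' @param dt time step, s
#' @return a `vtsim_config`
#' @export
preset_two_compartment <- function(style = c("none", "random", "direct",
                                             "linear", "dipole"),
                                   D_set = c("fast", "slow"), t_end = 150,
                                   seed = 1L, depol_time = 2,
                                   n_filaments = 30L, dt = 0.02) {
  style <- match.arg(style)
  D_set <- match.arg(D_set)
  ref_D <- if (D_set == "fast") 0.5 else 0.1
  mk <- function(nm, kl, r, ic = list(), ...) species_def(nm, kl, r, initial_counts = ic, ...)
  species <- list(
    mk("coatA", "coat", 0.02, list(cytosol = 60)),
    mk("coatB", "coat", 0.02, list(cytosol = 60)),
    mk("motor1", "motor", 0.01, list(cytosol = 30), speed = 1.0, direction = 1),
    mk("motor2", "motor", 0.01, list(cytosol = 30), speed = 1.0, direction = -1),
    mk("snareX", "snare", 0.005), mk("snareY", "snare", 0.005),
    mk("snareU", "snare", 0.005), mk("snareV", "snare", 0.005),
    mk("cargo1", "cargo_membrane", 0.005), mk("cargo2", "cargo_membrane", 0.005))
  names(species) <- vapply(species, `[[`, "", "name")

  snares <- c("snareX", "snareY", "snareU", "snareV")
  ss <- matrix(0, 4, 4, dimnames = list(snares, snares))
  ss["snareX", "snareY"] <- ss["snareY", "snareX"] <- 1
  ss["snareU", "snareV"] <- ss["snareV", "snareU"] <- 1

  kcc <- matrix(0, 2, 2, dimnames = list(c("coatA", "coatB"),
                                         c("cargo1", "cargo2")))
  kcc["coatA", "cargo1"] <- 5e3; kcc["coatB", "cargo2"] <- 5e3
  kcs <- matrix(0, 2, 4, dimnames = list(c("coatA", "coatB"), snares))
  kcs["coatA", "snareX"] <- 1e4; kcs["coatA", "snareV"] <- 2e3  # V: recycling
  kcs["coatB", "snareV"] <- 1e4; kcs["coatB", "snareX"] <- 2e3
  kcm <- matrix(0, 2, 2, dimnames = list(c("coatA", "coatB"),
                                         c("motor1", "motor2")))
  kcm["coatA", "motor1"] <- 2e4; kcm["coatB", "motor2"] <- 2e4
  catch <- matrix(0, 2, 2, dimnames = list(c("cargo1", "cargo2"),
                                           c("coatA", "coatB")))
  catch["cargo1", "coatA"] <- 1e7; catch["cargo2", "coatB"] <- 1e7
  mcatch <- matrix(0, 2, 2, dimnames = list(c("cargo1", "cargo2"),
                                            c("motor1", "motor2")))
  mcatch["cargo1", "motor1"] <- 2e5; mcatch["cargo2", "motor2"] <- 2e5

  tables <- interaction_tables(
    k_coat_cargo = kcc, k_coat_snare = kcs, k_coat_motor = kcm,
    snare_strength = ss, catcher_rate = catch, motor_catcher_rate = mcatch,
    coat_on_off = list(coatA = list(k_off = 0.08),
                       coatB = list(k_off = 0.08)),
    motor_on_off = list(motor1 = list(k_off = 0.005),
                        motor2 = list(k_off = 0.005)),
    k_poly = 0.25, k_fus_pair = 7e8, tau_pair = 2,
    class_limits = list(cargo = 20, snare = 15, motor = 5),
    shell_size = 30, k_fil_bind = 5e7)

  # SNARE pools follow the mixed-enrichment regime of the underlying
  # two-compartment model: every compartment holds all SNARE types, enriched
  # ~2.5:1 for its own route, so the donor stays a competent fusion partner
  # (backward fusion is possible and must be suppressed by the transport
  # architecture, not by the chemistry). Compartment separation is chosen so
  # that the motorized travel time exceeds the coat-shielding time
  # (depol_lag + depol_time), the timescale comparison the transport
  # architectures are meant to exploit.
  comp1 <- list(identity = "compartment1", position = c(-1.4, 0, 0), radius = 0.4,
                counts = list(cargo1 = 400, snareX = 250, snareU = 150,
                              snareY = 100, snareV = 100, motor1 = 50,
                              coatA = 60))
  comp2 <- list(identity = "compartment2", position = c(1.4, 0, 0), radius = 0.4,
                counts = list(cargo2 = 400, snareV = 250, snareY = 150,
                              snareU = 100, snareX = 100, motor2 = 50,
                              coatB = 60))
  cyto_style <- if (style == "none") "none" else style
  scenario <- list(cell = list(cell_radius = 2.5, nucleus_radius = 0),
                   cytoskeleton_style = cyto_style,
                   cytoskeleton_params = list(n = n_filaments),
                   compartments = list(comp1, comp2),
                   vesicle_radius = 0.05)
  structure(list(species = species, tables = tables, scenario = scenario,
                 params = .preset_params(t_end, dt = dt, seed = seed,
                                         depol_time = depol_time,
                                         ref_D = ref_D)),
            class = "vtsim_config")
}

#' Endo/exocytosis scenario: plasma membrane and central endosome
#'
#' The plasma membrane carries explicit diffusing molecules (clathrin-type
#' coat C, receptor cargo R, SNAREs); endocytic vesicles assemble by coat
#' clustering, launch with the actin boost, and travel (optionally along a
#' radial cytoskeleton with inward motors) to the endosome. A recycling
#' route (coat D, outward motors) returns material to the membrane.
#'
#' @param style `"radial"`, `"polarized"` or `"none"`
#' @param t_end simulated time, s
#' @param seed RNG seed
#' @param boost_speed actin boost speed, um/s
#' @param depol_time coat depolymerization duration, s
#' @param receptors receptor copy number on the PM
#' @param signaling optional [signaling_config()] list to enable the
#'   receptor/MAPK layer (renames the receptor species to `R`)
#' @param dt time step, s
#' @return a `vtsim_config`
#' @export
preset_endo_exo <- function(style = c("radial", "polarized", "none"),
                            t_end = 100, seed = 1L, boost_speed = 0.3,
                            depol_time = 5, receptors = 150,
                            signaling = NULL, dt = 0.02) {
  style <- match.arg(style)
  rec_name <- if (is.null(signaling)) "cargoR" else "R"
  mk <- function(nm, kl, r, ic = list(), ...) species_def(nm, kl, r, initial_counts = ic, ...)
  species <- list(
    mk("coatC", "coat", 0.02, list(cytosol = 40, PM = 60)),
    mk("coatD", "coat", 0.02, list(cytosol = 50)),
    mk("motorIn", "motor", 0.01, list(PM = 50), speed = 1.0, direction = -1),
    mk("motorOut", "motor", 0.01, list(cytosol = 25), speed = 1.0, direction = 1),
    mk("snareP", "snare", 0.005, list(PM = 120)),
    mk("snareQ", "snare", 0.005, list(PM = 40)),
    mk(rec_name, "cargo_membrane", 0.005, list(PM = receptors)),
    mk("cargoE", "cargo_membrane", 0.005))
  if (!is.null(signaling)) {
    species <- c(species, list(
      mk("RL", "cargo_membrane", 0.005),
      species_def("MAPK", "cytosolic", 0.004,
                  diffusion_coeff = signaling$D_signal %||% 1.0,
                  initial_counts = list(cytosol = 250)),
      species_def("MAPKp", "cytosolic", 0.004,
                  diffusion_coeff = signaling$D_signal %||% 1.0)))
  }
  names(species) <- vapply(species, `[[`, "", "name")
  snares <- c("snareP", "snareQ")
  ss <- matrix(0, 2, 2, dimnames = list(snares, snares))
  ss["snareP", "snareQ"] <- ss["snareQ", "snareP"] <- 1

  cargo_cols <- unique(c(rec_name, "cargoE", if (!is.null(signaling)) "RL"))
  kcc <- matrix(0, 2, length(cargo_cols),
                dimnames = list(c("coatC", "coatD"), cargo_cols))
  # endocytic coat C selects the (active) receptor; recycling coat D ships
  # receptors back out of the endosome
  kcc["coatC", if (is.null(signaling)) rec_name else "RL"] <- 8e3
  kcc["coatD", rec_name] <- 5e3
  kcc["coatD", "cargoE"] <- 5e3
  kcs <- matrix(0, 2, 2, dimnames = list(c("coatC", "coatD"), snares))
  kcs["coatC", "snareP"] <- 1e4; kcs["coatC", "snareQ"] <- 2e3
  kcs["coatD", "snareQ"] <- 1e4; kcs["coatD", "snareP"] <- 2e3
  kcm <- matrix(0, 2, 2, dimnames = list(c("coatC", "coatD"),
                                         c("motorIn", "motorOut")))
  kcm["coatC", "motorIn"] <- 3e4; kcm["coatD", "motorOut"] <- 3e4
  catcher_rows <- unique(c(rec_name, "cargoE", if (!is.null(signaling)) "RL"))
  catch <- matrix(0, length(catcher_rows), 2,
                  dimnames = list(catcher_rows, c("coatC", "coatD")))
  catch[if (is.null(signaling)) rec_name else "RL", "coatC"] <- 2e8
  catch["cargoE", "coatD"] <- 1e7
  mcatch <- matrix(0, length(catcher_rows), 2,
                   dimnames = list(catcher_rows, c("motorIn", "motorOut")))
  mcatch["cargoE", "motorOut"] <- 2e5

  tables <- interaction_tables(
    k_coat_cargo = kcc, k_coat_snare = kcs, k_coat_motor = kcm,
    snare_strength = ss, catcher_rate = catch, motor_catcher_rate = mcatch,
    coat_on_off = list(coatC = list(k_off = 0.1),
                       coatD = list(k_off = 0.08)),
    motor_on_off = list(motorIn = list(k_off = 0.005),
                        motorOut = list(k_off = 0.005)),
    k_poly = 0.25, k_fus_pair = 7e8, tau_pair = 2,
    class_limits = list(cargo = 20, snare = 15, motor = 5),
    shell_size = 12, k_fil_bind = 5e7)

  nucleus <- if (is.null(signaling)) list(nucleus_radius = 0) else
    list(nucleus_radius = 0.8, nucleus_center = c(1.0, 0, 0))
  endo_pos <- if (is.null(signaling)) c(0, 0, 0) else c(-0.6, 0, 0)
  # receptors sit mostly at the PM before ligand addition; the endosome
  # holds a small standing pool
  endosome <- list(identity = "endosome", position = endo_pos, radius = 0.5,
                   counts = stats::setNames(
                     list(200, 250, 50, 40, 60, 30),
                     c("cargoE", "snareQ", "snareP", "motorOut", "coatD",
                       rec_name)))
  scenario <- list(cell = c(list(cell_radius = 2.5), nucleus),
                   cytoskeleton_style = if (style == "none") "none" else style,
                   cytoskeleton_params = list(n = 40L, pole = c(-1, 0, 0),
                                              bias = 3),
                   compartments = list(endosome),
                   plasma_membrane = list(enabled = TRUE, D_mem = 0.01,
                                          a0 = 2e-3),
                   vesicle_radius = 0.05,
                   signaling = signaling)
  structure(list(species = species, tables = tables, scenario = scenario,
                 params = .preset_params(t_end, dt = dt, seed = seed,
                                         boost_speed = boost_speed,
                                         depol_time = depol_time)),
            class = "vtsim_config")
}

#' Receptor-mediated endocytosis + MAPK signaling scenario
#'
#' [preset_endo_exo()] with the signaling layer enabled: the cargo is the
#' Ste2p-like receptor `R`, activated to `RL` by an implicit ligand pulse,
#' endocytosed on demand, deactivated enzymatically in the endosome and
#' recycled; cytosolic MAPK is activated by RL and shuttles at the nucleus.
#'
#' @param polarized use the polarized cytoskeleton (cell-polarization study)
#' @param t_end simulated time, s
#' @param seed RNG seed
#' @param t_ligand ligand addition time, s
#' @param ... overrides passed to [signaling_config()]
#' @return a `vtsim_config`
#' @export
preset_signaling <- function(polarized = FALSE, t_end = 80, seed = 1L,
                             t_ligand = 5, ...) {
  sg <- signaling_config(t_ligand = t_ligand, ...)
  preset_endo_exo(style = if (polarized) "polarized" else "radial",
                  t_end = t_end, seed = seed, signaling = sg)
}

#' Species totals across every location (conservation audit)
#'
#' Sums each species over the cytosolic pool, membrane agents, endocytic
#' clusters, vesicle/compartment counts (including polymerized coat shells
#' and active budding processes) and the plasma-membrane pseudo-compartment.
#'
#' @param state the `state` environment of a `vtsim_run`
#' @return named numeric vector of total copy numbers per species
#' @export
species_totals <- function(state) {
  tot <- stats::setNames(numeric(length(state$species)), names(state$species))
  m <- state$mol
  if (length(m$species)) {
    tb <- table(m$species[m$alive])
    tot[names(tb)] <- tot[names(tb)] + as.numeric(tb)
  }
  if (length(state$mem$species)) {
    tb <- table(state$mem$species[state$mem$alive])
    ok <- intersect(names(tb), names(tot))
    tot[ok] <- tot[ok] + as.numeric(tb[ok])
  }
  for (cl in state$clusters) for (sp in names(cl$counts))
    tot[sp] <- tot[sp] + unname(cl$counts[[sp]])
  for (v in state$ves) {
    for (sp in names(v$counts)) tot[sp] <- tot[sp] + unname(v$counts[[sp]])
    if (v$n_pol > 0 && !is.na(v$pol_species))
      tot[v$pol_species] <- tot[v$pol_species] + v$n_pol
    if (!is.null(v$budding))
      tot[v$budding$coat] <- tot[v$budding$coat] + v$budding$n_pol
  }
  if (!is.null(state$pm) && length(state$pm$counts))
    for (sp in names(state$pm$counts))
      tot[sp] <- tot[sp] + unname(state$pm$counts[[sp]])
  tot
}

#' Total vesicle volume and surface in the system
#'
#' @param state the `state` environment of a `vtsim_run`
#' @return named vector `c(volume =, surface =)` summed over all vesicle
#'   agents (um^3, um^2)
#' @export
vesicle_totals <- function(state) {
  c(volume = sum(vapply(state$ves, `[[`, 0, "volume")),
    surface = sum(vapply(state$ves, `[[`, 0, "surface")))
}

#' Write run outputs to a directory
#'
#' Event log (tab-delimited), time series (tab-delimited), filament polyline
#' table and the resolved configuration (JSON) for provenance.
#'
#' @param run a `vtsim_run`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(log = file.path(dir, "events.tsv"),
             ts = file.path(dir, "timeseries.tsv"),
             fil = file.path(dir, "filaments.tsv"),
             cfg = file.path(dir, "resolved_config.json"),
             runlog = file.path(dir, "run.log"))
  utils::write.table(run$log, paths["log"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(run$timeseries, paths["ts"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(filament_table(run$state$filaments), paths["fil"],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(serialize_config(run$config), paths["cfg"])
  writeLines(c(paste("vtsim", as.character(utils::packageVersion("vtsim"))),
               paste("R", paste(R.version$major, R.version$minor, sep = ".")),
               paste("seed", run$seed),
               paste("t_end", run$config$params$t_end)), paths["runlog"])
  invisible(paths)
}

#' Command-line entry point
#'
#' `Rscript -e 'vtsim::vtsim_cli()' <preset|config.json> [--seed N]
#' [--t-end S] [--dt S] [--out-dir DIR]`. Presets: `two_compartment_<style>`
#' (style: none/random/direct/linear/dipole), `endo_exo`, `signaling`,
#' `signaling_polarized`.
#'
#' @param args command-line arguments (default: `commandArgs(TRUE)`)
#' @return exit status 0 invisibly on clean completion
#' @export
vtsim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: vtsim_cli <preset|config.json> [options]")
  target <- args[[1]]
  getopt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[[i + 1L]] else default
  }
  seed <- as.integer(getopt("--seed", 1L))
  t_end <- as.numeric(getopt("--t-end", NA))
  dt <- as.numeric(getopt("--dt", NA))
  out_dir <- getopt("--out-dir", "vtsim_out")
  cfg <- if (file.exists(target)) {
    load_config(target)
  } else if (grepl("^two_compartment_", target)) {
    preset_two_compartment(sub("^two_compartment_", "", target), seed = seed)
  } else if (target == "endo_exo") {
    preset_endo_exo(seed = seed)
  } else if (target == "signaling") {
    preset_signaling(seed = seed)
  } else if (target == "signaling_polarized") {
    preset_signaling(polarized = TRUE, seed = seed)
  } else stop("unknown preset or missing config file: ", target)
  if (!is.na(t_end)) cfg$params$t_end <- t_end
  if (!is.na(dt)) cfg$params$dt <- dt
  run <- run_simulation(cfg, seed = seed)
  write_run_outputs(run, out_dir)
  print(run)
  invisible(0L)
}
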