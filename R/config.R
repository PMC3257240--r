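#' Define a molecular species
#'
#' A species is the template every molecule agent of that kind inherits from:
#' a class tag that decides which machinery role it can play, a hydrodynamic
#' radius, and a diffusion coefficient (either explicit or derived from the
#' Stokes-Einstein relation relative to the configured reference object).
#'
#' @param name unique species identifier
#' @param klass one of `"coat"`, `"snare"`, `"motor"`, `"cargo_membrane"`,
#'   `"cargo_lumen"`, `"cytosolic"`
#' @param radius hydrodynamic radius in um (> 0)
#' @param diffusion_coeff diffusion coefficient in um^2/s, or the string
#'   `"stokes_einstein"` to scale from the reference object at run time
#' @param initial_counts named list/vector: compartment id (or `"cytosol"`)
#'   -> nonnegative integer count
#' @param speed motor walking speed in um/s (motor class only)
#' @param direction +1 (toward filament plus end) or -1 (motor class only)
#' @return an object of class `vtsim_species`
#' @export
species_def <- function(name, klass, radius, diffusion_coeff = "stokes_einstein",
                        initial_counts = list(), speed = NULL, direction = NULL) {
  klass <- match.arg(klass, c("coat", "snare", "motor", "cargo_membrane",
                              "cargo_lumen", "cytosolic"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("species `name` must be a non-empty string")
  if (!is.numeric(radius) || radius <= 0)
    stop("species `", name, "`: radius must be > 0")
  if (is.numeric(diffusion_coeff)) {
    if (diffusion_coeff < 0) stop("species `", name, "`: diffusion_coeff must be >= 0")
  } else if (!identical(diffusion_coeff, "stokes_einstein")) {
    stop("species `", name, "`: diffusion_coeff must be numeric or \"stokes_einstein\"")
  }
  ic <- unlist(initial_counts)
  if (length(ic) && (any(ic < 0) || any(ic != floor(ic))))
    stop("species `", name, "`: initial_counts must be nonnegative integers")
  if (klass == "motor") {
    speed <- speed %||% 1.0
    direction <- direction %||% 1
    if (!direction %in% c(-1, 1)) stop("motor direction must be +1 or -1")
    if (speed < 0) stop("motor speed must be >= 0")
  }
  structure(list(name = name, klass = klass, radius = radius,
                 diffusion_coeff = diffusion_coeff,
                 initial_counts = as.list(initial_counts),
                 speed = speed, direction = direction),
            class = "vtsim_species")
}

#' Assemble the interaction-rate tables of the vesicle machinery
#'
#' All pairwise rate constants are matrices over species names: which coat
#' selects which cargo/SNARE/motor, how strongly each SNARE type pairs with
#' each other type, and how fast compartment-resident catcher molecules
#' recruit cytosolic coats and motors. Rates are in 1/(M s) unless noted.
#'
#' @param k_coat_cargo,k_coat_snare,k_coat_motor named matrices
#'   (rows = coat species) used both for budding initiation (coat-cargo
#'   dimer) and for loading during budding
#' @param snare_strength symmetric named matrix of dimensionless pairing
#'   weights s_uv >= 0
#' @param catcher_rate named matrix (rows = catcher cargo species, cols =
#'   coat species): per-catcher recruitment rate; the compartment-level rate
#'   is `k_catch * n_catcher`
#' @param motor_catcher_rate analogous matrix for motors
#' @param coat_on_off,motor_on_off named list per species:
#'   `list(k_on=..., k_off=...)`; `k_off` in 1/s
#' @param k_poly coat polymerization rate, 1/s per bound monomer
#' @param k_fus_pair fusion rate constant per effective SNARE pair, 1/(M s)
#' @param tau_pair fusion time per pair, s (fusion duration = tau_pair/n_pairs)
#' @param class_limits named list: class -> maximum molecules loaded per
#'   vesicle (`cargo`, `snare`, `motor`)
#' @param shell_size number of coat monomers in a complete shell (>= 1)
#' @param k_fil_bind filament capture rate per motor protein, 1/(M s)
#' @param k_clust membrane clustering rate of the endocytic machinery
#'   (nucleation and cluster capture), 1/(M s); realized through the
#'   non-overlap reaction-layer rule on the membrane
#' @return an object of class `vtsim_tables`
#' @export
interaction_tables <- function(k_coat_cargo = NULL, k_coat_snare = NULL,
                               k_coat_motor = NULL, snare_strength = NULL,
                               catcher_rate = NULL, motor_catcher_rate = NULL,
                               coat_on_off = list(), motor_on_off = list(),
                               k_poly = 0.1, k_fus_pair = 0, tau_pair = 1,
                               class_limits = list(cargo = 20, snare = 15, motor = 5),
                               shell_size = 30, k_fil_bind = 0,
                               k_clust = 5e8) {
  chk_mat <- function(m, nm) {
    if (is.null(m)) return(matrix(0, 0, 0))
    m <- as.matrix(m)
    if (any(m < 0)) stop(nm, ": rates must be >= 0")
    m
  }
  k_coat_cargo <- chk_mat(k_coat_cargo, "k_coat_cargo")
  k_coat_snare <- chk_mat(k_coat_snare, "k_coat_snare")
  k_coat_motor <- chk_mat(k_coat_motor, "k_coat_motor")
  catcher_rate <- chk_mat(catcher_rate, "catcher_rate")
  motor_catcher_rate <- chk_mat(motor_catcher_rate, "motor_catcher_rate")
  snare_strength <- chk_mat(snare_strength, "snare_strength")
  if (nrow(snare_strength) > 0 &&
      !isTRUE(all.equal(snare_strength, t(snare_strength), tolerance = 1e-12)))
    stop("snare_strength must be symmetric")
  if (shell_size < 1) stop("shell_size must be >= 1")
  if (any(unlist(class_limits) < 0)) stop("class_limits must be >= 0")
  if (k_poly < 0 || k_fus_pair < 0 || tau_pair <= 0 || k_fil_bind < 0 ||
      k_clust < 0)
    stop("rates must be >= 0 and tau_pair > 0")
  structure(list(k_coat_cargo = k_coat_cargo, k_coat_snare = k_coat_snare,
                 k_coat_motor = k_coat_motor, snare_strength = snare_strength,
                 catcher_rate = catcher_rate,
                 motor_catcher_rate = motor_catcher_rate,
                 coat_on_off = rapply(coat_on_off, as.numeric, how = "replace"),
                 motor_on_off = rapply(motor_on_off, as.numeric, how = "replace"),
                 k_poly = as.numeric(k_poly),
                 k_fus_pair = as.numeric(k_fus_pair),
                 tau_pair = as.numeric(tau_pair),
                 class_limits = lapply(class_limits, as.numeric),
                 shell_size = as.integer(shell_size),
                 k_fil_bind = as.numeric(k_fil_bind),
                 k_clust = as.numeric(k_clust)),
            class = "vtsim_tables")
}

#' Simulation parameters
#'
#' @param dt time step in s (> 0); the Brownian step per axis is
#'   `sqrt(2 D dt)` so `dt` should keep steps small against the geometry
#' @param reaction_stride reaction sweeps run every this many movement steps
#'   with effective time step `reaction_stride * dt`
#' @param t_end simulated duration, s
#' @param seed RNG seed for the single per-run stream
#' @param boost_speed actin-boost speed of fresh endocytic vesicles, um/s
#' @param depol_time duration of linear coat depolymerization, s
#' @param depol_lag delay before depolymerization starts, s
#' @param ref_radius,ref_D Stokes-Einstein reference object (um, um^2/s)
#' @param stall_detach_time a motor-bound vesicle stalled (v_eff == 0) this
#'   long detaches to diffusion, s
#' @return object of class `vtsim_params`
#' @export
sim_params <- function(dt = 0.02, reaction_stride = 5L, t_end = 100, seed = 1L,
                       boost_speed = 0.3, depol_time = 2, depol_lag = 0.5,
                       ref_radius = 0.05, ref_D = 1.0,
                       stall_detach_time = 1) {
  if (dt <= 0) stop("dt must be > 0")
  if (reaction_stride < 1) stop("reaction_stride must be >= 1")
  if (t_end < 0) stop("t_end must be >= 0")
  structure(list(dt = as.numeric(dt),
                 reaction_stride = as.integer(reaction_stride),
                 t_end = as.numeric(t_end), seed = as.integer(seed),
                 boost_speed = as.numeric(boost_speed),
                 depol_time = as.numeric(depol_time),
                 depol_lag = as.numeric(depol_lag),
                 ref_radius = as.numeric(ref_radius),
                 ref_D = as.numeric(ref_D),
                 stall_detach_time = as.numeric(stall_detach_time)),
            class = "vtsim_params")
}

#' Load a configuration document
#'
#' Parses a JSON configuration (text or file path) into the validated species
#' registry, interaction tables, scenario specification and simulation
#' parameters. The resolved configuration can be serialized back with
#' [serialize_config()]; `load_config(serialize_config(cfg))` is the identity.
#'
#' @param document JSON text (or a path to a JSON file)
#' @return object of class `vtsim_config` with elements `species` (named
#'   list of [species_def()]s), `tables`, `scenario`, `params`
#' @export
load_config <- function(document) {
  raw <- if (length(document) == 1L && !grepl("[{]", document) &&
             file.exists(document)) {
    jsonlite::fromJSON(document, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(paste(document, collapse = "\n"), simplifyVector = FALSE)
  }
  for (f in c("species", "tables", "scenario", "params"))
    if (is.null(raw[[f]])) stop("configuration error: missing mandatory field `", f, "`")

  species <- lapply(raw$species, function(s) {
    for (f in c("name", "klass", "radius"))
      if (is.null(s[[f]])) stop("configuration error: species missing field `", f, "`")
    species_def(s$name, s$klass, s$radius,
                s$diffusion_coeff %||% "stokes_einstein",
                s$initial_counts %||% list(),
                speed = s$speed, direction = s$direction)
  })
  names(species) <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(names(species)))
    stop("validation error: duplicate species names")

  tb <- raw$tables
  as_named_matrix <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    cols <- unique(unlist(lapply(x, names)))
    m <- matrix(0, length(x), length(cols), dimnames = list(names(x), cols))
    for (r in names(x)) for (cc in names(x[[r]])) m[r, cc] <- x[[r]][[cc]]
    m
  }
  ss <- as_named_matrix(tb$snare_strength)
  if (!is.null(ss)) {
    # square it up on the union of row/col names before the symmetry check
    all_nm <- unique(c(rownames(ss), colnames(ss)))
    full <- matrix(0, length(all_nm), length(all_nm), dimnames = list(all_nm, all_nm))
    full[rownames(ss), colnames(ss)] <- ss
    ss <- full
  }
  tables <- interaction_tables(
    k_coat_cargo = as_named_matrix(tb$k_coat_cargo),
    k_coat_snare = as_named_matrix(tb$k_coat_snare),
    k_coat_motor = as_named_matrix(tb$k_coat_motor),
    snare_strength = ss,
    catcher_rate = as_named_matrix(tb$catcher_rate),
    motor_catcher_rate = as_named_matrix(tb$motor_catcher_rate),
    coat_on_off = tb$coat_on_off %||% list(),
    motor_on_off = tb$motor_on_off %||% list(),
    k_poly = tb$k_poly %||% 0.1,
    k_fus_pair = tb$k_fus_pair %||% 0,
    tau_pair = tb$tau_pair %||% 1,
    class_limits = tb$class_limits %||% list(cargo = 20, snare = 15, motor = 5),
    shell_size = tb$shell_size %||% 30,
    k_fil_bind = tb$k_fil_bind %||% 0,
    k_clust = tb$k_clust %||% 5e8)

  pr <- raw$params
  params <- do.call(sim_params, pr)

  scenario <- raw$scenario
  scenario$cytoskeleton_style <- scenario$cytoskeleton_style %||% "none"
  if (!scenario$cytoskeleton_style %in%
      c("none", "random", "direct", "linear", "dipole", "radial", "polarized"))
    stop("validation error: unknown cytoskeleton_style `",
         scenario$cytoskeleton_style, "`")
  # compartments must sit inside the cell and must not overlap each other
  cellp <- scenario$cell
  if (is.null(cellp$cell_radius))
    stop("configuration error: missing mandatory field `scenario$cell$cell_radius`")
  comps <- scenario$compartments %||% list()
  if (length(comps)) {
    pos <- t(vapply(comps, function(cp) as.numeric(unlist(cp$position)), numeric(3)))
    rad <- vapply(comps, function(cp) cp$radius, 0)
    if (any(sqrt(rowSums(pos^2)) + rad > cellp$cell_radius + 1e-9))
      stop("validation error: compartment outside the cell")
    if (length(comps) > 1L) {
      for (i in seq_len(length(comps) - 1L)) for (j in (i + 1L):length(comps)) {
        if (.vnorm(pos[i, ] - pos[j, ]) < rad[i] + rad[j] - 1e-9)
          stop("validation error: compartments overlap")
      }
    }
  }

  structure(list(species = species, tables = tables, scenario = scenario,
                 params = params), class = "vtsim_config")
}

#' Serialize a configuration back to JSON text
#'
#' @param config a `vtsim_config`
#' @return a JSON string; `load_config()` of it reproduces `config`
#' @export
serialize_config <- function(config) {
  mat_to_list <- function(m) {
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    out <- lapply(rownames(m), function(r)
      stats::setNames(as.list(unname(m[r, ])), colnames(m)))
    stats::setNames(out, rownames(m))
  }
  sp <- lapply(unname(config$species), function(s) {
    l <- list(name = s$name, klass = s$klass, radius = s$radius,
              diffusion_coeff = s$diffusion_coeff)
    if (length(s$initial_counts)) l$initial_counts <- s$initial_counts
    if (!is.null(s$speed)) l$speed <- s$speed
    if (!is.null(s$direction)) l$direction <- s$direction
    l
  })
  tb <- config$tables
  tables <- list(k_coat_cargo = mat_to_list(tb$k_coat_cargo),
                 k_coat_snare = mat_to_list(tb$k_coat_snare),
                 k_coat_motor = mat_to_list(tb$k_coat_motor),
                 snare_strength = mat_to_list(tb$snare_strength),
                 catcher_rate = mat_to_list(tb$catcher_rate),
                 motor_catcher_rate = mat_to_list(tb$motor_catcher_rate),
                 coat_on_off = tb$coat_on_off, motor_on_off = tb$motor_on_off,
                 k_poly = tb$k_poly, k_fus_pair = tb$k_fus_pair,
                 tau_pair = tb$tau_pair, class_limits = tb$class_limits,
                 shell_size = tb$shell_size, k_fil_bind = tb$k_fil_bind,
                 k_clust = tb$k_clust)
  tables <- tables[!vapply(tables, is.null, TRUE)]
  pr <- unclass(config$params)
  jsonlite::toJSON(list(species = sp, tables = tables,
                        scenario = config$scenario, params = pr),
                   auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

#' Decompose the interaction tables into transport modules
#'
#' A transport module is one connected component of the species graph in
#' which coat, SNARE, motor and cargo species are linked by nonzero rates
#' (coat-cargo/snare/motor selection, SNARE-SNARE pairing, catcher
#' recruitment). Independent sub-matrices of the full interaction matrix
#' correspond to independently operating transport connections.
#'
#' @param tables a `vtsim_tables`
#' @return object of class `vtsim_modules`: list with `n_modules` and
#'   `modules` (list of character vectors of species names)
#' @export
validate_module_structure <- function(tables) {
  edges <- list()
  add_edges <- function(m) {
    if (is.null(m) || nrow(m) == 0L) return()
    idx <- which(m != 0, arr.ind = TRUE)
    if (nrow(idx)) {
      e <- cbind(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]])
      e <- e[e[, 1] != e[, 2], , drop = FALSE]
      if (nrow(e)) edges[[length(edges) + 1L]] <<- e
    }
  }
  add_edges(tables$k_coat_cargo); add_edges(tables$k_coat_snare)
  add_edges(tables$k_coat_motor); add_edges(tables$snare_strength)
  add_edges(tables$catcher_rate); add_edges(tables$motor_catcher_rate)
  if (!length(edges))
    return(structure(list(n_modules = 0L, modules = list()),
                     class = "vtsim_modules"))
  e <- do.call(rbind, edges)
  nodes <- sort(unique(c(e[, 1], e[, 2])))
  # union-find over species incident to at least one nonzero rate
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(e))) {
    a <- find(match(e[r, 1], nodes)); b <- find(match(e[r, 2], nodes))
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_along(nodes), find, 0L)
  modules <- split(nodes, comp)
  names(modules) <- NULL
  structure(list(n_modules = length(modules), modules = modules),
            class = "vtsim_modules")
}

#' @export
print.vtsim_modules <- function(x, ...) {
  cat("Transport modules:", x$n_modules, "\n")
  for (i in seq_along(x$modules))
    cat("  [", i, "] ", paste(x$modules[[i]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
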