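# Main simulation loop: movement every step, reaction sweeps every
# `reaction_stride` steps (effective dt = stride * dt), vesicle actions with
# every sweep, in the fixed order: internal chemistry -> depolymerization ->
# budding progression -> fusion attempts.

#' Run a full trafficking simulation
#'
#' Executes the main loop on a parsed configuration: (1) initialize, (2)
#' advance time, (3) move all agents (Brownian / motor / boost; steps into
#' obstacles rejected), (4) second-order reactions between agents or agents
#' and structures, (5) first-order reactions, (6) vesicle actions (internal
#' chemistry, coat depolymerization, budding, fusion, endocytosis), repeat.
#' Fully reproducible given (config, seed).
#'
#' @param config a `vtsim_config` (from [load_config()] or a preset)
#' @param seed optional integer overriding `config$params$seed`
#' @param record_every record time series every this many seconds (default:
#'   every reaction sweep)
#' @param progress unused hook for callers
#' @return object of class `vtsim_run`: list with `log` (event data.frame),
#'   `timeseries` (per-species, per-location counts), `metrics` (see
#'   [summarize()]), `state` (final simulation state environment), `config`
#' @export
run_simulation <- function(config, seed = NULL, record_every = NULL,
                           progress = FALSE) {
  stopifnot(inherits(config, "vtsim_config"))
  seed <- as.integer(seed %||% config$params$seed)
  set.seed(seed)
  st <- .init_state(config)
  p <- config$params
  nsteps <- if (p$t_end <= 0) 0L else as.integer(round(p$t_end / p$dt))
  stride <- p$reaction_stride
  dt_r <- stride * p$dt
  record_every <- record_every %||% dt_r
  rec_stride <- max(1L, as.integer(round(record_every / p$dt)))

  .record_timeseries(st)
  if (nsteps > 0L) for (step in seq_len(nsteps)) {
    st$t <- st$t + p$dt
    .move_agents(st)
    if (step %% stride == 0L) {
      .pair_sweep(st, dt_r)
      .first_order(st, dt_r)
      .vesicle_actions(st, dt_r)
      if (!is.null(st$signaling)) signaling_sweep(st, dt_r)
    }
    if (step %% rec_stride == 0L) .record_timeseries(st)
  }

  log <- .finalize_log(st)
  ts <- .finalize_timeseries(st)
  out <- list(log = log, timeseries = ts, metrics = summarize(log),
              state = st, config = config, seed = seed)
  class(out) <- "vtsim_run"
  out
}

#' @export
print.vtsim_run <- function(x, ...) {
  m <- x$metrics
  cat("vtsim run: t_end =", x$config$params$t_end, "s, seed =", x$seed, "\n")
  cat("  fusion events:", m$n_fusions, "(forward", m$n_forward,
      "/ backward", m$n_backward, ")\n")
  cat("  budding events:", m$n_buds, "; mean travel time:",
      round(m$mean_travel_time, 2), "s\n")
  invisible(x)
}

# ---------------------------------------------------------------- state ----

.init_state <- function(config) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$species <- config$species
  st$tables <- config$tables
  st$params <- config$params
  sc <- config$scenario
  cp <- sc$cell
  st$cell <- build_cell(cp$cell_radius, cp$nucleus_radius %||% 0,
                        as.numeric(unlist(cp$nucleus_center %||% c(0, 0, 0))))
  comps <- sc$compartments %||% list()
  cs_params <- sc$cytoskeleton_params %||% list()
  if (length(comps) >= 2L && is.null(cs_params$from)) {
    cs_params$from <- as.numeric(unlist(comps[[1]]$position))
    cs_params$to <- as.numeric(unlist(comps[[2]]$position))
    cs_params$r_from <- comps[[1]]$radius
    cs_params$r_to <- comps[[2]]$radius
  }
  st$filaments <- generate_cytoskeleton(sc$cytoskeleton_style %||% "none",
                                        cs_params, st$cell)
  st$t <- 0
  st$next_id <- 1L
  st$log <- vector("list", 256L); st$log_n <- 0L
  st$ts <- vector("list", 256L);  st$ts_n <- 0L
  st$clusters <- list()

  klass_of <- vapply(st$species, `[[`, "", "klass")
  st$klass_of <- klass_of

  # vesicle agents for the initial compartments
  st$ves <- list()
  for (cmp in comps) {
    counts <- unlist(cmp$counts %||% list())
    v <- vesicle_agent(st$next_id, cmp$identity, as.numeric(unlist(cmp$position)),
                       cmp$radius, counts)
    v$is_compartment <- TRUE
    v$state$mode <- if (isTRUE(cmp$mobile)) "diffusing" else "fixed"
    st$ves[[as.character(v$id)]] <- v
    st$next_id <- st$next_id + 1L
  }
  # plasma-membrane pseudo-compartment (endo/exocytosis scenarios)
  st$pm <- NULL
  if (isTRUE(sc$plasma_membrane$enabled %||% FALSE)) {
    pmc <- sc$plasma_membrane
    st$pm <- list(id = st$next_id, identity = "PM",
                  counts = unlist(pmc$counts %||% list()))
    st$next_id <- st$next_id + 1L
  }

  # cytosolic molecule pool
  n_tot <- 0L
  specs <- character(0)
  for (sp in names(st$species)) {
    n <- st$species[[sp]]$initial_counts[["cytosol"]] %||% 0
    if (n > 0) { specs <- c(specs, rep(sp, n)); n_tot <- n_tot + n }
  }
  st$mol <- .new_mol_set(specs, st)
  # membrane agents (explicit PM molecules)
  mem_specs <- character(0)
  if (!is.null(st$pm)) {
    for (sp in names(st$species)) {
      n <- st$species[[sp]]$initial_counts[["PM"]] %||% 0
      if (n > 0) mem_specs <- c(mem_specs, rep(sp, n))
    }
  }
  st$mem <- .new_mem_set(mem_specs, st)

  st$signaling <- if (!is.null(sc$signaling) &&
                      isTRUE(sc$signaling$enabled %||% TRUE) &&
                      length(sc$signaling)) sc$signaling else NULL
  st$internal_reactions <- lapply(sc$internal_reactions %||% list(), function(r)
    internal_reaction(unlist(r$educts), unlist(r$products %||% character(0)),
                      r$k, r$basis %||% "volume"))
  st
}

.species_D <- function(sp_def, params) {
  if (is.numeric(sp_def$diffusion_coeff)) sp_def$diffusion_coeff
  else stokes_einstein_D(sp_def$radius, params$ref_radius, params$ref_D)
}

.new_mol_set <- function(specs, st) {
  n <- length(specs)
  cellR <- st$cell$cell_radius
  pos <- matrix(0, n, 3)
  i <- 0L
  while (i < n) {
    cand <- matrix(stats::runif(3 * (n - i), -cellR, cellR), ncol = 3)
    ok <- .inside_cell(cand, st$cell)
    k <- which(ok)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - i))]
      pos[(i + 1L):(i + length(take)), ] <- cand[take, , drop = FALSE]
      i <- i + length(take)
    }
  }
  list(pos = pos, species = specs,
       radius = vapply(specs, function(s) st$species[[s]]$radius, 0,
                       USE.NAMES = FALSE),
       D = vapply(specs, function(s) .species_D(st$species[[s]], st$params), 0,
                  USE.NAMES = FALSE),
       alive = rep(TRUE, n), location = rep("cyt", n))
}

.new_mem_set <- function(specs, st) {
  n <- length(specs)
  pos <- if (n) .runit(n) * st$cell$cell_radius else matrix(0, 0, 3)
  list(pos = pos, species = specs,
       klass = if (n) unname(st$klass_of[specs]) else character(0),
       alive = rep(TRUE, n))
}

.mol_add <- function(st, species, pos, location = "cyt") {
  n <- length(species)
  if (!n) return(invisible())
  m <- st$mol
  m$pos <- rbind(m$pos, pos)
  m$species <- c(m$species, species)
  m$radius <- c(m$radius, vapply(species, function(s) st$species[[s]]$radius, 0,
                                 USE.NAMES = FALSE))
  m$D <- c(m$D, vapply(species, function(s) .species_D(st$species[[s]], st$params),
                       0, USE.NAMES = FALSE))
  m$alive <- c(m$alive, rep(TRUE, n))
  m$location <- c(m$location, rep(location, n))
  st$mol <- m
  invisible()
}

.mem_add <- function(st, species, pos) {
  n <- length(species)
  if (!n) return(invisible())
  m <- st$mem
  m$pos <- rbind(m$pos, pos)
  m$species <- c(m$species, species)
  m$klass <- c(m$klass, unname(st$klass_of[species]))
  m$alive <- c(m$alive, rep(TRUE, n))
  st$mem <- m
  invisible()
}

.log_event <- function(st, kind, id = NA, donor = NA, target = NA,
                       direction = NA_character_, manifest = NA_real_,
                       detail = NA_real_) {
  st$log_n <- st$log_n + 1L
  if (st$log_n > length(st$log)) st$log <- c(st$log, vector("list", length(st$log)))
  st$log[[st$log_n]] <- list(time = st$t, kind = kind, id = id, donor = donor,
                             target = target, direction = direction,
                             manifest = manifest, detail = detail)
  invisible()
}

.finalize_log <- function(st) {
  if (st$log_n == 0L)
    return(data.frame(time = numeric(), kind = character(), id = integer(),
                      donor = integer(), target = integer(),
                      direction = character(), manifest = numeric(),
                      detail = numeric()))
  recs <- st$log[seq_len(st$log_n)]
  data.frame(time = vapply(recs, `[[`, 0, "time"),
             kind = vapply(recs, `[[`, "", "kind"),
             id = vapply(recs, function(r) as.integer(r$id), 0L),
             donor = vapply(recs, function(r) as.integer(r$donor), 0L),
             target = vapply(recs, function(r) as.integer(r$target), 0L),
             direction = vapply(recs, function(r) as.character(r$direction), ""),
             manifest = vapply(recs, function(r) as.numeric(r$manifest), 0),
             detail = vapply(recs, function(r) as.numeric(r$detail), 0))
}

# ------------------------------------------------------------- movement ----

.move_agents <- function(st) {
  p <- st$params
  # cytosolic molecules (location "cyt"): reject steps out of the cell or
  # into the nucleus; "nuc" molecules stay inside the nucleus
  m <- st$mol
  idx <- which(m$alive & m$location == "cyt")
  if (length(idx)) {
    cell <- st$cell
    m$pos[idx, ] <- diffusion_step(m$pos[idx, , drop = FALSE], m$D[idx], p$dt,
                                   obstacle = function(pp) .inside_cell(pp, cell))
  }
  idx <- which(m$alive & m$location == "nuc")
  if (length(idx)) {
    cell <- st$cell
    inside_nuc <- function(pp) {
      sqrt(.rownorm2(sweep(pp, 2, cell$nucleus_center))) <= cell$nucleus_radius
    }
    m$pos[idx, ] <- diffusion_step(m$pos[idx, , drop = FALSE], m$D[idx], p$dt,
                                   obstacle = inside_nuc)
  }
  st$mol <- m
  # membrane agents: tangential diffusion on the cell sphere
  if (length(st$mem$species)) {
    mm <- st$mem
    idx <- which(mm$alive)
    if (length(idx)) {
      D_mem <- st$config$scenario$plasma_membrane$D_mem %||% 0.0025
      step <- matrix(.runif_unitvar(3L * length(idx)), ncol = 3) *
        sqrt(2 * D_mem * p$dt)
      np <- mm$pos[idx, , drop = FALSE] + step
      np <- np / sqrt(.rownorm2(np)) * st$cell$cell_radius
      mm$pos[idx, ] <- np
      st$mem <- mm
    }
  }
  # vesicles
  for (k in seq_along(st$ves)) {
    v <- st$ves[[k]]
    mode <- v$state$mode
    if (mode == "fixed" || mode == "docked") next
    if (mode == "diffusing") {
      D <- stokes_einstein_D(v$radius, p$ref_radius, p$ref_D) *
        (st$config$scenario$vesicle_D_scale %||% 1)
      prop <- v$position + .runif_unitvar(3L) * sqrt(2 * D * p$dt)
      if (.vesicle_position_ok(st, prop, v$radius, v$id)) v$position <- prop
    } else if (mode == "on_filament") {
      v <- .move_on_filament(st, v)
    } else if (mode == "boosted") {
      if (v$n_pol <= 0) {
        v$state$mode <- "diffusing"
      } else {
        prop <- v$position + v$state$boost_direction * p$boost_speed * p$dt
        if (.vesicle_position_ok(st, prop, v$radius, v$id)) v$position <- prop
        else v$state$mode <- "diffusing"
      }
    }
    st$ves[[k]] <- v
  }
}

.vesicle_position_ok <- function(st, pos, radius, self_id) {
  if (!.inside_cell(rbind(pos), st$cell, r = radius)) return(FALSE)
  for (w in st$ves) {
    if (w$id == self_id) next
    if (.vnorm(w$position - pos) < w$radius + radius - 1e-9) return(FALSE)
  }
  TRUE
}

.motor_counts <- function(st, v) {
  n_plus <- 0; n_minus <- 0; v_plus <- 0; v_minus <- 0
  for (sp in names(st$species)) {
    if (st$klass_of[[sp]] != "motor") next
    n <- .vcount(v, sp)
    if (n == 0) next
    d <- st$species[[sp]]$direction
    s <- st$species[[sp]]$speed
    if (d > 0) { n_plus <- n_plus + n; v_plus <- s }
    else { n_minus <- n_minus + n; v_minus <- s }
  }
  list(n_plus = n_plus, v_plus = v_plus, n_minus = n_minus, v_minus = v_minus)
}

.move_on_filament <- function(st, v) {
  fil <- st$filaments[[v$state$filament_id]]
  mc <- .motor_counts(st, v)
  v_eff <- tug_of_war_velocity(mc$n_plus, mc$v_plus, mc$n_minus, mc$v_minus)
  ns <- motor_step(v$state, fil, v_eff, st$params$dt,
                   stall_detach_time = st$params$stall_detach_time)
  newpos <- ns$position
  if (.vesicle_position_ok(st, newpos, v$radius, v$id)) {
    v$position <- newpos
    v$state <- if (identical(ns$mode, "diffusing"))
      list(mode = "diffusing") else
      utils::modifyList(v$state, ns[names(ns) != "position"])
  } else {
    # blocked on the track (e.g. reached the caged target compartment):
    # fall off and let local diffusion + fusion take over
    v$state <- list(mode = "diffusing")
  }
  v
}

# -------------------------------------------------------- reaction sweep ----

.catcher_k_on <- function(st, v, machinery_sp, tab) {
  if (is.null(tab) || nrow(tab) == 0L || !(machinery_sp %in% colnames(tab)))
    return(0)
  k <- 0
  for (catcher in rownames(tab)) {
    n <- .vcount(v, catcher)
    if (n > 0 && tab[catcher, machinery_sp] > 0)
      k <- k + catcher_binding_rate(tab[catcher, machinery_sp], n)
  }
  k
}

.pair_sweep <- function(st, dt_r) {
  # (a) cytosolic coat/motor recruitment onto vesicle agents (Eq 5b rule:
  # molecule and vesicle agents may overlap)
  m <- st$mol
  for (k in seq_along(st$ves)) {
    v <- st$ves[[k]]
    for (sp in names(st$species)) {
      kl <- st$klass_of[[sp]]
      if (!(kl %in% c("coat", "motor"))) next
      tab <- if (kl == "coat") st$tables$catcher_rate else st$tables$motor_catcher_rate
      k_on <- .catcher_k_on(st, v, sp, tab)
      if (k_on == 0) next
      idx <- which(m$alive & m$location == "cyt" & m$species == sp)
      if (!length(idx)) next
      cr <- suppressWarnings(
        contact_rule(st$species[[sp]]$radius, v$radius, k_on, dt_r,
                     overlap_allowed = TRUE))
      d2 <- .rownorm2(sweep(m$pos[idx, , drop = FALSE], 2, v$position))
      inr <- idx[d2 <= cr$critical_distance^2]
      if (!length(inr)) next
      hit <- inr[stats::runif(length(inr)) <= cr$probability]
      if (length(hit)) {
        m$alive[hit] <- FALSE
        v <- .vadd(v, sp, length(hit))
        for (h in hit) .log_event(st, "bind", id = h, target = v$id)
      }
    }
    st$ves[[k]] <- v
  }
  st$mol <- m
  # (b) cytosolic coat binding to the plasma membrane (structure partner,
  # Eq 5a analogue on the sphere shell): becomes an explicit membrane agent
  if (!is.null(st$pm)) .pm_recruitment(st, dt_r)
  # (c) diffusing vesicles with motors bind the nearest filament
  if (length(st$filaments) && st$tables$k_fil_bind > 0) {
    for (k in seq_along(st$ves)) {
      v <- st$ves[[k]]
      if (isTRUE(v$is_compartment) || v$state$mode != "diffusing") next
      mc <- .motor_counts(st, v)
      n_mot <- mc$n_plus + mc$n_minus
      if (n_mot == 0) next
      cr <- contact_rule(v$radius, 0, st$tables$k_fil_bind * n_mot, dt_r,
                         overlap_allowed = FALSE)
      nf <- .nearest_filament(v$position, st$filaments)
      if (is.finite(nf$distance) && nf$distance <= cr$critical_distance) {
        v$state <- list(mode = "on_filament", filament_id = nf$id,
                        arc = nf$arc, stalled_for = 0)
        st$ves[[k]] <- v
        .log_event(st, "bind", id = v$id, target = -nf$id)
      }
    }
  }
}

.pm_recruitment <- function(st, dt_r) {
  tab <- st$tables$catcher_rate
  m <- st$mol
  cellR <- st$cell$cell_radius
  for (sp in names(st$species)) {
    if (st$klass_of[[sp]] != "coat") next
    # PM catcher count: explicit membrane cargo agents act as catchers
    k_on <- 0
    if (!is.null(tab) && nrow(tab) > 0L && sp %in% colnames(tab)) {
      for (catcher in rownames(tab)) {
        n_c <- sum(st$mem$alive & st$mem$species == catcher) +
          (st$pm$counts[catcher] %|na|% 0)
        if (n_c > 0) k_on <- k_on + catcher_binding_rate(tab[catcher, sp], n_c)
      }
    }
    if (k_on == 0) next
    # Eq 5a with the membrane's local geometry: the reaction volume is a
    # shell of thickness delta on the inner face, V_r = 4 pi R^2 delta
    V_r <- reaction_volume(k_on, dt_r)
    delta <- V_r / (4 * pi * cellR^2)
    idx <- which(m$alive & m$location == "cyt" & m$species == sp)
    if (!length(idx)) next
    d <- sqrt(.rownorm2(m$pos[idx, , drop = FALSE]))
    hit <- idx[d >= cellR - delta]
    if (length(hit)) {
      m$alive[hit] <- FALSE
      .mem_add(st, m$species[hit],
               m$pos[hit, , drop = FALSE] /
                 sqrt(.rownorm2(m$pos[hit, , drop = FALSE])) * cellR)
    }
  }
  st$mol <- m
}

.first_order <- function(st, dt_r) {
  # coat/motor unbinding from vesicle agents back into the cytosol
  for (k in seq_along(st$ves)) {
    v <- st$ves[[k]]
    for (sp in names(st$species)) {
      kl <- st$klass_of[[sp]]
      if (!(kl %in% c("coat", "motor"))) next
      oo <- if (kl == "coat") st$tables$coat_on_off[[sp]] else
        st$tables$motor_on_off[[sp]]
      k_off <- oo$k_off %||% 0
      n <- .vcount(v, sp)
      if (k_off == 0 || n == 0) next
      fired <- stats::rbinom(1, n, first_order_probability(k_off, dt_r))
      if (fired > 0) {
        v <- .vadd(v, sp, -fired)
        dirs <- .runit(fired)
        .mol_add(st, rep(sp, fired),
                 matrix(v$position, fired, 3, byrow = TRUE) +
                   dirs * (v$radius + 1e-3))
        .log_event(st, "unbind", id = v$id, manifest = fired)
      }
    }
    st$ves[[k]] <- v
  }
  # membrane coat agents unbind from the PM into the cytosol
  if (!is.null(st$pm) && length(st$mem$species)) {
    mm <- st$mem
    for (sp in names(st$species)) {
      if (st$klass_of[[sp]] != "coat") next
      k_off <- st$tables$coat_on_off[[sp]]$k_off %||% 0
      if (k_off == 0) next
      idx <- which(mm$alive & mm$species == sp)
      if (!length(idx)) next
      p <- first_order_probability(k_off, dt_r)
      off <- idx[stats::runif(length(idx)) <= p]
      if (length(off)) {
        mm$alive[off] <- FALSE
        .mol_add(st, mm$species[off],
                 mm$pos[off, , drop = FALSE] * (1 - 0.01))
      }
    }
    st$mem <- mm
  }
}

# -------------------------------------------------------- vesicle actions ---

.vesicle_actions <- function(st, dt_r) {
  tb <- st$tables; p <- st$params
  # 1. internal chemistry
  if (length(st$internal_reactions)) {
    for (k in seq_along(st$ves))
      st$ves[[k]] <- internal_reaction_sweep(st$ves[[k]],
                                             st$internal_reactions, dt_r)
  }
  # 2. coat depolymerization (post-budding vesicles only)
  for (k in seq_along(st$ves)) {
    v <- st$ves[[k]]
    if (v$n_pol > 0 && is.null(v$budding)) {
      dp <- depolymerize_coat(v, tb, p, dt_r)
      v <- dp$vesicle
      if (dp$released > 0 && !is.na(v$pol_species)) {
        dirs <- .runit(dp$released)
        .mol_add(st, rep(v$pol_species, dp$released),
                 matrix(v$position, dp$released, 3, byrow = TRUE) +
                   dirs * (v$radius + 1e-3))
      }
      st$ves[[k]] <- v
    }
  }
  # 3. budding progression + initiation (donor compartments)
  .budding_actions(st, dt_r)
  # 4. endocytosis at the plasma membrane
  if (!is.null(st$pm)) .endocytosis_actions(st, dt_r)
  # 5. fusion attempts and dock completion
  .fusion_actions(st, dt_r)
}

.budding_actions <- function(st, dt_r) {
  tb <- st$tables; p <- st$params
  new_ves <- list()
  for (k in seq_along(st$ves)) {
    v <- st$ves[[k]]
    if (!isTRUE(v$is_compartment)) next
    if (is.null(v$budding)) {
      v <- initiate_budding(v, st$species, tb, dt_r, st$filaments)
      if (!is.null(v$budding))
        .log_event(st, "bud_start", id = v$id, detail = NA_real_)
    } else {
      v <- polymerize_coat_step(v, tb, dt_r)
      if (isTRUE(v$budding$complete)) {
        ld <- load_on_separation(v, st$species, tb)
        v <- ld$vesicle
        b <- v$budding
        r_new <- st$config$scenario$vesicle_radius %||% 0.05
        vol_new <- 4 / 3 * pi * r_new^2 * r_new
        surf_new <- 4 * pi * r_new^2
        pos_new <- v$position + b$site_dir * (v$radius + r_new + 1e-3)
        nv <- vesicle_agent(st$next_id, paste0("vesicle_from_", v$identity),
                            pos_new, r_new, ld$transfer, donor_id = v$id)
        st$next_id <- st$next_id + 1L
        nv$donor_identity <- v$identity
        nv$n_pol <- b$n_pol
        nv$pol_species <- b$coat
        nv$depol_clock <- 0
        nv$birth_time <- st$t
        nv$state <- list(mode = "diffusing")
        # volume & surface conservation: carve the bud out of the donor
        v$volume <- max(v$volume - vol_new, 1e-6)
        v$surface <- max(v$surface - surf_new, 1e-6)
        v$radius <- (3 * v$volume / (4 * pi))^(1 / 3)
        v$budding <- NULL
        new_ves[[length(new_ves) + 1L]] <- nv
        .log_event(st, "bud", id = nv$id, donor = v$id,
                   manifest = sum(ld$transfer), detail = b$t_bud)
      }
    }
    st$ves[[k]] <- v
  }
  for (nv in new_ves) st$ves[[as.character(nv$id)]] <- nv
}

.endocytosis_actions <- function(st, dt_r) {
  eo <- endocytosis_step(st$mem, st$clusters, st$species, st$tables, st$cell,
                         dt_r,
                         a0 = st$config$scenario$plasma_membrane$a0 %||% 2e-4,
                         mol = st$mol,
                         nuc_rate = st$config$scenario$plasma_membrane$nuc_rate %||% 0.05)
  st$mem <- eo$mem
  st$clusters <- eo$clusters
  st$mol <- eo$mol
  for (cl in eo$completed) {
    r_new <- st$config$scenario$vesicle_radius %||% 0.05
    inward <- -.unit(cl$anchor)
    pos <- cl$anchor + inward * (r_new + 1e-3)
    counts <- cl$counts
    # the shell coats are polymerized, not bound monomers
    coat_sp <- names(counts)[unname(st$klass_of[names(counts)]) == "coat"]
    n_shell <- sum(counts[coat_sp])
    counts <- counts[setdiff(names(counts), coat_sp)]
    nv <- vesicle_agent(st$next_id, "endocytic_vesicle", pos, r_new, counts,
                        donor_id = st$pm$id)
    st$next_id <- st$next_id + 1L
    nv$donor_identity <- "PM"
    nv$n_pol <- as.integer(n_shell)
    nv$pol_species <- if (length(coat_sp)) coat_sp[1] else NA_character_
    nv$depol_clock <- 0
    nv$birth_time <- st$t
    nv$state <- list(mode = "boosted", boost_direction = inward)
    st$ves[[as.character(nv$id)]] <- nv
    .log_event(st, "endocytose", id = nv$id, donor = st$pm$id,
               manifest = sum(counts))
  }
}

.fusion_actions <- function(st, dt_r) {
  tb <- st$tables
  # complete docks whose fusion time has elapsed
  ids <- names(st$ves)
  for (id in ids) {
    v <- st$ves[[id]]
    if (is.null(v) || is.na(v$docked_with)) next
    if (st$t >= v$dock_until) {
      pid <- as.character(v$docked_with)
      w <- st$ves[[pid]]
      if (is.null(w)) { v$docked_with <- NA_integer_; st$ves[[id]] <- v; next }
      # merge once per pair: act when v is the smaller id
      if (v$id > w$id) next
      mobile <- if (isTRUE(v$is_compartment)) w else v
      target <- if (isTRUE(v$is_compartment)) v else w
      dirn <- classify_fusion(mobile, target)
      merged <- merge_vesicles(v, w)
      merged$is_compartment <- isTRUE(v$is_compartment) || isTRUE(w$is_compartment)
      if (merged$is_compartment) {
        merged$identity <- target$identity
        merged$id <- target$id
        merged$state <- target$state
        merged$position <- target$position
      }
      travel <- if (!is.na(mobile$birth_time)) st$t - mobile$birth_time else NA_real_
      st$ves[[as.character(v$id)]] <- NULL
      st$ves[[as.character(w$id)]] <- NULL
      st$ves[[as.character(merged$id)]] <- merged
      .log_event(st, "fuse", id = mobile$id, donor = mobile$donor_id,
                 target = target$id, direction = dirn, detail = travel)
      next
    }
  }
  # new docking attempts: mobile, uncoated, undocked vesicles
  ids <- names(st$ves)
  for (id in ids) {
    v <- st$ves[[id]]
    if (is.null(v) || isTRUE(v$is_compartment)) next
    if (!is.na(v$docked_with) || v$n_pol > 0) next
    if (!v$state$mode %in% c("diffusing", "on_filament")) next
    for (jd in ids) {
      if (jd == id) next
      w <- st$ves[[jd]]
      if (is.null(w) || !is.na(w$docked_with)) next
      if (w$n_pol > 0) next
      af <- attempt_fusion(v, w, tb, dt_r)
      if (identical(af$outcome, "docked")) {
        v$docked_with <- w$id; w$docked_with <- v$id
        v$dock_until <- st$t + af$t_fus; w$dock_until <- v$dock_until
        v$state$mode <- "docked"
        if (!isTRUE(w$is_compartment)) w$state$mode <- "docked"
        st$ves[[id]] <- v; st$ves[[jd]] <- w
        .log_event(st, "dock", id = v$id, target = w$id,
                   detail = af$n_pairs)
        break
      }
    }
  }
  # exocytosis: fusion with the plasma membrane as structure partner
  if (!is.null(st$pm)) .pm_fusion(st, dt_r)
}

.pm_fusion <- function(st, dt_r) {
  tb <- st$tables
  cellR <- st$cell$cell_radius
  ids <- names(st$ves)
  for (id in ids) {
    v <- st$ves[[id]]
    if (is.null(v) || isTRUE(v$is_compartment) || v$n_pol > 0) next
    if (!is.na(v$docked_with)) next
    if (identical(v$state$mode, "boosted")) next
    d_to_pm <- cellR - .vnorm(v$position) - v$radius
    layer <- contact_rule(v$radius, 0, tb$k_fus_pair, dt_r,
                          overlap_allowed = FALSE)$delta
    if (d_to_pm > max(layer, 0.05)) next
    # local PM SNARE counts: explicit membrane SNARE agents inside the
    # contact patch around the closest membrane point
    anchor <- .unit(v$position) * cellR
    patch_r <- sqrt(max(2 * v$radius * layer, 0)) + v$radius
    snare_idx <- which(st$mem$alive & st$mem$klass == "snare")
    local_counts <- numeric(0)
    if (length(snare_idx)) {
      d2 <- .rownorm2(sweep(st$mem$pos[snare_idx, , drop = FALSE], 2, anchor))
      near <- snare_idx[d2 <= (3 * patch_r)^2]
      if (length(near)) local_counts <- table(st$mem$species[near])
    }
    if (!length(local_counts)) next
    np <- 0
    ss <- tb$snare_strength
    for (u in names(v$counts)) {
      if (!(u %in% rownames(ss))) next
      nu <- .vcount(v, u)
      if (nu == 0) next
      for (sv in names(local_counts)) {
        if (!(sv %in% colnames(ss)) || ss[u, sv] == 0) next
        np <- np + ss[u, sv] * min(nu, as.numeric(local_counts[[sv]]))
      }
    }
    if (np <= 0) next
    fr <- fusion_rate(np, tb$k_fus_pair, tb$tau_pair)
    crd <- contact_rule(v$radius, 0, fr$k_fus, dt_r, overlap_allowed = FALSE)
    if (d_to_pm <= crd$delta) {
      dirn <- classify_fusion(v, list(id = st$pm$id, identity = "PM"))
      # cargo and SNAREs become explicit membrane agents at the fusion site
      for (sp in names(v$counts)) {
        n <- .vcount(v, sp)
        if (n == 0) next
        kl <- st$klass_of[[sp]]
        if (kl %in% c("snare", "cargo_membrane")) {
          jitter <- .runit(n) * 0.05
          ppos <- matrix(anchor, n, 3, byrow = TRUE) + jitter
          ppos <- ppos / sqrt(.rownorm2(ppos)) * cellR
          .mem_add(st, rep(sp, n), ppos)
        } else if (kl %in% c("coat", "motor")) {
          st$pm$counts[sp] <- (st$pm$counts[sp] %|na|% 0) + n
        } else {
          st$pm$counts[sp] <- (st$pm$counts[sp] %|na|% 0) + n
        }
      }
      travel <- if (!is.na(v$birth_time)) st$t - v$birth_time else NA_real_
      .log_event(st, "fuse", id = v$id, donor = v$donor_id,
                 target = st$pm$id, direction = dirn, detail = travel)
      st$ves[[id]] <- NULL
    }
  }
}

# ------------------------------------------------------------ recording ----

.record_timeseries <- function(st) {
  row <- list(time = st$t)
  sp_names <- names(st$species)
  # cytosol
  for (sp in sp_names) {
    n <- sum(st$mol$alive & st$mol$species == sp & st$mol$location == "cyt")
    row[[paste0(sp, "@cytosol")]] <- n
  }
  if (length(st$mol$species)) {
    for (sp in unique(st$mol$species)) {
      n_nuc <- sum(st$mol$alive & st$mol$species == sp & st$mol$location == "nuc")
      if (n_nuc > 0 || paste0(sp, "@nucleus") %in% names(row))
        row[[paste0(sp, "@nucleus")]] <- n_nuc
      n_ns <- sum(st$mol$alive & st$mol$species == sp &
                    st$mol$location == "nuc_surface")
      if (n_ns > 0) row[[paste0(sp, "@nuc_surface")]] <- n_ns
    }
  }
  # membrane
  if (length(st$mem$species)) {
    for (sp in unique(st$mem$species))
      row[[paste0(sp, "@PM")]] <- sum(st$mem$alive & st$mem$species == sp)
  }
  if (!is.null(st$pm) && length(st$pm$counts)) {
    for (sp in names(st$pm$counts))
      row[[paste0(sp, "@PM")]] <- (row[[paste0(sp, "@PM")]] %||% 0) +
        unname(st$pm$counts[[sp]])
  }
  # clusters hold membrane molecules too
  if (length(st$clusters)) {
    for (cl in st$clusters) for (sp in names(cl$counts))
      row[[paste0(sp, "@PM")]] <- (row[[paste0(sp, "@PM")]] %||% 0) +
        unname(cl$counts[[sp]])
  }
  # compartments and in-transit vesicles
  for (v in st$ves) {
    loc <- if (isTRUE(v$is_compartment)) v$identity else "transit"
    for (sp in names(v$counts)) {
      key <- paste0(sp, "@", loc)
      row[[key]] <- (row[[key]] %||% 0) + unname(v$counts[[sp]])
    }
    if (v$n_pol > 0 && !is.na(v$pol_species)) {
      key <- paste0(v$pol_species, "@", if (isTRUE(v$is_compartment))
        v$identity else "transit")
      row[[key]] <- (row[[key]] %||% 0) + v$n_pol
    }
    if (!is.null(v$budding)) {
      key <- paste0(v$budding$coat, "@", v$identity)
      row[[key]] <- (row[[key]] %||% 0) + v$budding$n_pol
    }
  }
  st$ts_n <- st$ts_n + 1L
  if (st$ts_n > length(st$ts)) st$ts <- c(st$ts, vector("list", length(st$ts)))
  st$ts[[st$ts_n]] <- row
  invisible()
}

.finalize_timeseries <- function(st) {
  rows <- st$ts[seq_len(st$ts_n)]
  keys <- unique(unlist(lapply(rows, names)))
  mat <- matrix(0, length(rows), length(keys), dimnames = list(NULL, keys))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    mat[i, names(r)] <- unlist(r)
  }
  as.data.frame(mat)
}

# -------------------------------------------------------------- metrics ----

#' Summarize an event log into run metrics
#'
#' @param eventlog event data.frame of a `vtsim_run` (or the run itself)
#' @return list: `n_fusions`, `n_forward`, `n_backward`, `n_buds`,
#'   `mean_travel_time` (budding to fusion, s), `fusion_times` (event
#'   times), `backward_fraction`
#' @export
summarize <- function(eventlog) {
  if (inherits(eventlog, "vtsim_run")) eventlog <- eventlog$log
  fus <- eventlog[eventlog$kind == "fuse", , drop = FALSE]
  buds <- eventlog[eventlog$kind %in% c("bud", "endocytose"), , drop = FALSE]
  nf <- sum(fus$direction == "forward", na.rm = TRUE)
  nb <- sum(fus$direction == "backward", na.rm = TRUE)
  list(n_fusions = nrow(fus), n_forward = nf, n_backward = nb,
       n_buds = nrow(buds),
       mean_travel_time = if (nrow(fus)) mean(fus$detail, na.rm = TRUE) else NaN,
       fusion_times = fus$time,
       backward_fraction = if (nrow(fus)) nb / nrow(fus) else NaN)
}
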