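#' Create a vesicle/compartment agent
#'
#' Compartments are just large vesicles. Volume and surface are tracked
#' separately (both are conserved exactly by budding and fusion; after a
#' fusion the sphere radius is derived from the volume and the surplus
#' surface is implicitly corrugated). Molecule content is held as named
#' integer counts in six groups: bound coat monomers, polymerized coat
#' (`n_pol`), SNAREs, motors, membrane cargo and luminal cargo.
#'
#' @param id integer id
#' @param identity compartment label (e.g. `"compartment1"`, `"endosome"`)
#' @param position length-3 centre, um
#' @param radius sphere radius, um (sets volume and surface if not given)
#' @param counts named numeric vector of per-species molecule counts
#' @param donor_id id of the compartment this vesicle budded from (NA for
#'   initial compartments)
#' @param volume,surface override the spherical defaults, um^3 / um^2
#' @return object of class `vtsim_vesicle`
#' @export
vesicle_agent <- function(id, identity, position, radius, counts = numeric(0),
                          donor_id = NA_integer_, volume = NULL,
                          surface = NULL) {
  stopifnot(radius > 0, all(counts >= 0))
  volume <- volume %||% (4 / 3 * pi * radius^3)
  surface <- surface %||% (4 * pi * radius^2)
  v <- list(id = as.integer(id), identity = identity,
            donor_id = as.integer(donor_id),
            position = as.numeric(position),
            volume = volume, surface = surface,
            radius = (3 * volume / (4 * pi))^(1 / 3),
            counts = counts, n_pol = 0L, pol_species = NA_character_,
            state = list(mode = "diffusing"),
            budding = NULL, depol_clock = NA_real_, birth_time = NA_real_,
            docked_with = NA_integer_, dock_until = NA_real_)
  class(v) <- "vtsim_vesicle"
  v
}

.vcount <- function(ves, sp) {
  if (is.null(ves$counts) || !sp %in% names(ves$counts)) 0 else
    unname(ves$counts[[sp]])
}

.vadd <- function(ves, sp, n) {
  cur <- .vcount(ves, sp)
  new <- cur + n
  if (new < -1e-9) stop("count of ", sp, " would become negative")
  ves$counts[[sp]] <- max(0, new)
  ves
}

#' Coat/motor recruitment rate of a compartment
#'
#' Compartment-resident catcher molecules trigger the association of
#' cytosolic coats (or motors): the compartment-level binding rate constant
#' is the per-catcher rate times the catcher count, `k_on = k_catch *
#' n_catcher`. It is used as the second-order rate between the cytosolic
#' agent and the vesicle agent.
#'
#' @param k_catch per-catcher rate constant, 1/(M s)
#' @param n_catcher catcher molecule count (>= 0)
#' @return recruitment rate constant, 1/(M s)
#' @export
catcher_binding_rate <- function(k_catch, n_catcher) {
  stopifnot(k_catch >= 0, n_catcher >= 0)
  k_catch * n_catcher
}

#' Define an internal (well-mixed) vesicle reaction
#'
#' @param educts character (length 1 or 2) of species names
#' @param products character vector (may be empty = degradation)
#' @param k rate constant: 1/s (first order); second order: 1/(M s) for
#'   `basis = "volume"`, um^2/s per molecule pair for `basis = "surface"`
#' @param basis density basis of second-order propensities: luminal species
#'   react by volume, membrane-bound species by surface area
#' @return a `vtsim_internal_rule`
#' @export
internal_reaction <- function(educts, products, k, basis = c("volume", "surface")) {
  basis <- match.arg(basis)
  stopifnot(length(educts) %in% 1:2, k >= 0)
  structure(list(order = length(educts), educts = educts, products = products,
                 k = k, basis = basis), class = "vtsim_internal_rule")
}

# propensity of an internal rule given current counts (1/s)
.internal_propensity <- function(rule, ves) {
  if (rule$order == 1L) {
    rule$k * .vcount(ves, rule$educts[1])
  } else {
    ni <- .vcount(ves, rule$educts[1]); nj <- .vcount(ves, rule$educts[2])
    if (identical(rule$educts[1], rule$educts[2])) nj <- max(nj - 1, 0)
    if (rule$basis == "volume") {
      rule$k * ni * nj / (.N_A * .um3_to_litre(ves$volume))
    } else {
      rule$k * ni * nj / ves$surface
    }
  }
}

#' Stochastic sweep of the internal vesicle chemistry
#'
#' Runs the well-mixed multi-scale scheme inside one vesicle: for every
#' reaction the per-molecule reaction probability `a dt / n_i` (second
#' order, propensity `a = k n_i n_j / (N_A V)` by volume or `k n_i n_j / S`
#' by surface) or `1 - exp(-k dt)` (first order) is tested for each educt
#' molecule; counts and hence propensities are updated immediately after
#' each event.
#'
#' @param vesicle a `vtsim_vesicle`
#' @param reactions list of [internal_reaction()]s
#' @param dt effective sweep time step, s
#' @return the updated vesicle; attribute `"n_events"` counts firings
#' @export
internal_reaction_sweep <- function(vesicle, reactions, dt) {
  n_events <- 0L
  for (rule in reactions) {
    if (rule$k == 0) next
    n0 <- .vcount(vesicle, rule$educts[1])
    if (n0 == 0) next
    if (rule$order == 1L) {
      p <- first_order_probability(rule$k, dt)
      fired <- sum(stats::runif(n0) <= p)
      if (fired > 0) {
        vesicle <- .vadd(vesicle, rule$educts[1], -fired)
        for (pr in rule$products) vesicle <- .vadd(vesicle, pr, fired)
        n_events <- n_events + fired
      }
    } else {
      # per-molecule test with immediate updates
      for (m in seq_len(n0)) {
        ni <- .vcount(vesicle, rule$educts[1])
        if (ni == 0) break
        a <- .internal_propensity(rule, vesicle)
        if (a == 0) break
        p_mol <- a * dt / ni
        if (p_mol > 0.1)
          warning("internal_reaction_sweep: per-molecule probability ",
                  signif(p_mol, 3), " > 0.1; dt too coarse")
        if (stats::runif(1) <= p_mol) {
          for (ed in rule$educts) vesicle <- .vadd(vesicle, ed, -1)
          for (pr in rule$products) vesicle <- .vadd(vesicle, pr, 1)
          n_events <- n_events + 1L
        }
      }
    }
  }
  attr(vesicle, "n_events") <- n_events
  vesicle
}

#' Attempt to initiate a budding process at a donor compartment
#'
#' Budding is on demand: it starts with the stochastic formation of a
#' coat-cargo dimer with the coat(i)-cargo(j) rate constant, evaluated under
#' the internal well-mixed scheme. With no cargo, or no bound coat
#' monomers, no vesicle is ever formed. The budding site is the point of
#' the donor surface nearest to an attached cytoskeleton filament if one is
#' within reach, otherwise uniform random on the surface.
#'
#' @param vesicle donor compartment (not already budding)
#' @param species named list of [species_def()]s
#' @param tables a `vtsim_tables`
#' @param dt effective sweep time step, s
#' @param filaments optional filament list for budding-site selection
#' @param capture_dist filament must be closer than this for the site to
#'   snap to it, um
#' @return the vesicle, with `$budding` set to a new process (or unchanged)
#' @export
initiate_budding <- function(vesicle, species, tables, dt, filaments = list(),
                             capture_dist = 0.3) {
  if (!is.null(vesicle$budding)) return(vesicle)
  kcc <- tables$k_coat_cargo
  if (is.null(kcc) || nrow(kcc) == 0L) return(vesicle)
  for (coat in rownames(kcc)) {
    n_coat <- .vcount(vesicle, coat)
    if (n_coat == 0) next
    for (cargo in colnames(kcc)) {
      k <- kcc[coat, cargo]
      n_cargo <- .vcount(vesicle, cargo)
      if (k == 0 || n_cargo == 0) next
      a <- k * n_coat * n_cargo / (.N_A * .um3_to_litre(vesicle$volume))
      if (stats::runif(1) <= 1 - exp(-a * dt)) {
        # choose the budding site
        dir <- NULL
        if (length(filaments)) {
          nf <- .nearest_filament(vesicle$position, filaments)
          if (is.finite(nf$distance) && nf$distance <= vesicle$radius + capture_dist) {
            fil <- filaments[[nf$id]]
            fp <- .filament_point(fil, nf$arc)
            dir <- .unit(fp$point - vesicle$position)
          }
        }
        if (is.null(dir) || all(dir == 0)) dir <- .runit(1)[1, ]
        vesicle$budding <- list(coat = coat, n_pol = 0L, t_bud = 0,
                                site_dir = dir)
        return(vesicle)
      }
    }
  }
  vesicle
}

#' Advance coat polymerization of an active budding process
#'
#' Each donor-bound coat monomer of the budding coat species polymerizes into
#' the nascent shell with per-monomer probability `1 - exp(-k_poly dt)`
#' (propensity `k_poly * n_bound`). The nascent vesicle is pushed out of the
#' donor proportionally to shell completion; budding completes when
#' `n_pol == shell_size`. A donor depleted of monomers stalls.
#'
#' @param vesicle donor with `$budding` active
#' @param tables a `vtsim_tables` (uses `k_poly`, `shell_size`)
#' @param dt effective sweep time step, s
#' @return the vesicle; `$budding$complete` is TRUE when the shell is done
#' @export
polymerize_coat_step <- function(vesicle, tables, dt) {
  b <- vesicle$budding
  if (is.null(b)) return(vesicle)
  b$t_bud <- b$t_bud + dt
  n_bound <- .vcount(vesicle, b$coat)
  need <- tables$shell_size - b$n_pol
  if (n_bound > 0 && need > 0 && tables$k_poly > 0) {
    p <- first_order_probability(tables$k_poly, dt)
    fired <- min(stats::rbinom(1, n_bound, p), need)
    if (fired > 0) {
      vesicle <- .vadd(vesicle, b$coat, -fired)
      b$n_pol <- b$n_pol + fired
    }
  }
  b$complete <- b$n_pol >= tables$shell_size
  vesicle$budding <- b
  vesicle
}

#' Class-saturation of loading try numbers
#'
#' All species of one class (cargo, snare or motor) compete for a limited
#' number of binding sites on the coat: if the summed try numbers exceed the
#' class limit `L`, all are scaled by `L / sum` and re-integerized by
#' largest-remainder rounding so the total equals `floor(L)`.
#'
#' @param try_numbers named nonnegative counts per species
#' @param limit class limit `L` (>= 0)
#' @return integer counts, `sum <= limit`
#' @export
apply_class_saturation <- function(try_numbers, limit) {
  stopifnot(all(try_numbers >= 0), limit >= 0)
  s <- sum(try_numbers)
  if (s <= limit) {
    out <- as.integer(round(try_numbers))
    names(out) <- names(try_numbers)
    return(out)
  }
  scaled <- try_numbers * (limit / s)
  out <- .largest_remainder(scaled, limit)
  names(out) <- names(try_numbers)
  out
}

#' Load cargo, SNAREs and motors into a completed bud
#'
#' On separation each donor molecule of species `j` (class cargo, snare or
#' motor) is transferred with probability
#' `p_j = 1 - exp(-k_load(i, j) * <n_pol> * t_bud / (N_A V_donor))`
#' (surface-based density for membrane species), where `<n_pol> =
#' shell_size / 2` is the time-average of the linearly growing shell. Try
#' numbers are binomial draws, then class-saturated, then moved from donor
#' to vesicle.
#'
#' @param vesicle donor with a complete budding process
#' @param species named list of [species_def()]s
#' @param tables a `vtsim_tables`
#' @return list: `transfer` (named integer counts), `vesicle` (donor with
#'   counts removed)
#' @export
load_on_separation <- function(vesicle, species, tables) {
  b <- vesicle$budding
  stopifnot(!is.null(b), isTRUE(b$complete))
  npol_avg <- tables$shell_size / 2
  klass_of <- vapply(species, `[[`, "", "klass")
  load_tab <- list(cargo = tables$k_coat_cargo, snare = tables$k_coat_snare,
                   motor = tables$k_coat_motor)
  class_members <- list(
    cargo = names(species)[klass_of %in% c("cargo_membrane", "cargo_lumen")],
    snare = names(species)[klass_of == "snare"],
    motor = names(species)[klass_of == "motor"])
  transfer <- numeric(0)
  for (cls in names(class_members)) {
    tab <- load_tab[[cls]]
    if (is.null(tab) || nrow(tab) == 0L || !(b$coat %in% rownames(tab))) next
    tries <- numeric(0)
    for (sp in intersect(class_members[[cls]], colnames(tab))) {
      k <- tab[b$coat, sp]
      n_don <- .vcount(vesicle, sp)
      if (k == 0 || n_don == 0) { tries[sp] <- 0; next }
      denom <- if (identical(species[[sp]]$klass, "cargo_lumen"))
        .N_A * .um3_to_litre(vesicle$volume) else
        .N_A * .um3_to_litre(.surface_equiv_volume(vesicle))
      p <- 1 - exp(-k * npol_avg * b$t_bud / denom)
      tries[sp] <- stats::rbinom(1, n_don, min(p, 1))
    }
    if (!length(tries)) next
    lim <- tables$class_limits[[cls]] %||% Inf
    final <- apply_class_saturation(tries, lim)
    for (sp in names(final)) if (final[[sp]] > 0) {
      vesicle <- .vadd(vesicle, sp, -final[[sp]])
      transfer[sp] <- final[[sp]]
    }
  }
  list(transfer = transfer, vesicle = vesicle)
}

# Effective volume for surface-based loading densities: a thin membrane
# shell of thickness .MEM_THICK around the donor surface, so that surface
# rates use the same 1/(M s) entry unit as volume rates.
.MEM_THICK <- 0.01  # um
.surface_equiv_volume <- function(ves) ves$surface * .MEM_THICK

#' Linear coat depolymerization after budding
#'
#' After a lag `depol_lag` the shell shrinks linearly over `depol_time`:
#' `n_pol(t) = shell_size * max(0, 1 - (t - lag)/depol_time)`. Monomers
#' released since the last call are reported so the caller can return them
#' to the cytosolic pool at the vesicle position. Fusion is impossible
#' while `n_pol > 0` (coat shielding).
#'
#' @param vesicle a post-budding vesicle (`n_pol > 0`); `$depol_clock` holds
#'   the time since separation
#' @param tables a `vtsim_tables` (`shell_size`)
#' @param params a `vtsim_params` (`depol_lag`, `depol_time`)
#' @param dt elapsed time to add to the clock, s
#' @return list: `vesicle` (updated `n_pol`, clock), `released` (monomer
#'   count freed in this step)
#' @export
depolymerize_coat <- function(vesicle, tables, params, dt) {
  if (vesicle$n_pol <= 0) return(list(vesicle = vesicle, released = 0L))
  t0 <- vesicle$depol_clock
  if (is.na(t0)) t0 <- 0
  t1 <- t0 + dt
  target <- function(t) {
    if (params$depol_time <= 0) {
      if (t >= params$depol_lag) 0 else tables$shell_size
    } else {
      ceiling(tables$shell_size *
                max(0, 1 - max(0, t - params$depol_lag) / params$depol_time))
    }
  }
  new_n <- min(vesicle$n_pol, target(t1))
  released <- vesicle$n_pol - new_n
  vesicle$n_pol <- new_n
  vesicle$depol_clock <- t1
  list(vesicle = vesicle, released = as.integer(released))
}

#' One step of endocytic coat clustering at the plasma membrane
#'
#' Plasma-membrane molecules are explicit 2D diffusers on the cell sphere.
#' A cluster nucleates when a membrane coat and a membrane cargo meet within
#' the contact distance of the coat-cargo rate; it then grows by capturing
#' coat, snare, motor and cargo agents. The capture radius grows with the
#' cluster: footprint disc of area `size * a0` plus the reaction layer.
#' At `size == shell_size` the members convert into a vesicle with a full
#' shell (`n_pol = shell_size`), launched in boosted mode along the inward
#' normal.
#'
#' @param mem membrane agent set: list with `pos` (n x 3, on the sphere),
#'   `species`, `klass`, `alive`
#' @param clusters list of clusters (`anchor`, `members`, `size`, `counts`)
#' @param species named list of species defs
#' @param tables a `vtsim_tables`
#' @param cell a `vtsim_cell`
#' @param dt effective sweep time step, s
#' @param a0 membrane footprint area per coat, um^2
#' @param mol optional cytosolic molecule set (as in the driver state):
#'   clusters also recruit cytosolic coat monomers within their capture
#'   radius, the dominant supply route of a growing pit
#' @param nuc_rate nucleation rate per membrane coat in cargo contact, 1/s
#' @return list: `mem`, `clusters`, `completed` (list of completed-cluster
#'   descriptors with `anchor` and `counts`), and `mol` if it was supplied
#' @export
endocytosis_step <- function(mem, clusters, species, tables, cell, dt,
                             a0 = 2e-4, mol = NULL, nuc_rate = 0.05) {
  completed <- list()
  kcc <- tables$k_coat_cargo
  layer <- contact_rule(0.01, 0.01, tables$k_clust, dt,
                        overlap_allowed = FALSE)$delta
  # --- growth first: existing clusters capture nearby membrane agents, so
  # free coats preferentially join a cluster instead of nucleating a new one
  if (length(clusters)) {
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      if (cl$size >= tables$shell_size) next
      foot_r <- sqrt(cl$size * a0 / pi)
      capture <- foot_r + layer
      idx <- which(mem$alive)
      if (!length(idx)) next
      d2 <- .rownorm2(sweep(mem$pos[idx, , drop = FALSE], 2, cl$anchor))
      near <- idx[d2 <= capture^2]
      for (gi in near) {
        if (cl$size >= tables$shell_size) break
        sp <- mem$species[gi]; kl <- mem$klass[gi]
        if (!kl %in% c("coat", "snare", "motor", "cargo_membrane")) next
        mem$alive[gi] <- FALSE
        cl$counts[sp] <- (if (sp %in% names(cl$counts)) cl$counts[[sp]] else 0) + 1
        if (kl == "coat") cl$size <- cl$size + 1L
      }
      # cytosolic coat monomers are the dominant supply of a growing pit
      if (!is.null(mol) && cl$size < tables$shell_size) {
        cidx <- which(mol$alive & mol$location == "cyt")
        if (length(cidx)) {
          is_coat <- vapply(mol$species[cidx], function(sp)
            identical(species[[sp]]$klass, "coat"), TRUE)
          cidx <- cidx[is_coat]
        }
        if (length(cidx)) {
          d2c <- .rownorm2(sweep(mol$pos[cidx, , drop = FALSE], 2, cl$anchor))
          nearc <- cidx[d2c <= capture^2]
          for (gi in nearc) {
            if (cl$size >= tables$shell_size) break
            sp <- mol$species[gi]
            mol$alive[gi] <- FALSE
            cl$counts[sp] <- (if (sp %in% names(cl$counts)) cl$counts[[sp]] else 0) + 1
            cl$size <- cl$size + 1L
          }
        }
      }
      clusters[[k]] <- cl
    }
  }
  cluster_capture <- layer
  near_cluster <- function(p) {
    for (cl in clusters) {
      if (sum((p - cl$anchor)^2) <=
          (sqrt(cl$size * a0 / pi) + cluster_capture)^2) return(TRUE)
    }
    FALSE
  }
  # --- nucleation: rate-limited coat-cargo dimer formation within the
  # clustering reaction layer, on free membrane only
  if (!is.null(kcc) && nrow(kcc) > 0L) {
    coats <- which(mem$alive & mem$klass == "coat" &
                     mem$species %in% rownames(kcc))
    p_nuc <- 1 - exp(-nuc_rate * dt)
    if (length(coats)) {
      # species pairs with nonzero selection rate
      ok_cargo <- colnames(kcc)[colSums(kcc != 0) > 0]
      cargos <- which(mem$alive & mem$klass == "cargo_membrane" &
                        mem$species %in% ok_cargo)
      if (length(cargos)) {
        crit2 <- (0.01 + layer)^2   # molecule-scale radii + clustering layer
        for (ci in coats) {
          if (!mem$alive[ci]) next
          if (stats::runif(1) > p_nuc) next
          co <- mem$species[ci]
          pc <- mem$pos[ci, ]
          if (near_cluster(pc)) next
          d2 <- .rownorm2(sweep(mem$pos[cargos, , drop = FALSE], 2, pc))
          hit <- which(d2 <= crit2 & mem$alive[cargos] &
                         kcc[co, mem$species[cargos]] > 0)
          if (length(hit)) {
            gi <- cargos[hit[1]]
            counts <- stats::setNames(c(1, 1), c(co, mem$species[gi]))
            clusters[[length(clusters) + 1L]] <-
              list(anchor = .unit(pc) * cell$cell_radius,
                   size = 1L, counts = counts)
            mem$alive[c(ci, gi)] <- FALSE
          }
        }
      }
    }
  }
  if (length(clusters)) {
    done <- vapply(clusters, function(cl) cl$size >= tables$shell_size, TRUE)
    completed <- clusters[done]
    clusters <- clusters[!done]
  }
  out <- list(mem = mem, clusters = clusters, completed = completed)
  if (!is.null(mol)) out$mol <- mol
  out
}
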