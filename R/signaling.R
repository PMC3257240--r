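# Receptor-mediated endocytosis coupled to a one-stage MAPK cascade.
#
# Species conventions: "R" / "RL" are membrane-cargo receptor species
# (explicit agents on the PM, counts inside vesicles/endosomes); "MAPK" /
# "MAPKp" are cytosolic molecule agents. The ligand is an implicit bulk
# concentration: activation is first order after the ligand-addition time.

#' Default signaling block
#'
#' All rates are provisional config defaults (the source values are not
#' printed); the enzymatic deactivation runs only in the endosome with the
#' stated enzyme copy number.
#'
#' @param t_ligand ligand addition time, s
#' @param k_RL_on receptor activation rate after ligand addition, 1/s
#' @param enzyme_count deactivating enzyme copies in the endosome
#' @param k_cat,K_M Michaelis-Menten parameters of RL deactivation (1/s,
#'   molecule counts)
#' @param k_MAPK_act_PM MAPK activation rate by a PM receptor agent, 1/(M s)
#' @param k_MAPK_act_vesicle per-RL activation rate for RL inside
#'   vesicles/endosomes, 1/(M s)
#' @param k_dephos_cyt,k_dephos_nuc MAPKp deactivation rates, 1/s
#' @param k_nuc_bind nucleus-surface binding rate, 1/(M s)
#' @param k_nuc_release release rate from the nucleus surface, 1/s
#' @param D_signal diffusion coefficient of the signaling molecules, um^2/s
#' @return a list suitable as `scenario$signaling`
#' @export
signaling_config <- function(t_ligand = 5, k_RL_on = 0.5,
                             enzyme_count = 394, k_cat = 1, K_M = 50,
                             k_MAPK_act_PM = 1e8, k_MAPK_act_vesicle = 5e8,
                             k_dephos_cyt = 0.05, k_dephos_nuc = 0.05,
                             k_nuc_bind = 5e8, k_nuc_release = 0.5,
                             D_signal = 1.0) {
  as.list(environment())
}

#' One signaling sweep (runs inside the main loop)
#'
#' Applies, per reaction sweep: ligand binding at the PM (R -> RL, first
#' order after `t_ligand`); enzymatic RL deactivation inside endosomes
#' (Michaelis-Menten propensity `k_cat E RL / (K_M + RL)`); MAPK activation
#' by PM receptor agents (bimolecular, overlap rule) and by RL counts in
#' vesicles/endosomes (vesicle-protein interaction: rate scaled by the RL
#' count); MAPKp/MAPK dephosphorylation by location; nucleus-surface binding
#' (non-overlap layer rule) and release to the opposite side of the
#' envelope.
#'
#' @param st simulation state environment (internal)
#' @param dt_r effective sweep time step, s
#' @return invisibly, the state
#' @export
signaling_sweep <- function(st, dt_r) {
  sg <- st$signaling
  if (is.null(sg)) return(invisible(st))
  cell <- st$cell
  # --- r1: ligand binding at the PM
  if (st$t >= sg$t_ligand && length(st$mem$species)) {
    idx <- which(st$mem$alive & st$mem$species == "R")
    if (length(idx)) {
      p <- first_order_probability(sg$k_RL_on, dt_r)
      hit <- idx[stats::runif(length(idx)) <= p]
      if (length(hit)) st$mem$species[hit] <- "RL"
    }
  }
  # also receptors captured into clusters stay inactive/active as stored
  # --- r2: enzymatic deactivation, only inside endosome compartments
  for (k in seq_along(st$ves)) {
    v <- st$ves[[k]]
    if (!isTRUE(v$is_compartment) || !grepl("endosome", v$identity)) next
    n_rl <- .vcount(v, "RL")
    if (n_rl == 0) next
    a <- sg$k_cat * sg$enzyme_count * n_rl / (sg$K_M + n_rl)
    p_mol <- min(1, a * dt_r / n_rl)
    fired <- stats::rbinom(1, n_rl, p_mol)
    if (fired > 0) {
      v <- .vadd(v, "RL", -fired)
      v <- .vadd(v, "R", fired)
      st$ves[[k]] <- v
    }
  }
  # --- r11a: MAPK activation by explicit PM receptor agents
  m <- st$mol
  mapk_idx <- which(m$alive & m$species == "MAPK" & m$location == "cyt")
  if (length(mapk_idx)) {
    rl_idx <- which(st$mem$alive & st$mem$species == "RL")
    if (length(rl_idx)) {
      # membrane-bound RL acts as a structure partner: non-overlap layer
      cr <- contact_rule(0.005, 0.005, sg$k_MAPK_act_PM, dt_r,
                         overlap_allowed = FALSE)
      # candidates: MAPK near the membrane at all
      d_pm <- cell$cell_radius - sqrt(.rownorm2(m$pos[mapk_idx, , drop = FALSE]))
      near <- mapk_idx[d_pm <= cr$critical_distance + 0.05]
      if (length(near)) {
        rp <- st$mem$pos[rl_idx, , drop = FALSE]
        for (mi in near) {
          d2 <- .rownorm2(sweep(rp, 2, m$pos[mi, ]))
          nhits <- sum(d2 <= cr$critical_distance^2)
          if (nhits > 0 &&
              stats::runif(1) <= 1 - (1 - cr$probability)^nhits)
            m$species[mi] <- "MAPKp"
        }
      }
    }
    # --- r11b: activation by RL counts in vesicle agents (vesicle-protein
    # interaction: k_eff = k * n_RL, molecule and vesicle may overlap)
    mapk_idx <- which(m$alive & m$species == "MAPK" & m$location == "cyt")
    for (v in st$ves) {
      n_rl <- .vcount(v, "RL")
      if (n_rl == 0 || !length(mapk_idx)) next
      cr <- suppressWarnings(
        contact_rule(0.005, v$radius, sg$k_MAPK_act_vesicle * n_rl, dt_r,
                     overlap_allowed = TRUE))
      d2 <- .rownorm2(sweep(m$pos[mapk_idx, , drop = FALSE], 2, v$position))
      inr <- mapk_idx[d2 <= cr$critical_distance^2]
      if (length(inr)) {
        hit <- inr[stats::runif(length(inr)) <= cr$probability]
        if (length(hit)) m$species[hit] <- "MAPKp"
        mapk_idx <- setdiff(mapk_idx, hit)
      }
    }
  }
  # --- r12: dephosphorylation, separate constants in cytoplasm and nucleus
  for (loc in c("cyt", "nuc")) {
    kd <- if (loc == "cyt") sg$k_dephos_cyt else sg$k_dephos_nuc
    if (kd == 0) next
    idx <- which(m$alive & m$species == "MAPKp" & m$location == loc)
    if (!length(idx)) next
    p <- first_order_probability(kd, dt_r)
    hit <- idx[stats::runif(length(idx)) <= p]
    if (length(hit)) m$species[hit] <- "MAPK"
  }
  # --- r13/r14: nucleus-surface binding and trans-envelope release
  if (cell$nucleus_radius > 0) {
    V_r <- reaction_volume(sg$k_nuc_bind, dt_r)
    delta <- V_r / (4 * pi * cell$nucleus_radius^2)
    for (loc in c("cyt", "nuc")) {
      idx <- which(m$alive & m$species %in% c("MAPK", "MAPKp") &
                     m$location == loc)
      if (!length(idx)) next
      dn <- sqrt(.rownorm2(sweep(m$pos[idx, , drop = FALSE], 2,
                                 cell$nucleus_center)))
      hit <- if (loc == "cyt")
        idx[dn <= cell$nucleus_radius + delta] else
        idx[dn >= cell$nucleus_radius - delta]
      if (length(hit)) {
        m$location[hit] <- "nuc_surface"
        m$from_side <- m$from_side %||% rep(NA_character_, length(m$species))
        if (length(m$from_side) < length(m$species))
          m$from_side <- c(m$from_side,
                           rep(NA_character_,
                               length(m$species) - length(m$from_side)))
        m$from_side[hit] <- loc
        # snap onto the surface
        u <- sweep(m$pos[hit, , drop = FALSE], 2, cell$nucleus_center)
        u <- u / sqrt(.rownorm2(u))
        m$pos[hit, ] <- sweep(u * cell$nucleus_radius, 2,
                              cell$nucleus_center, "+")
      }
    }
    # release: emerge on the opposite side of the envelope
    idx <- which(m$alive & m$location == "nuc_surface")
    if (length(idx)) {
      p <- first_order_probability(sg$k_nuc_release, dt_r)
      hit <- idx[stats::runif(length(idx)) <= p]
      for (h in hit) {
        side <- m$from_side[h] %|na|% "cyt"
        u <- .unit(m$pos[h, ] - cell$nucleus_center)
        off <- 0.02
        if (side == "cyt") {   # entered from the cytoplasm -> release inside
          m$pos[h, ] <- cell$nucleus_center + u * (cell$nucleus_radius - off)
          m$location[h] <- "nuc"
        } else {               # entered from inside -> release outside
          m$pos[h, ] <- cell$nucleus_center + u * (cell$nucleus_radius + off)
          m$location[h] <- "cyt"
        }
      }
    }
  }
  st$mol <- m
  invisible(st)
}

#' Receptor and signaling flux report of a completed run
#'
#' @param run a `vtsim_run` from a signaling scenario
#' @return list: `series` (data.frame: time, R/RL per location, MAPKp by
#'   location), `budding` (times and cargo loads of endocytic budding
#'   events), `budding_frequency` (events/s), `mean_cargo_load`
#' @export
receptor_flux_report <- function(run) {
  ts <- run$timeseries
  gc <- function(nm) if (nm %in% names(ts)) ts[[nm]] else rep(0, nrow(ts))
  endo_cols <- grep("^R@.*endosome", names(ts), value = TRUE)
  endo_rl <- grep("^RL@.*endosome", names(ts), value = TRUE)
  series <- data.frame(
    time = ts$time,
    R_PM = gc("R@PM"), RL_PM = gc("RL@PM"),
    R_transit = gc("R@transit"), RL_transit = gc("RL@transit"),
    R_endosome = if (length(endo_cols))
      rowSums(ts[, endo_cols, drop = FALSE]) else rep(0, nrow(ts)),
    RL_endosome = if (length(endo_rl))
      rowSums(ts[, endo_rl, drop = FALSE]) else rep(0, nrow(ts)),
    MAPKp_cyt = gc("MAPKp@cytosol"),
    MAPKp_nuc = gc("MAPKp@nucleus") + gc("MAPKp@nuc_surface"),
    MAPK_cyt = gc("MAPK@cytosol"))
  buds <- run$log[run$log$kind %in% c("endocytose", "bud"), , drop = FALSE]
  t_span <- max(run$log$time, run$config$params$t_end, 1e-9)
  list(series = series,
       budding = data.frame(time = buds$time, cargo_load = buds$manifest),
       budding_frequency = nrow(buds) / t_span,
       mean_cargo_load = if (nrow(buds)) mean(buds$manifest) else NaN)
}
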