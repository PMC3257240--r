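#' Effective number of SNARE pairs between two vesicles
#'
#' Only SNAREs within the membrane contact patch can pair. The patch on each
#' partner is a spherical cap of height `delta` (the thickness of the
#' non-overlap reaction layer), area `2 pi r delta`; the smaller patch
#' governs. Local counts are total counts scaled by patch/total membrane
#' area. The pair count is then
#' `n_pairs = sum_uv s_uv * min(n_u_local(i), n_v_local(j))` -- the minimum
#' rule: there cannot be more pairs than the smaller number of partners.
#'
#' @param counts_i,counts_j named SNARE counts of the two partners
#' @param snare_strength symmetric pairing-strength matrix
#' @param r_i,r_j membrane sphere radii of the two partners, um
#' @param delta contact-layer thickness, um
#' @param area_i,area_j total membrane areas (defaults: spheres of the
#'   given radii), um^2
#' @return effective (real-valued) number of SNARE pairs
#' @export
snare_pairs <- function(counts_i, counts_j, snare_strength, r_i, r_j, delta,
                        area_i = 4 * pi * r_i^2, area_j = 4 * pi * r_j^2) {
  if (is.null(snare_strength) || nrow(snare_strength) == 0L) return(0)
  a_int <- 2 * pi * min(r_i, r_j) * delta        # smaller cap governs
  frac_i <- min(1, a_int / area_i)
  frac_j <- min(1, a_int / area_j)
  total <- 0
  for (u in rownames(snare_strength)) {
    nu <- (counts_i[u] %|na|% 0) * frac_i
    if (nu == 0) next
    for (v in colnames(snare_strength)) {
      s <- snare_strength[u, v]
      if (s == 0) next
      nv <- (counts_j[v] %|na|% 0) * frac_j
      total <- total + s * min(nu, nv)
    }
  }
  total
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else unname(a)

#' Fusion rate constant and fusion time from the SNARE pairing
#'
#' The fusion rate constant is the per-pair constant scaled by the effective
#' pair count, `k_fus = k_fus_pair * n_pairs`; the fusion duration is
#' inversely proportional to it, `t_fus = tau_pair / n_pairs` (more pairs =
#' faster zippering; infinite with no pairs).
#'
#' @param n_pairs effective pair count (>= 0)
#' @param k_fus_pair per-pair rate constant, 1/(M s)
#' @param tau_pair fusion time per pair, s
#' @return list `k_fus`, `t_fus`
#' @export
fusion_rate <- function(n_pairs, k_fus_pair, tau_pair) {
  stopifnot(n_pairs >= 0)
  list(k_fus = k_fus_pair * n_pairs,
       t_fus = if (n_pairs > 0) tau_pair / n_pairs else Inf)
}

#' Test a vesicle pair for docking/fusion
#'
#' Vesicle fusion is a bimolecular reaction between two non-overlapping
#' agents: the mobile partner must have a fully depolymerized coat
#' (`n_pol == 0`, coat shielding), the SNARE sets must give `n_pairs > 0`,
#' and the partners must be within the non-overlap contact distance derived
#' from `k_fus`. On success the pair docks (both immobilized) for `t_fus`,
#' after which the caller merges them; otherwise the vesicles bounce.
#'
#' @param ves_i,ves_j the two vesicle agents (i = mobile candidate)
#' @param tables a `vtsim_tables`
#' @param dt effective sweep time step, s
#' @return list: `outcome` (`"bounce"`, `"docked"`), `n_pairs`, `t_fus`,
#'   `critical_distance`
#' @export
attempt_fusion <- function(ves_i, ves_j, tables, dt) {
  bounce <- function(np = 0) list(outcome = "bounce", n_pairs = np,
                                  t_fus = Inf, critical_distance = NA_real_)
  if (ves_i$n_pol > 0 || isTRUE(ves_j$n_pol > 0)) return(bounce())
  layer <- contact_rule(ves_i$radius, ves_j$radius, tables$k_fus_pair, dt,
                        overlap_allowed = FALSE)$delta
  np <- snare_pairs(ves_i$counts, ves_j$counts, tables$snare_strength,
                    ves_i$radius, ves_j$radius, layer,
                    area_i = ves_i$surface, area_j = ves_j$surface)
  if (np <= 0) return(bounce(0))
  fr <- fusion_rate(np, tables$k_fus_pair, tables$tau_pair)
  cr <- contact_rule(ves_i$radius, ves_j$radius, fr$k_fus, dt,
                     overlap_allowed = FALSE)
  d <- .vnorm(ves_i$position - ves_j$position)
  if (d <= cr$critical_distance) {
    list(outcome = "docked", n_pairs = np, t_fus = fr$t_fus,
         critical_distance = cr$critical_distance)
  } else {
    out <- bounce(np)
    out$critical_distance <- cr$critical_distance
    out
  }
}

#' Merge two docked vesicles
#'
#' Volume and surface add exactly (both conserved); the merged radius is
#' derived from the volume, so the sphere carries surplus surface. All
#' molecule counts add. The merged agent keeps the identity and id of the
#' larger partner; the smaller partner's id is recorded as absorbed.
#'
#' @param ves_i,ves_j docked vesicle agents
#' @return merged `vtsim_vesicle`; attribute `"absorbed"` holds the id of
#'   the partner that lost its identity
#' @export
merge_vesicles <- function(ves_i, ves_j) {
  big <- if (ves_i$volume >= ves_j$volume) ves_i else ves_j
  small <- if (ves_i$volume >= ves_j$volume) ves_j else ves_i
  out <- big
  out$volume <- ves_i$volume + ves_j$volume
  out$surface <- ves_i$surface + ves_j$surface
  out$radius <- (3 * out$volume / (4 * pi))^(1 / 3)
  all_sp <- union(names(ves_i$counts), names(ves_j$counts))
  merged <- stats::setNames(vapply(all_sp, function(sp)
    .vcount(ves_i, sp) + .vcount(ves_j, sp), 0), all_sp)
  out$counts <- merged
  out$n_pol <- 0L
  out$docked_with <- NA_integer_
  out$dock_until <- NA_real_
  out$state <- big$state
  attr(out, "absorbed") <- small$id
  out
}

#' Classify a committed fusion event
#'
#' Backward fusion returns a vesicle to the compartment it budded from (the
#' failure mode a transport architecture must suppress); everything else is
#' forward.
#'
#' @param vesicle the fusing vesicle (carries `donor_id`)
#' @param target the target vesicle/compartment agent
#' @return `"backward"` or `"forward"`
#' @export
classify_fusion <- function(vesicle, target) {
  if (!is.na(vesicle$donor_id) &&
      (identical(vesicle$donor_id, target$id) ||
       identical(target$identity, vesicle$donor_identity %||% NULL)))
    return("backward")
  "forward"
}
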