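#' First-order reaction probability per time step
#'
#' `p = 1 - exp(-k dt)`: the exact per-step conversion probability of a
#' Poisson process with rate `k`.
#'
#' @param k rate constant, 1/s (>= 0)
#' @param dt time step, s (> 0)
#' @return probability in `[0, 1]`
#' @export
first_order_probability <- function(k, dt) {
  stopifnot(all(k >= 0), dt > 0)
  1 - exp(-k * dt)
}

#' Contact distance and acceptance probability of a bimolecular reaction
#'
#' A second-order rate constant over one time step defines a reaction volume
#' `V_r = k dt` (converted via Avogadro scaling, see [reaction_volume()]).
#' Two geometries realize it:
#'
#' * non-overlapping partners (`overlap_allowed = FALSE`): the reaction
#'   volume is wrapped around the contact sphere as a thin layer; partners
#'   react with probability 1 when their distance is below
#'   `r_i + r_j + delta`, where `delta` solves
#'   `(4 pi / 3) ((r_i + r_j + delta)^3 - (r_i + r_j)^3) = V_r`.
#' * overlapping partners (`overlap_allowed = TRUE`): the critical distance
#'   is the collision distance `r_i + r_j` and the acceptance probability is
#'   `P = V_r / V_int` with `V_int = (4 pi / 3)(r_i + r_j)^3`, clamped to 1
#'   with a warning (time step too large).
#'
#' @param r_i,r_j agent radii, um (>= 0)
#' @param k bimolecular rate constant, 1/(M s)
#' @param dt effective time step of the reaction sweep, s
#' @param overlap_allowed logical
#' @return list: `critical_distance` (um), `probability`, `delta` (layer
#'   thickness, um; 0 in the overlap case), `V_r` (um^3)
#' @export
contact_rule <- function(r_i, r_j, k, dt, overlap_allowed = FALSE) {
  stopifnot(r_i >= 0, r_j >= 0, k >= 0, dt > 0)
  V_r <- reaction_volume(k, dt)
  R <- r_i + r_j
  if (!overlap_allowed) {
    delta <- (V_r * 3 / (4 * pi) + R^3)^(1 / 3) - R
    list(critical_distance = R + delta, probability = if (k > 0) 1 else 0,
         delta = delta, V_r = V_r)
  } else {
    V_int <- 4 / 3 * pi * R^3
    P <- if (V_int > 0) V_r / V_int else 0
    if (P > 1) {
      warning("contact_rule: acceptance probability ", signif(P, 3),
              " clamped to 1 (dt too large for this rate)")
      P <- 1
    }
    list(critical_distance = R, probability = P, delta = 0, V_r = V_r)
  }
}

#' Define a reaction rule between explicit agents
#'
#' @param order 1 or 2
#' @param educts character vector of species names (length = order); for
#'   agent-structure reactions the second element names the structure
#' @param products character vector of product species names (may be empty)
#' @param k rate constant: 1/s (order 1) or 1/(M s) (order 2)
#' @param overlap_allowed do the educt agents overlap (order 2 only)?
#' @return a `vtsim_rule`
#' @export
reaction_rule <- function(order, educts, products, k, overlap_allowed = TRUE) {
  stopifnot(order %in% c(1L, 2L), k >= 0, length(educts) == order)
  structure(list(order = as.integer(order), educts = educts,
                 products = products, k = k,
                 overlap_allowed = isTRUE(overlap_allowed)),
            class = "vtsim_rule")
}

#' Sweep all bimolecular reactions between explicit agents
#'
#' Candidate pairs are found within the largest critical distance of any
#' rule, then tested with [contact_rule()]. Each agent is consumed at most
#' once per sweep: pairs are visited in randomized order, first match wins.
#'
#' @param agents list: `pos` (n x 3), `species` (character n), `radius`
#'   (numeric n), `alive` (logical n)
#' @param rules list of second-order [reaction_rule()]s
#' @param dt effective sweep time step, s
#' @return data.frame of events: rule index, agent indices `i`, `j`
#' @export
pair_reaction_sweep <- function(agents, rules, dt) {
  rules <- Filter(function(r) r$order == 2L, rules)
  events <- list()
  if (!length(rules)) return(.empty_pair_events())
  used <- rep(FALSE, length(agents$species))
  # precompute per-rule geometry
  cand_all <- list()
  for (ri in seq_along(rules)) {
    r <- rules[[ri]]
    ia <- which(agents$alive & agents$species == r$educts[1])
    ib <- which(agents$alive & agents$species == r$educts[2])
    if (!length(ia) || !length(ib)) next
    rad_a <- agents$radius[ia[1]]; rad_b <- agents$radius[ib[1]]
    cr <- contact_rule(rad_a, rad_b, r$k, dt, r$overlap_allowed)
    if (cr$critical_distance <= 0 || cr$probability <= 0) next
    # all pairs within the critical distance (n is small in sweep callers;
    # block distance computation keeps this vectorized)
    pa <- agents$pos[ia, , drop = FALSE]
    pb <- agents$pos[ib, , drop = FALSE]
    d2 <- outer(.rownorm2(pa), .rownorm2(pb), "+") - 2 * tcrossprod(pa, pb)
    hit <- which(d2 <= cr$critical_distance^2 + 1e-12, arr.ind = TRUE)
    if (!nrow(hit)) next
    keep <- ia[hit[, 1]] != ib[hit[, 2]]
    hit <- hit[keep, , drop = FALSE]
    if (!nrow(hit)) next
    cand_all[[length(cand_all) + 1L]] <-
      data.frame(rule = ri, i = ia[hit[, 1]], j = ib[hit[, 2]],
                 p = cr$probability)
  }
  if (!length(cand_all)) return(.empty_pair_events())
  cand <- do.call(rbind, cand_all)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  fired <- logical(nrow(cand))
  for (rr in seq_len(nrow(cand))) {
    i <- cand$i[rr]; j <- cand$j[rr]
    if (used[i] || used[j]) next
    if (stats::runif(1) <= cand$p[rr]) {
      used[i] <- TRUE; used[j] <- TRUE
      fired[rr] <- TRUE
    }
  }
  out <- cand[fired, c("rule", "i", "j")]
  rownames(out) <- NULL
  out
}

.empty_pair_events <- function()
  data.frame(rule = integer(), i = integer(), j = integer())

#' Sweep all first-order reactions over explicit agents
#'
#' Each eligible agent converts with probability `1 - exp(-k dt)`,
#' independently of its position.
#'
#' @param agents list as in [pair_reaction_sweep()]
#' @param rules list of first-order [reaction_rule()]s
#' @param dt effective sweep time step, s
#' @return data.frame of events: rule index, agent index `i`
#' @export
first_order_sweep <- function(agents, rules, dt) {
  rules1 <- which(vapply(rules, function(r) r$order == 1L, TRUE))
  events <- list()
  claimed <- rep(FALSE, length(agents$species))
  for (ri in sample(rules1)) {   # random rule order: fair channel competition
    r <- rules[[ri]]
    idx <- which(agents$alive & !claimed & agents$species == r$educts[1])
    if (!length(idx) || r$k == 0) next
    p <- first_order_probability(r$k, dt)
    hit <- idx[stats::runif(length(idx)) <= p]
    if (length(hit)) {
      claimed[hit] <- TRUE
      events[[length(events) + 1L]] <- data.frame(rule = ri, i = hit)
    }
  }
  if (!length(events)) return(data.frame(rule = integer(), i = integer()))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}
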