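#' Brownian displacement step
#'
#' Advances positions by a continuous-space random walk: each coordinate is
#' incremented by `sqrt(2 D dt) * xi` where `xi` is drawn from a uniform
#' distribution on `[-sqrt(3), sqrt(3)]` (mean 0, variance 1). The uniform
#' step avoids the long tails of the Gaussian and converges to it within a
#' few iterations by the central limit theorem. Obstacle handling is the
#' caller's job (see `obstacle` argument): proposed steps that would enter an
#' obstacle are rejected, the agent keeps its old position.
#'
#' @param position n x 3 matrix (or length-3 vector) of positions
#' @param D diffusion coefficient(s), um^2/s; scalar or length n
#' @param dt time step, s
#' @param obstacle optional predicate: given an n x 3 matrix of proposed
#'   positions, returns a logical vector, TRUE = position allowed
#' @return updated positions, same shape as the input
#' @export
diffusion_step <- function(position, D, dt, obstacle = NULL) {
  vec <- is.null(dim(position))
  pos <- if (vec) matrix(position, ncol = 3) else position
  n <- nrow(pos)
  if (n == 0L) return(position)
  stopifnot(all(D >= 0), dt > 0)
  disp <- matrix(.runif_unitvar(3L * n), ncol = 3) * sqrt(2 * D * dt)
  prop <- pos + disp
  if (!is.null(obstacle)) {
    ok <- obstacle(prop)
    prop[!ok, ] <- pos[!ok, ]
  }
  if (vec) prop[1, ] else prop
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = ref_D * ref_radius / radius`: diffusion scales inversely with the
#' hydrodynamic radius, anchored at a reference object.
#'
#' @param radius object radius, um (> 0)
#' @param ref_radius,ref_D reference radius (um) and diffusion coefficient
#'   (um^2/s)
#' @return diffusion coefficient, um^2/s
#' @export
stokes_einstein_D <- function(radius, ref_radius, ref_D) {
  if (any(radius <= 0)) stop("radius must be > 0")
  ref_D * ref_radius / radius
}

#' Effective velocity of a motor tug-of-war
#'
#' Oppositely directed motors on one vesicle compete; the effective signed
#' speed along the filament polarity is the motor-number-weighted mean
#' `(n+ v+ - n- v-) / (n+ + n-)` (0 when no motors are engaged). Positive
#' values move toward the filament plus end.
#'
#' @param n_plus,n_minus motor counts walking to the plus/minus end
#' @param v_plus,v_minus their speeds, um/s (>= 0)
#' @return signed effective speed, um/s
#' @export
tug_of_war_velocity <- function(n_plus, v_plus, n_minus, v_minus) {
  stopifnot(n_plus >= 0, n_minus >= 0)
  tot <- n_plus + n_minus
  if (tot == 0) return(0)
  (n_plus * v_plus - n_minus * v_minus) / tot
}

#' Advance an agent along a filament
#'
#' Moves the arc position by `v_eff * dt` (sign = polarity direction). An
#' agent stepping past either filament end detaches and returns to the
#' diffusing mode at the end point. An agent stalled (`v_eff == 0`) for
#' longer than `stall_detach_time` also detaches.
#'
#' @param state motion state list: `mode`, `filament_id`, `arc`,
#'   `stalled_for` (s)
#' @param filament the filament the agent is bound to
#' @param v_eff signed speed, um/s
#' @param dt time step, s
#' @param stall_detach_time seconds of stall tolerated before detaching
#' @return updated state; field `position` holds the new point
#' @export
motor_step <- function(state, filament, v_eff, dt, stall_detach_time = Inf) {
  stopifnot(identical(state$mode, "on_filament"))
  if (v_eff == 0) {
    state$stalled_for <- (state$stalled_for %||% 0) + dt
    if (state$stalled_for >= stall_detach_time) {
      fp <- .filament_point(filament, state$arc)
      return(list(mode = "diffusing", position = fp$point))
    }
    fp <- .filament_point(filament, state$arc)
    state$position <- fp$point
    return(state)
  }
  state$stalled_for <- 0
  s <- state$arc + v_eff * dt
  if (s <= 0 || s >= filament$length) {
    s <- max(0, min(filament$length, s))
    fp <- .filament_point(filament, s)
    return(list(mode = "diffusing", position = fp$point))
  }
  state$arc <- s
  fp <- .filament_point(filament, s)
  state$position <- fp$point
  state$tangent <- fp$tangent
  state
}

#' Actin-boost step of a fresh endocytic vesicle
#'
#' While the coat shell persists (`n_pol > 0`) the vesicle is pushed along
#' its stored boost direction (the inward membrane normal at the budding
#' site) with speed `v_boost`; once the shell is gone the undirected random
#' walk takes over.
#'
#' @param state motion state: `mode = "boosted"`, `position`,
#'   `boost_direction` (unit, pointing into the cell)
#' @param v_boost boost speed, um/s
#' @param n_pol remaining polymerized coat monomers
#' @param dt time step, s
#' @return updated state (mode `"diffusing"` once `n_pol == 0`)
#' @export
boost_step <- function(state, v_boost, n_pol, dt) {
  stopifnot(identical(state$mode, "boosted"))
  if (n_pol <= 0) {
    state$mode <- "diffusing"
    return(state)
  }
  state$position <- state$position + state$boost_direction * v_boost * dt
  state
}
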