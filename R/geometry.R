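#' Build the spherical model cell
#'
#' The cell is a sphere centred at the origin; an optional spherical nucleus
#' (radius 0 disables it) acts, like the plasma membrane, as a reflecting
#' obstacle and a reaction surface. Lengths in um.
#'
#' @param cell_radius cell radius (> 0)
#' @param nucleus_radius nucleus radius (>= 0; 0 = nucleus-free cell)
#' @param nucleus_center length-3 numeric, nucleus centre
#' @return object of class `vtsim_cell`
#' @export
build_cell <- function(cell_radius, nucleus_radius = 0,
                       nucleus_center = c(0, 0, 0)) {
  if (cell_radius <= 0) stop("cell_radius must be > 0")
  if (nucleus_radius < 0) stop("nucleus_radius must be >= 0")
  nucleus_center <- as.numeric(nucleus_center)
  if (nucleus_radius > 0 &&
      .vnorm(nucleus_center) + nucleus_radius >= cell_radius)
    stop("nucleus must lie strictly inside the cell")
  structure(list(cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 nucleus_center = nucleus_center, origin = c(0, 0, 0)),
            class = "vtsim_cell")
}

# Is each row of pos (n x 3) a legal centre for a sphere of radius r?
# Inside the plasma membrane and outside the nucleus.
.inside_cell <- function(pos, cell, r = 0) {
  d <- sqrt(.rownorm2(pos))
  ok <- d + r <= cell$cell_radius
  if (cell$nucleus_radius > 0) {
    dn <- sqrt(.rownorm2(sweep(pos, 2, cell$nucleus_center)))
    ok <- ok & (dn - r >= cell$nucleus_radius)
  }
  ok
}

.new_filament <- function(id, vertices, type = "microtubule") {
  vertices <- as.matrix(vertices)
  seg <- diff(vertices)
  keep <- c(TRUE, sqrt(rowSums(seg^2)) > 1e-12)
  vertices <- vertices[keep, , drop = FALSE]
  if (nrow(vertices) < 2L) return(NULL)
  seg <- diff(vertices)
  seglen <- sqrt(rowSums(seg^2))
  structure(list(id = id, vertices = vertices, type = type,
                 seglen = seglen, arclen = c(0, cumsum(seglen)),
                 length = sum(seglen)),
            class = "vtsim_filament")
}

# point at arc-length s along the filament; also the local unit tangent
.filament_point <- function(fil, s) {
  s <- max(0, min(fil$length, s))
  i <- findInterval(s, fil$arclen, rightmost.closed = TRUE)
  i <- max(1L, min(i, length(fil$seglen)))
  a <- fil$vertices[i, ]; b <- fil$vertices[i + 1L, ]
  t <- (s - fil$arclen[i]) / fil$seglen[i]
  list(point = a + t * (b - a), tangent = (b - a) / fil$seglen[i])
}

# clip a polyline to the cell interior (stop at first vertex outside)
.clip_polyline <- function(v, cell, margin = 0) {
  ok <- .inside_cell(v, cell, r = margin)
  last <- which(!ok)[1]
  if (!is.na(last)) v <- v[seq_len(max(1L, last - 1L)), , drop = FALSE]
  v
}

#' Generate a cytoskeleton architecture
#'
#' Produces the filament fields used in the transport scenarios. Filaments
#' are oriented polylines: the vertex order defines polarity, plus-direction
#' motors walk toward the last vertex.
#'
#' * `none`: empty list.
#' * `random`: `n` persistent random walks from uniform anchor points.
#' * `direct`: a bundle of straight filaments joining the surfaces of two
#'   compartments (`from`/`to` centres and radii).
#' * `linear`: parallel straight filaments along the compartment axis,
#'   offset across the cell cross-section.
#' * `dipole`: numerically traced field lines of two opposite point charges
#'   placed at the compartment centres; seeds on the donor sphere, traced
#'   until they hit the target sphere or the membrane.
#' * `radial`: straight rays from the cell centre to the plasma membrane.
#' * `polarized`: radial with an angular density bias toward a pole.
#'
#' @param style one of the above
#' @param params list of style parameters: `n` (filament count, default 40);
#'   `from`, `to`, `r_from`, `r_to` (compartment centres/radii, styles
#'   direct/linear/dipole); `step` (trace/growth step, um, default 0.05);
#'   `persistence` (random style, um, default 1); `pole` (unit vector,
#'   polarized), `bias` (von-Mises-like concentration, default 2)
#' @param cell a `vtsim_cell`
#' @return list of filaments
#' @export
generate_cytoskeleton <- function(style, params = list(), cell) {
  style <- match.arg(style, c("none", "random", "direct", "linear", "dipole",
                              "radial", "polarized"))
  n <- params$n %||% 40L
  step <- params$step %||% 0.05
  R <- cell$cell_radius
  fils <- switch(style,
    none = list(),
    radial = {
      dirs <- .runit(n)
      lapply(seq_len(n), function(i)
        .new_filament(i, rbind(c(0, 0, 0), dirs[i, ] * (R - 1e-3))))
    },
    polarized = {
      pole <- .unit(params$pole %||% c(-1, 0, 0))
      bias <- params$bias %||% 2
      dirs <- matrix(0, n, 3)
      i <- 0L
      while (i < n) {
        d <- .runit(1)[1, ]
        # accept with weight exp(bias * cos(angle to pole)) (rejection)
        if (stats::runif(1) < exp(bias * (sum(d * pole) - 1))) {
          i <- i + 1L; dirs[i, ] <- d
        }
      }
      lapply(seq_len(n), function(i)
        .new_filament(i, rbind(c(0, 0, 0), dirs[i, ] * (R - 1e-3))))
    },
    random = {
      persistence <- params$persistence %||% 1
      len <- params$length %||% (1.5 * R)
      lapply(seq_len(n), function(i) {
        # uniform anchor inside the cell
        repeat {
          p <- stats::runif(3, -R, R)
          if (.inside_cell(rbind(p), cell)) break
        }
        d <- .runit(1)[1, ]
        nstep <- ceiling(len / step)
        v <- matrix(0, nstep + 1L, 3); v[1, ] <- p
        sigma <- sqrt(step / persistence)   # angular diffusion of the tangent
        for (s in seq_len(nstep)) {
          d <- .unit(d + sigma * stats::rnorm(3))
          v[s + 1L, ] <- v[s, ] + d * step
        }
        .new_filament(i, .clip_polyline(v, cell))
      })
    },
    direct = {
      from <- as.numeric(params$from); to <- as.numeric(params$to)
      r_from <- params$r_from %||% 0; r_to <- params$r_to %||% 0
      axis <- .unit(to - from)
      # orthonormal frame for jitter around the axis
      e1 <- .unit(if (abs(axis[1]) < 0.9) pracma_cross(axis, c(1, 0, 0)) else
                    pracma_cross(axis, c(0, 1, 0)))
      e2 <- pracma_cross(axis, e1)
      spread <- params$spread %||% (0.5 * (r_from %||% 0.2))
      lapply(seq_len(n), function(i) {
        ang <- stats::runif(1, 0, 2 * pi); rr <- spread * sqrt(stats::runif(1))
        off <- rr * (cos(ang) * e1 + sin(ang) * e2)
        a <- from + axis * r_from + off
        b <- to - axis * r_to + off
        .new_filament(i, rbind(a, b))
      })
    },
    linear = {
      from <- as.numeric(params$from); to <- as.numeric(params$to)
      axis <- .unit(to - from)
      e1 <- .unit(if (abs(axis[1]) < 0.9) pracma_cross(axis, c(1, 0, 0)) else
                    pracma_cross(axis, c(0, 1, 0)))
      e2 <- pracma_cross(axis, e1)
      lapply(seq_len(n), function(i) {
        repeat {
          off <- stats::runif(2, -R, R)
          if (sum(off^2) < R^2) break
        }
        off3 <- off[1] * e1 + off[2] * e2
        # chord of the cell sphere in direction `axis` through the offset
        h <- sqrt(max(R^2 - sum(off3^2), 0)) - 1e-3
        if (h <= step) return(NULL)
        mid <- off3 - sum(off3 * axis) * axis
        .new_filament(i, rbind(mid - axis * h, mid + axis * h))
      })
    },
    dipole = {
      from <- as.numeric(params$from); to <- as.numeric(params$to)
      r_from <- params$r_from %||% 0.2; r_to <- params$r_to %||% 0.2
      seeds <- .runit(n) * (r_from + 1e-3)
      lapply(seq_len(n), function(i) {
        .trace_fieldline(from + seeds[i, ], from, to, r_to, cell, step)
      })
    })
  fils <- Filter(Negate(is.null), fils)
  for (i in seq_along(fils)) fils[[i]]$id <- i
  fils
}

# cross product (avoid a dependency for one 3-vector op)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Trace the field line of +q at `from`, -q at `to` starting at `p0` until it
# enters the target sphere (radius r_to about `to`) or leaves the cell.
.trace_fieldline <- function(p0, from, to, r_to, cell, step,
                             max_steps = 20000L) {
  v <- matrix(0, max_steps, 3)
  p <- p0; v[1, ] <- p
  nkeep <- 1L
  for (s in 2:max_steps) {
    d1 <- p - from; d2 <- p - to
    E <- d1 / (.vnorm(d1)^3 + 1e-12) - d2 / (.vnorm(d2)^3 + 1e-12)
    q <- p + .unit(E) * step
    if (!.inside_cell(rbind(q), cell)) {
      # a line that would leave the cell bends along the cortex: drop the
      # radial field component and keep the tangential one
      u <- .unit(p)
      Et <- E - sum(E * u) * u
      if (.vnorm(Et) < 1e-9) break
      q <- p + .unit(Et) * step
      q <- .unit(q) * min(.vnorm(q), cell$cell_radius - 1e-3)
    }
    p <- q
    nkeep <- s; v[s, ] <- p
    if (.vnorm(p - to) <= r_to) break
  }
  .new_filament(0L, v[seq_len(nkeep), , drop = FALSE])
}

#' Distance from a point to the nearest cellular structure
#'
#' Exact Euclidean distance to the nearest cytoskeleton filament segment, the
#' plasma membrane and the nucleus surface; used for capture tests and step
#' rejection.
#'
#' @param point length-3 numeric, inside the cell
#' @param cell a `vtsim_cell`
#' @param filaments list of filaments (may be empty)
#' @return list: `structure` (`"filament"`, `"membrane"`, `"nucleus"`),
#'   `distance`, `normal` (unit vector away from the structure surface),
#'   `filament_id`, `arc` (arc position of the closest filament point), plus
#'   `membrane_distance` and the per-structure distances
#' @export
distance_to_structures <- function(point, cell, filaments = list()) {
  point <- as.numeric(point)
  d_mem <- cell$cell_radius - .vnorm(point)
  best <- list(structure = "membrane", distance = d_mem,
               normal = -.unit(point), filament_id = NA_integer_, arc = NA_real_)
  if (cell$nucleus_radius > 0) {
    dn <- .vnorm(point - cell$nucleus_center) - cell$nucleus_radius
    if (dn < best$distance)
      best <- list(structure = "nucleus", distance = dn,
                   normal = .unit(point - cell$nucleus_center),
                   filament_id = NA_integer_, arc = NA_real_)
  }
  d_fil <- Inf
  for (f in filaments) {
    nf <- nrow(f$vertices)
    for (i in seq_len(nf - 1L)) {
      ps <- .point_segment(point, f$vertices[i, ], f$vertices[i + 1L, ])
      if (ps$dist < d_fil) {
        d_fil <- ps$dist
        if (ps$dist < best$distance)
          best <- list(structure = "filament", distance = ps$dist,
                       normal = .unit(point - ps$point), filament_id = f$id,
                       arc = f$arclen[i] + ps$t * f$seglen[i])
      }
    }
  }
  best$membrane_distance <- d_mem
  best$filament_distance <- d_fil
  best
}

# nearest filament only (id, distance, arc) — vectorized enough for the loop
.nearest_filament <- function(point, filaments) {
  bid <- NA_integer_; bd <- Inf; barc <- NA_real_
  for (f in filaments) {
    nf <- nrow(f$vertices)
    for (i in seq_len(nf - 1L)) {
      ps <- .point_segment(point, f$vertices[i, ], f$vertices[i + 1L, ])
      if (ps$dist < bd) {
        bd <- ps$dist; bid <- f$id; barc <- f$arclen[i] + ps$t * f$seglen[i]
      }
    }
  }
  list(id = bid, distance = bd, arc = barc)
}

#' Export filaments as a polyline table
#'
#' @param filaments list of filaments
#' @return data.frame with columns filament id, vertex index, x, y, z and the
#'   polarity flag (+1: vertex order runs toward the plus end)
#' @export
filament_table <- function(filaments) {
  if (!length(filaments))
    return(data.frame(filament = integer(), vertex = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      polarity = integer()))
  do.call(rbind, lapply(filaments, function(f) {
    data.frame(filament = f$id, vertex = seq_len(nrow(f$vertices)),
               x = f$vertices[, 1], y = f$vertices[, 2], z = f$vertices[, 3],
               polarity = 1L)
  }))
}
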