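# Internal constants and small numeric helpers shared across modules.

# Avogadro's number (1/mol).
.N_A <- 6.02214076e23

# Conversion: a bimolecular rate constant entered in 1/(M*s) corresponds to a
# reaction volume per molecule pair of k*dt / N_A litres; in um^3 (1 l = 1e15
# um^3) this is k*dt * .KVOL um^3. Fixed once, used everywhere.
.KVOL <- 1e15 / .N_A

#' Convert a bimolecular rate constant to a reaction volume
#'
#' A second-order rate constant `k` entered in 1/(M s) acting over a time step
#' `dt` defines a reaction volume `V_r = k * dt / N_A` (in litres), here
#' returned in um^3. This single conversion fixes the repo-wide unit system
#' (um, s, molecule counts).
#'
#' @param k bimolecular rate constant, 1/(M s)
#' @param dt time step, s
#' @return reaction volume in um^3
#' @export
reaction_volume <- function(k, dt) {
  stopifnot(k >= 0, dt > 0)
  k * dt * .KVOL
}

# litres from um^3
.um3_to_litre <- function(v) v * 1e-15

# Largest-remainder rounding of a nonnegative real vector to integers summing
# to `total` (total must be <= sum(x) rounded sensibly). Used by the class
# saturation rule.
.largest_remainder <- function(x, total) {
  if (length(x) == 0L) return(integer(0))
  total <- as.integer(floor(total))
  fl <- floor(x)
  out <- as.integer(fl)
  deficit <- total - sum(out)
  if (deficit > 0L) {
    rem <- x - fl
    ord <- order(rem, decreasing = TRUE)
    take <- ord[seq_len(min(deficit, length(ord)))]
    out[take] <- out[take] + 1L
  }
  out
}

# Uniform variate with mean 0 and variance 1: U(-sqrt(3), sqrt(3)).
.runif_unitvar <- function(n) stats::runif(n, min = -sqrt(3), max = sqrt(3))

# Squared row norms of an n x 3 matrix.
.rownorm2 <- function(m) rowSums(m * m)

# Euclidean norm of a length-3 vector.
.vnorm <- function(v) sqrt(sum(v * v))

# Unit vector (zero vector maps to zero).
.unit <- function(v) {
  n <- .vnorm(v)
  if (n == 0) v else v / n
}

# Distance from point p (length 3) to segment a-b; also returns closest point.
.point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab * ab)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  q <- a + t * ab
  list(dist = .vnorm(p - q), point = q, t = t)
}

# Random unit vector(s), n x 3.
.runit <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(.rownorm2(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
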