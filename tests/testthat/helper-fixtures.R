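# Shared fixtures: small configs and tables built in code.

minimal_config_json <- function() {
  jsonlite::toJSON(list(
    species = list(
      list(name = "coatA", klass = "coat", radius = 0.02,
           initial_counts = list(cytosol = 10)),
      list(name = "snare1", klass = "snare", radius = 0.005),
      list(name = "snare2", klass = "snare", radius = 0.005),
      list(name = "cargo1", klass = "cargo_membrane", radius = 0.005)),
    tables = list(
      snare_strength = list(snare1 = list(snare2 = 1),
                            snare2 = list(snare1 = 1)),
      k_coat_cargo = list(coatA = list(cargo1 = 1000)),
      catcher_rate = list(cargo1 = list(coatA = 1e6)),
      k_poly = 0.2, k_fus_pair = 1e8, tau_pair = 2,
      class_limits = list(cargo = 20, snare = 15, motor = 5),
      shell_size = 10),
    params = list(dt = 0.02, reaction_stride = 5, t_end = 1, seed = 7),
    scenario = list(cell = list(cell_radius = 3, nucleus_radius = 0),
                    cytoskeleton_style = "none",
                    compartments = list(
                      list(identity = "c1", position = c(-1, 0, 0),
                           radius = 0.4,
                           counts = list(cargo1 = 50, coatA = 10))))),
    auto_unbox = TRUE, digits = NA)
}

# independent connected-components oracle: brute-force reachability
brute_modules <- function(edges) {
  if (!nrow(edges)) return(0L)
  nodes <- unique(c(edges[, 1], edges[, 2]))
  reach <- function(start) {
    seen <- start
    repeat {
      nb <- unique(c(edges[edges[, 1] %in% seen, 2],
                     edges[edges[, 2] %in% seen, 1]))
      new <- setdiff(nb, seen)
      if (!length(new)) return(seen)
      seen <- c(seen, new)
    }
  }
  left <- nodes
  n <- 0L
  while (length(left)) {
    comp <- reach(left[1])
    left <- setdiff(left, comp)
    n <- n + 1L
  }
  n
}

# tiny vesicle for unit tests
test_vesicle <- function(id = 1L, radius = 0.4, counts = numeric(0),
                         position = c(0, 0, 0), donor_id = NA_integer_) {
  vesicle_agent(id, "test", position, radius, counts, donor_id = donor_id)
}

# distance from point p to a polyline given as a vertex matrix
seg_dist <- function(p, verts) {
  best <- Inf
  for (i in seq_len(nrow(verts) - 1)) {
    a <- verts[i, ]; b <- verts[i + 1, ]
    ab <- b - a
    t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    best <- min(best, sqrt(sum((p - (a + t * ab))^2)))
  }
  best
}
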