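test_that("snare_pairs: min rule, zero cases, brute-force equality", {
  ss <- matrix(0, 2, 2, dimnames = list(c("u1", "u2"), c("u1", "u2")))
  ss["u1", "u2"] <- ss["u2", "u1"] <- 1
  # no SNAREs on one partner -> 0
  expect_equal(snare_pairs(c(u1 = 5), numeric(0), ss, 0.05, 0.4, 0.02), 0)
  # single pair, s = 1: full-area patch -> min(3, 5) = 3
  big <- 100   # delta so large the patch covers everything (fractions clamp to 1)
  expect_equal(snare_pairs(c(u1 = 3), c(u2 = 5), ss, 0.05, 0.05, big), 3)

  # brute-force oracle on random small cases: enumerate all (u, v) terms
  set.seed(15)
  for (rep in 1:50) {
    ns <- sample(2:4, 1)
    nm <- paste0("s", 1:ns)
    m <- matrix(runif(ns * ns), ns, ns, dimnames = list(nm, nm))
    m <- (m + t(m)) / 2
    ci <- stats::setNames(rpois(ns, 4), nm)
    cj <- stats::setNames(rpois(ns, 4), nm)
    r_i <- runif(1, 0.03, 0.5); r_j <- runif(1, 0.03, 0.5)
    delta <- runif(1, 0.005, 0.05)
    a_int <- 2 * pi * min(r_i, r_j) * delta
    fi <- min(1, a_int / (4 * pi * r_i^2)); fj <- min(1, a_int / (4 * pi * r_j^2))
    brute <- 0
    for (u in nm) for (v in nm)
      brute <- brute + m[u, v] * min(ci[[u]] * fi, cj[[v]] * fj)
    expect_equal(snare_pairs(ci, cj, m, r_i, r_j, delta), brute,
                 tolerance = 1e-12)
  }
})

test_that("fusion_rate is linear in pairs and inverse for the time", {
  expect_equal(fusion_rate(0, 0.1, 5)$k_fus, 0)
  expect_equal(fusion_rate(0, 0.1, 5)$t_fus, Inf)
  f1 <- fusion_rate(7, 0.1, 5)
  expect_equal(f1$k_fus, 0.7)
  expect_equal(f1$t_fus, 5 / 7)
  f2 <- fusion_rate(14, 0.1, 5)
  expect_equal(f2$k_fus, 2 * f1$k_fus)
  expect_equal(f2$t_fus, f1$t_fus / 2)
})

test_that("attempt_fusion: shielding, nonmatching bounce, geometric waiting time", {
  ss <- matrix(0, 2, 2, dimnames = list(c("sX", "sY"), c("sX", "sY")))
  ss["sX", "sY"] <- ss["sY", "sX"] <- 1
  tb <- interaction_tables(snare_strength = ss, k_fus_pair = 5e8,
                           tau_pair = 2)
  vi <- test_vesicle(1L, radius = 0.05, counts = c(sX = 10),
                     position = c(0.449, 0, 0))
  vj <- test_vesicle(2L, radius = 0.4, counts = c(sY = 200),
                     position = c(0, 0, 0))
  # coated vesicle always bounces even with matching SNAREs
  vi_coated <- vi; vi_coated$n_pol <- 5L
  expect_equal(attempt_fusion(vi_coated, vj, tb, 0.1)$outcome, "bounce")
  # nonmatching SNARE sets bounce
  vj_bad <- vj; vj_bad$counts <- c(sX = 200)
  expect_equal(attempt_fusion(vi, vj_bad, tb, 0.1)$outcome, "bounce")
  # matched pair in contact docks
  res <- attempt_fusion(vi, vj, tb, 0.1)
  expect_equal(res$outcome, "docked")
  expect_gt(res$n_pairs, 0)
  expect_lt(res$t_fus, Inf)
})

test_that("merge geometry: 2^(1/3) law, surplus surface, exact conservation", {
  r <- 0.2
  vi <- test_vesicle(1L, radius = r, counts = c(sX = 3))
  vj <- test_vesicle(2L, radius = r, counts = c(sX = 5, sY = 2))
  m <- merge_vesicles(vi, vj)
  expect_equal(m$radius, 2^(1 / 3) * r, tolerance = 1e-12)
  expect_equal(m$volume, vi$volume + vj$volume)
  expect_equal(m$surface, 8 * pi * r^2)
  expect_gt(m$surface, 4 * pi * m$radius^2)      # surplus surface
  expect_equal(unname(m$counts[["sX"]]), 8)
  expect_equal(unname(m$counts[["sY"]]), 2)

  # conservation audit over many random merges
  set.seed(16)
  vol_tot <- 0; surf_tot <- 0; vol_in <- 0; surf_in <- 0
  for (i in 1:1000) {
    a <- test_vesicle(1L, radius = runif(1, 0.05, 0.5))
    b <- test_vesicle(2L, radius = runif(1, 0.05, 0.5))
    vol_in <- vol_in + a$volume + b$volume
    surf_in <- surf_in + a$surface + b$surface
    m <- merge_vesicles(a, b)
    vol_tot <- vol_tot + m$volume
    surf_tot <- surf_tot + m$surface
  }
  expect_equal(vol_tot, vol_in, tolerance = 1e-12)
  expect_equal(surf_tot, surf_in, tolerance = 1e-12)
})

test_that("classify_fusion partitions events by donor identity", {
  comp1 <- test_vesicle(1L)
  comp2 <- test_vesicle(2L)
  v <- test_vesicle(9L, donor_id = 1L)
  expect_equal(classify_fusion(v, comp1), "backward")
  expect_equal(classify_fusion(v, comp2), "forward")
})

test_that("repeated collisions give a geometric docking waiting time", {
  # a matched pair bouncing near contact: each sweep the gap is resampled
  # uniformly on [0, g_max]; docking succeeds iff gap <= delta(k_fus), so
  # the per-sweep success probability is p = delta/g_max and the number of
  # collisions until docking is geometric (vesicles "might need several
  # collisions until they finally fuse").
  set.seed(17)
  ss <- matrix(1, 1, 1, dimnames = list("sX", "sX"))
  tb <- interaction_tables(snare_strength = ss, k_fus_pair = 5e8,
                           tau_pair = 2)
  vj <- test_vesicle(2L, radius = 0.4, counts = c(sX = 300))
  vi0 <- test_vesicle(1L, radius = 0.05, counts = c(sX = 10))
  probe <- attempt_fusion(vi0, vj, tb, 0.1)   # to learn the critical distance
  dcrit <- probe$critical_distance
  delta <- dcrit - 0.45
  expect_gt(delta, 0)
  g_max <- 4 * delta
  p_true <- delta / g_max
  waits <- vapply(1:1500, function(i) {
    n <- 0L
    repeat {
      n <- n + 1L
      gap <- runif(1, 0, g_max)
      vi <- vi0; vi$position <- c(0.45 + gap, 0, 0)
      if (identical(attempt_fusion(vi, vj, tb, 0.1)$outcome, "docked")) break
    }
    n
  }, 1L)
  # chi-square against the geometric pmf (discrete, so no KS)
  kmax <- 8
  obs <- table(factor(pmin(waits, kmax), levels = 1:kmax))
  pr <- dgeom(0:(kmax - 2), p_true)
  pr <- c(pr, 1 - sum(pr))
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(chi$p.value, 0.01)
})
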