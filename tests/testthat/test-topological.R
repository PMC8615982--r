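# Gauss integrals (writhe family) and Rips persistence with independent
# oracles.

test_that("writhe matches the numerical Gauss double integral on random
           polygons", {
  set.seed(41)
  for (rep in 1:2) {
    xyz <- matrix(rnorm(12 * 3, sd = 3), 12, 3)
    p <- mk_structure(xyz)
    g <- gauss_integrals(p, max_link = 1e9)
    expect_equal(unname(g["writhe"]), writhe_quadrature(xyz),
                 tolerance = 1e-6)
  }
})

test_that("planar curves have zero writhe and mirrors negate the signed
           family", {
  xy <- cbind(seq(0, 11) * 2, sin(seq(0, 11)) * 4, 0)
  g <- gauss_integrals(mk_structure(xy), max_link = 1e9)
  expect_lt(abs(g["writhe"]), 1e-9)

  set.seed(42)
  xyz <- matrix(rnorm(14 * 3, sd = 3), 14, 3)
  mir <- xyz
  mir[, 1] <- -mir[, 1]
  g0 <- gauss_integrals(mk_structure(xyz), max_link = 1e9)
  g1 <- gauss_integrals(mk_structure(mir), max_link = 1e9)
  # odd number of signed factors -> negated; fully absolute -> unchanged
  expect_equal(unname(g1["writhe"]), -unname(g0["writhe"]), tolerance = 1e-9)
  expect_equal(unname(g1["acn"]), unname(g0["acn"]), tolerance = 1e-9)
  expect_equal(unname(g1["o2_1234_aa"]), unname(g0["o2_1234_aa"]),
               tolerance = 1e-9)
  expect_equal(unname(g1["o2_1234_ss"]), unname(g0["o2_1234_ss"]),
               tolerance = 1e-9) # two signed factors: sign cancels
  expect_equal(unname(g1["o2_1324_sa"]), -unname(g0["o2_1324_sa"]),
               tolerance = 1e-9) # one signed factor survives
  expect_equal(unname(g1["o3_123456"]), -unname(g0["o3_123456"]),
               tolerance = 1e-9) # three signed factors
  expect_equal(unname(g1["o3_123456_abs"]), unname(g0["o3_123456_abs"]),
               tolerance = 1e-9)
})

test_that("Gauss descriptor has 31 finite components, rigid-motion invariant", {
  set.seed(43)
  ds <- small_dataset()
  p <- ds$structures[[7]]
  g0 <- gauss_integrals(p)
  expect_length(g0, 31L)
  expect_true(all(is.finite(g0)))
  g1 <- gauss_integrals(rotate_structure(p, seed = 3))
  expect_equal(g0, g1, tolerance = 1e-9)

  short <- make_segment("helix", 3)
  expect_warning(gs <- gauss_integrals(short), "shorter")
  expect_true(all(gs == 0))
})

test_that("Rips barcodes match closed-form cases", {
  # points pairwise far beyond the filtration cap: n H0 bars, nothing above
  far <- cbind(c(0, 100, 200, 300), 0, 0)
  b <- persistent_homology(far, max_radius = 16)
  expect_equal(nrow(b$h0), 4L)
  expect_true(all(is.infinite(b$h0[, "death"])))
  expect_equal(nrow(b$h1), 0L)
  expect_equal(nrow(b$h2), 0L)

  # two points at distance d: one H0 bar dies exactly at d
  b2 <- persistent_homology(cbind(c(0, 7.5), 0, 0), max_radius = 16)
  deaths <- sort(b2$h0[, "death"])
  expect_equal(deaths[1], 7.5)
  expect_true(is.infinite(deaths[2]))

  # 8 points on a circle of radius 5: exactly one H1 bar, persistent
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  circ <- cbind(5 * cos(th), 5 * sin(th), 0)
  b3 <- persistent_homology(circ, max_radius = 16)
  expect_equal(nrow(b3$h1), 1L)
  expect_gt(b3$h1[1, "death"] / b3$h1[1, "birth"], 1)
})

test_that("H0 deaths equal single-linkage merge heights and alive counts
           equal GF(2) Betti numbers", {
  set.seed(44)
  xyz <- matrix(rnorm(10 * 3, sd = 4), 10, 3)
  b <- persistent_homology(xyz, max_radius = 1e6)
  hc <- hclust(dist(xyz), method = "single")
  expect_equal(sort(b$h0[is.finite(b$h0[, "death"]), "death"]),
               sort(hc$height), tolerance = 1e-9)

  # independent boundary-rank oracle at every critical scale, dims 0-2
  xyz7 <- matrix(rnorm(7 * 3, sd = 2.2), 7, 3)
  d <- as.matrix(dist(xyz7))
  b7 <- persistent_homology(xyz7, max_radius = 1e6)
  crit <- sort(unique(c(0, d[upper.tri(d)])))
  probes <- c(crit + 1e-9, (crit[-1] + crit[-length(crit)]) / 2)
  for (t in probes) {
    betti <- betti_rips(d, t)
    expect_equal(bars_alive(b7$h0, t), unname(betti["b0"]))
    expect_equal(bars_alive(b7$h1, t), unname(betti["b1"]))
    expect_equal(bars_alive(b7$h2, t), unname(betti["b2"]))
  }
})

test_that("barcodes are exactly rigid-motion and reflection invariant", {
  set.seed(45)
  xyz <- matrix(rnorm(12 * 3, sd = 3), 12, 3)
  b0 <- persistent_homology(xyz, max_radius = 20)
  motion <- structloc:::random_rigid_motion(6)
  b1 <- persistent_homology(structloc:::apply_rigid(xyz, motion),
                            max_radius = 20)
  mir <- xyz
  mir[, 2] <- -mir[, 2]
  b2 <- persistent_homology(mir, max_radius = 20)
  for (h in c("h0", "h1", "h2")) {
    expect_equal(b0[[h]], b1[[h]], tolerance = 1e-9)
    expect_equal(b0[[h]], b2[[h]], tolerance = 1e-9)
  }
})

test_that("barcode statistics fill the 34-slot layout and recount
           endpoints", {
  # slot arithmetic: 3 counts + 12 birth bins + 12 death bins + 3 + 3 + 1
  expect_equal(3 + 12 + 12 + 3 + 3 + 1, 34)

  far <- cbind(c(0, 100, 200), 0, 0)
  v <- ph_features(persistent_homology(far, max_radius = 16))
  expect_length(v, 34L)
  expect_equal(unname(v["h0_count"]), 3)
  expect_equal(unname(v["h1_count"]), 0)
  expect_true(all(v[grep("^h1_|^h2_", names(v))] == 0))
  expect_equal(unname(v["total_count"]), 3)
  # infinite deaths capped at the filtration maximum
  expect_equal(unname(v["h0_max_death"]), 16)
  expect_equal(unname(v["h0_death_bin4"]), 3)

  set.seed(46)
  xyz <- matrix(rnorm(15 * 3, sd = 4), 15, 3)
  b <- persistent_homology(xyz, max_radius = 16)
  v2 <- ph_features(b)
  bins <- c(0, 4, 8, 12, 16)
  for (h in 0:2) {
    iv <- b[[paste0("h", h)]]
    if (nrow(iv) == 0) next
    births <- iv[, "birth"]
    for (k in 1:4) {
      lo <- bins[k]; hi <- bins[k + 1]
      brute <- sum(births >= lo & (births < hi | (k == 4 & births <= hi)))
      expect_equal(unname(v2[paste0("h", h, "_birth_bin", k)]), brute)
    }
    expect_equal(unname(v2[paste0("h", h, "_min_birth")]), min(births))
  }
})
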