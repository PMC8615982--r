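# Contact histogram, dihedral transforms, sub-structures, codebook,
# frequencies.

test_that("contact descriptor bins collinear CA distances as enumerated", {
  xyz <- cbind(c(0, 3.8, 7.6), 0, 0)
  p <- mk_structure(xyz, aa = "A")
  v <- contact_descriptor(p)
  expect_length(v, 1680L)
  # all three pairwise distances (3.8, 3.8, 7.6) fall in bin 1 ([0,8)) of AA
  expect_equal(unname(v["AA_bin1"]), 3)
  expect_equal(sum(v), 3)

  # distances at or beyond 64 A are discarded, not clipped
  far <- mk_structure(cbind(c(0, 70), 0, 0))
  expect_equal(sum(contact_descriptor(far)), 0)
  edge <- mk_structure(cbind(c(0, 63.9), 0, 0))
  expect_equal(unname(contact_descriptor(edge)["AA_bin8"]), 1)

  expect_error(contact_descriptor(mk_structure(cbind(0, 0, 0))),
               "standard residues")
})

test_that("contact totals match an independent double loop on random structures", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 25
    xyz <- matrix(rnorm(n * 3, sd = 12), n, 3)
    aa <- sample(structloc::AA20, n, replace = TRUE)
    p <- mk_structure(xyz, aa = aa)
    v <- contact_descriptor(p)
    count <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 64) count <- count + 1L
    }
    expect_equal(sum(v), count)
    # spot-check one cell against brute force
    cell_bin <- 2L
    pair <- sort(match(aa[c(1, 2)], structloc::AA20))
    brute <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      ij <- sort(match(aa[c(i, j)], structloc::AA20))
      if (all(ij == pair) && d >= 8 && d < 16) brute <- brute + 1L
    }
    nm <- paste0(structloc::AA20[pair[1]], structloc::AA20[pair[2]],
                 "_bin", cell_bin)
    expect_equal(unname(v[nm]), brute)
  }
})

test_that("dihedral series is a signed torsion, reversal-invariant and
           mirror-antisymmetric", {
  set.seed(3)
  pts <- lapply(1:4, function(i) rnorm(3, sd = 2))
  t_fwd <- structloc:::torsion_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  t_rev <- structloc:::torsion_angle(pts[[4]], pts[[3]], pts[[2]], pts[[1]])
  expect_equal(t_fwd, t_rev, tolerance = 1e-9)
  mir <- lapply(pts, function(v) c(-v[1], v[2], v[3]))
  t_mir <- structloc:::torsion_angle(mir[[1]], mir[[2]], mir[[3]], mir[[4]])
  expect_equal(t_mir, -t_fwd, tolerance = 1e-9)

  # rigid-motion invariance of the full series
  h <- make_segment("helix", 15)
  s0 <- dihedral_series(h)
  s1 <- dihedral_series(rotate_structure(h, seed = 8))
  expect_equal(s0$phi, s1$phi, tolerance = 1e-6)
  expect_equal(s0$psi, s1$psi, tolerance = 1e-6)

  # single residue: empty series
  empty <- suppressWarnings(dihedral_series(make_segment("helix", 1)))
  expect_length(empty$phi, 0)
  expect_length(empty$psi, 0)
})

test_that("dihedral features: 30 values, centering kills constants, wavelet
           energies normalize", {
  v0 <- suppressWarnings(dihedral_features(list(phi = numeric(0),
                                                psi = numeric(0))))
  expect_length(v0, 30L)
  expect_true(all(v0 == 0))

  const <- dihedral_features(list(phi = rep(-57, 40), psi = rep(-47, 40)))
  expect_length(const, 30L)
  expect_true(all(abs(const[1:8]) < 1e-9))   # phi Fourier magnitudes
  expect_true(all(abs(const[16:23]) < 1e-9)) # psi Fourier magnitudes

  set.seed(6)
  vr <- dihedral_features(list(phi = runif(50, -180, 180),
                               psi = runif(33, -180, 180)))
  expect_equal(sum(vr[9:15]), 1, tolerance = 1e-9)
  expect_equal(sum(vr[24:30]), 1, tolerance = 1e-9)
})

test_that("sub-structure windows follow the 10x10/step-5 enumeration", {
  expect_equal(nrow(extract_substructures(make_segment("helix", 9))$reps), 0L)

  # length 10: single candidate window at (0, 0)
  h10 <- make_segment("helix", 10)
  s10 <- extract_substructures(h10)
  expect_equal(nrow(s10$reps), 1L)
  expect_equal(s10$windows$row_off, 0L)
  d <- as.matrix(dist(structloc:::ca_coords(h10)))
  expect_lt(mean(d), 15) # kept because compact
  expect_equal(s10$mean_dist, mean(d))

  # kept set matches a brute-force scan of all candidate windows
  h20 <- make_segment("helix", 20)
  s20 <- extract_substructures(h20)
  k <- length(seq(0, 10, by = 5)) # offsets 0,5,10
  d20 <- as.matrix(dist(structloc:::ca_coords(h20)))
  cand <- expand.grid(i = seq(0, 10, 5), j = seq(0, 10, 5))
  cand <- cand[cand$i <= cand$j, ]
  expect_equal(nrow(cand), k * (k + 1) / 2) # upper triangle incl diagonal
  keep <- mapply(function(i, j) {
    mean(d20[(i + 1):(i + 10), (j + 1):(j + 10)]) < 15
  }, cand$i, cand$j)
  expect_equal(nrow(s20$reps), sum(keep))
  for (r in seq_len(nrow(s20$reps))) {
    i <- s20$windows$row_off[r]; j <- s20$windows$col_off[r]
    expect_lt(mean(d20[(i + 1):(i + 10), (j + 1):(j + 10)]), 15)
  }

  # fully compact cloud (radius ~4 A): every candidate window kept
  set.seed(15)
  blob <- mk_structure(matrix(rnorm(20 * 3, sd = 2), 20, 3))
  expect_equal(nrow(extract_substructures(blob)$reps), k * (k + 1) / 2)

  # closed-form candidate count on a larger chain, vs brute force
  L <- 37
  offs <- seq(0, L - 10, by = 5)
  brute <- sum(outer(offs, offs, function(a, b) a <= b))
  expect_equal(brute, length(offs) * (length(offs) + 1) / 2)

  # rep layout: 100 distances row-major + AAC summing to 1
  expect_equal(ncol(s10$reps), 120L)
  expect_equal(unname(s10$reps[1, 1:100]), as.numeric(t(d)))
  expect_equal(sum(s10$reps[1, 101:120]), 1, tolerance = 1e-9)
})

test_that("codebook clustering and frequency assignment match brute force", {
  # one protein, one sub-structure -> one centroid equal to its rep
  h10 <- make_segment("helix", 10)
  s10 <- extract_substructures(h10)
  cb1 <- build_codebook(list(s10), local_t = 5, global_t = 5)
  expect_equal(nrow(cb1$centroids), 1L)
  expect_equal(unname(cb1$centroids[1, ]), unname(s10$reps[1, ]))

  # two tight groups separated far beyond global_t -> exactly 2 centroids
  set.seed(12)
  g1 <- matrix(rnorm(5 * 120, 0, 0.1), 5, 120)
  g2 <- matrix(rnorm(5 * 120, 500, 0.1), 5, 120)
  fake <- structure(list(reps = rbind(g1, g2),
                         centroids = matrix(0, 10, 3),
                         mean_dist = rep(1, 10),
                         windows = data.frame(row_off = 0:9, col_off = 0:9)),
                    class = "substructure_set")
  cb2 <- build_codebook(list(fake), local_t = 10, global_t = 40)
  expect_equal(nrow(cb2$centroids), 2L)
  means <- rbind(colMeans(g1), colMeans(g2))
  ord <- order(cb2$centroids[, 1])
  expect_equal(unname(cb2$centroids[ord, ]), unname(means[order(means[, 1]), ]),
               tolerance = 1e-9)
  # centroids stay inside pooled per-dimension bounds
  pooled <- rbind(g1, g2)
  expect_true(all(t(cb2$centroids) >= apply(pooled, 2, min) - 1e-12))
  expect_true(all(t(cb2$centroids) <= apply(pooled, 2, max) + 1e-12))

  # frequencies: nearest-centroid proportions equal exhaustive comparison
  set.seed(13)
  reps <- matrix(rnorm(6 * 120), 6, 120)
  subs <- structure(list(reps = reps, centroids = matrix(0, 6, 3),
                         mean_dist = rep(1, 6),
                         windows = data.frame(row_off = 0:5, col_off = 0:5)),
                    class = "substructure_set")
  cents <- matrix(rnorm(3 * 120), 3, 120)
  cb <- structure(list(centroids = cents, params = list()),
                  class = "substructure_codebook")
  freq <- substructure_frequency(subs, cb)
  brute <- table(factor(apply(reps, 1, function(r) {
    which.min(colSums((t(cents) - r)^2))
  }), levels = 1:3)) / 6
  expect_equal(unname(freq), as.numeric(brute))
  expect_equal(sum(freq), 1, tolerance = 1e-9)

  # zero sub-structures -> zero vector
  empty <- extract_substructures(make_segment("helix", 9))
  expect_true(all(substructure_frequency(empty, cb) == 0))
})

test_that("physical descriptors are invariant to rigid motions", {
  set.seed(14)
  ds <- small_dataset()
  p <- ds$structures[[3]]
  q <- rotate_structure(p, seed = 99)
  expect_equal(contact_descriptor(p), contact_descriptor(q))
  s0 <- extract_substructures(p)
  s1 <- extract_substructures(q)
  expect_equal(s0$reps, s1$reps, tolerance = 1e-6)
  expect_equal(s0$windows, s1$windows)
})
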