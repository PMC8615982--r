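# Shared fixtures and independent oracles, all built in code.

# protein_structure from a bare CA coordinate matrix
mk_structure <- function(xyz, aa = "A", id = "fixture") {
  n <- nrow(xyz)
  aa <- rep_len(aa, n)
  res <- data.frame(
    aa = aa, seq_num = seq_len(n),
    ca_x = xyz[, 1], ca_y = xyz[, 2], ca_z = xyz[, 3],
    n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
    c_x = NA_real_, c_y = NA_real_, c_z = NA_real_,
    stringsAsFactors = FALSE
  )
  structloc:::new_protein_structure(id, "A", res)
}

# apply a seeded random rotation + translation to every atom of a structure
rotate_structure <- function(p, seed = 1L, reflect = FALSE) {
  motion <- structloc:::random_rigid_motion(seed)
  R <- motion$R
  if (reflect) R[, 1] <- -R[, 1]
  q <- p
  for (pref in c("ca", "n", "c")) {
    cols <- paste0(pref, c("_x", "_y", "_z"))
    m <- as.matrix(p$residues[, cols])
    ok <- !is.na(m[, 1])
    m[ok, ] <- m[ok, , drop = FALSE] %*% t(R) +
      matrix(motion$t, sum(ok), 3, byrow = TRUE)
    q$residues[, cols] <- m
  }
  q
}

# writhe of a polygonal curve by adaptive numerical double integration of
# the Gauss linking integrand over every non-adjacent edge pair
writhe_quadrature <- function(xyz) {
  n <- nrow(xyz)
  tot <- 0
  for (a in 1:(n - 3)) {
    for (b in (a + 2):(n - 1)) {
      p1 <- xyz[a, ]; d1 <- xyz[a + 1, ] - p1
      p2 <- xyz[b, ]; d2 <- xyz[b + 1, ] - p2
      cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
              d1[3] * d2[1] - d1[1] * d2[3],
              d1[1] * d2[2] - d1[2] * d2[1])
      f_outer <- Vectorize(function(t1) {
        stats::integrate(Vectorize(function(t2) {
          r <- (p1 + t1 * d1) - (p2 + t2 * d2)
          sum(cr * r) / sum(r^2)^1.5
        }), 0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
      })
      tot <- tot + 2 * stats::integrate(f_outer, 0, 1, rel.tol = 1e-10,
                                        abs.tol = 1e-12)$value / (4 * pi)
    }
  }
  tot
}

# GF(2) rank by Gaussian elimination
rank_gf2 <- function(M) {
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  M <- M %% 2
  r <- 0L
  for (j in seq_len(ncol(M))) {
    piv <- which(M[, j] == 1 & seq_len(nrow(M)) > r)
    if (!length(piv)) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    for (i in which(M[, j] == 1)) {
      if (i != r) M[i, ] <- (M[i, ] + M[r, ]) %% 2
    }
  }
  r
}

# Betti numbers (dims 0..2) of the Rips complex at scale t, by explicit
# simplex enumeration and boundary-matrix ranks over GF(2)
betti_rips <- function(dmat, t) {
  n <- nrow(dmat)
  verts <- seq_len(n)
  edges <- list(); tris <- list(); tets <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (dmat[i, j] <= t) edges[[length(edges) + 1L]] <- c(i, j)
  }
  ek <- function(i, j) paste(i, j)
  eset <- vapply(edges, function(e) ek(e[1], e[2]), character(1))
  has_edge <- function(i, j) ek(i, j) %in% eset
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (has_edge(i, j) && has_edge(i, k) && has_edge(j, k)) {
      tris[[length(tris) + 1L]] <- c(i, j, k)
    }
  }
  if (n >= 4) for (i in 1:(n - 3)) for (j in (i + 1):(n - 2)) {
    for (k in (j + 1):(n - 1)) for (l in (k + 1):n) {
      if (has_edge(i, j) && has_edge(i, k) && has_edge(i, l) &&
          has_edge(j, k) && has_edge(j, l) && has_edge(k, l)) {
        tets[[length(tets) + 1L]] <- c(i, j, k, l)
      }
    }
  }
  bd <- function(simplices, faces, face_key) {
    if (!length(simplices)) {
      return(matrix(0L, length(faces), 0L))
    }
    M <- matrix(0L, length(faces), length(simplices))
    fk <- vapply(faces, face_key, character(1))
    for (c_ in seq_along(simplices)) {
      s <- simplices[[c_]]
      for (drop in seq_along(s)) {
        M[match(face_key(s[-drop]), fk), c_] <- 1L
      }
    }
    M
  }
  key <- function(v) paste(v, collapse = " ")
  d1 <- bd(edges, as.list(verts), key)
  d2 <- bd(tris, edges, key)
  d3 <- bd(tets, tris, key)
  r1 <- rank_gf2(d1); r2 <- rank_gf2(d2); r3 <- rank_gf2(d3)
  c(b0 = n - r1,
    b1 = length(edges) - r1 - r2,
    b2 = length(tris) - r2 - r3)
}

# number of barcode intervals alive at scale t (born at or before, dying after)
bars_alive <- function(iv, t) {
  if (nrow(iv) == 0L) return(0L)
  sum(iv[, "birth"] <= t & iv[, "death"] > t)
}

# small synthetic dataset shared across test files, generated once
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(synth_spec(n_per_class = 6L, seed = 11L))
    }
    cache
  }
})
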