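# Physical descriptors: CA contact-distance histogram per amino-acid pair,
# dihedral-angle curve transforms, and compact sub-structure frequencies
# against a two-step clustered codebook.

#' Contact-matrix descriptor
#'
#' Histograms all unordered CA-CA distances between standard residues into
#' 8 distance bins of 8 Angstrom covering \[0, 64); distances >= 64 are
#' discarded. One histogram per unordered amino-acid pair (210 pairs in
#' canonical alphabetical order), flattened bin-major to length 1680.
#'
#' @param p a `protein_structure`.
#' @param n_bins,bin_width histogram geometry (defaults 8 x 8 Angstrom).
#' @return named numeric vector of length `n_bins * 210`, names
#'   `<pair>_bin<k>`.
#' @export
contact_descriptor <- function(p, n_bins = 8L, bin_width = 8) {
  std <- p$residues$aa %in% AA20
  if (sum(std) < 2L) stop("need >= 2 standard residues")
  xyz <- ca_coords(p)[std, , drop = FALSE]
  aa <- match(p$residues$aa[std], AA20)
  d <- as.matrix(dist(xyz))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[iu]
  bin <- floor(dv / bin_width)
  ok <- bin < n_bins
  ai <- pmin(aa[iu[, 1]], aa[iu[, 2]])[ok]
  aj <- pmax(aa[iu[, 1]], aa[iu[, 2]])[ok]
  bin <- bin[ok]
  # pair index in the canonical (i <= j) alphabetical ordering
  pid <- (ai - 1) * 21 - (ai - 1) * ai / 2 + (aj - ai + 1)
  counts <- matrix(0L, nrow = n_bins, ncol = 210L)
  if (length(pid)) {
    tab <- table(factor(bin + 1, levels = seq_len(n_bins)),
                 factor(pid, levels = seq_len(210L)))
    counts <- matrix(as.integer(tab), n_bins, 210L)
  }
  # bin-major flattening: the 210 pairs of bin 1, then bin 2, ...
  v <- as.numeric(t(counts))
  names(v) <- paste0(rep(aa_pair_index()$name, times = n_bins), "_bin",
                     rep(seq_len(n_bins), each = 210L))
  v
}

#' Backbone dihedral-angle series
#'
#' Signed torsions in degrees: phi(i) from C(i-1), N(i), CA(i), C(i); psi(i)
#' from N(i), CA(i), C(i), N(i+1). Undefined angles (segment boundaries,
#' missing N/C atoms) are skipped, and angles never span a chain break.
#'
#' @param p a `protein_structure`.
#' @param max_link chain-break threshold passed to [chain_break_segments()].
#' @return list with numeric vectors `phi` and `psi` (degrees, in
#'   \[-180, 180\]).
#' @export
dihedral_series <- function(p, max_link = 4.5) {
  res <- p$residues
  segs <- chain_break_segments(p, max_link)
  phi <- numeric(0)
  psi <- numeric(0)
  n_at <- function(i) c(res$n_x[i], res$n_y[i], res$n_z[i])
  ca_at <- function(i) c(res$ca_x[i], res$ca_y[i], res$ca_z[i])
  c_at <- function(i) c(res$c_x[i], res$c_y[i], res$c_z[i])
  for (seg in segs) {
    if (length(seg) < 2L) next
    for (k in seq_along(seg)) {
      i <- seg[k]
      if (k > 1L) {
        prev <- seg[k - 1L]
        pts <- list(c_at(prev), n_at(i), ca_at(i), c_at(i))
        if (!anyNA(unlist(pts))) {
          phi <- c(phi, torsion_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]))
        }
      }
      if (k < length(seg)) {
        nxt <- seg[k + 1L]
        pts <- list(n_at(i), ca_at(i), c_at(i), n_at(nxt))
        if (!anyNA(unlist(pts))) {
          psi <- c(psi, torsion_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]))
        }
      }
    }
  }
  if (!length(phi) && !length(psi)) {
    warning("no computable dihedral angles")
  }
  list(phi = phi, psi = psi)
}

# Linear resampling of a series to a fixed length.
resample_series <- function(x, len) {
  if (length(x) == 1L) return(rep(x, len))
  stats::approx(seq_along(x), x, n = len)$y
}

# Haar discrete wavelet transform (pyramid algorithm); returns the list of
# detail coefficient vectors per level plus the final approximation.
haar_dwt <- function(x) {
  stopifnot(length(x) >= 2, bitwAnd(length(x), length(x) - 1L) == 0L)
  details <- list()
  a <- x
  while (length(a) > 1L) {
    even <- a[seq(2, length(a), 2)]
    odd <- a[seq(1, length(a), 2)]
    details[[length(details) + 1L]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(details = details, approx = a)
}

# 15 features of one dihedral curve: magnitudes of DFT coefficients 1..8 of
# the mean-centered length-64 resampled series, plus the 7 relative wavelet
# energies (6 Haar detail levels + approximation, normalized to sum 1).
curve_features <- function(x, resample_len = 64L) {
  if (length(x) == 0L) return(numeric(15L))
  if (length(x) < 8L) x <- c(x, numeric(8L - length(x)))
  y <- resample_series(x, resample_len)
  y <- y - mean(y)
  ft <- Mod(stats::fft(y))[2:9]
  w <- haar_dwt(y)
  energies <- c(vapply(w$details, function(d) sum(d^2), numeric(1)),
                sum(w$approx^2))
  tot <- sum(energies)
  rel <- if (tot > 0) energies / tot else numeric(length(energies))
  c(ft, rel)
}

#' Frequency-domain and wavelet features of the dihedral curves
#'
#' 15 features per curve (8 Fourier magnitudes of the mean-centered,
#' length-64 resampled series; 7 relative wavelet-level energies from a Haar
#' decomposition), phi then psi, giving 30 values.
#'
#' @param s output of [dihedral_series()].
#' @return named numeric vector of length 30.
#' @export
dihedral_features <- function(s) {
  if (!length(s$phi) && !length(s$psi)) {
    warning("empty dihedral series; returning zeros")
  }
  v <- c(curve_features(s$phi), curve_features(s$psi))
  names(v) <- paste0(rep(c("phi", "psi"), each = 15L), "_",
                     rep(c(paste0("fft", 1:8), paste0("wav", 1:7)), 2L))
  v
}

#' Extract compact sub-structures
#'
#' Slides a 10 x 10 window over the CA distance matrix at row/column offsets
#' that are multiples of `step`, keeping windows whose mean distance is below
#' `threshold`. Off-diagonal windows (discontiguous residue stretches) are
#' included; mirrored duplicates are dropped by requiring row offset <=
#' column offset. Each kept window is represented by its 100 distance
#' entries (row-major) plus the 20-dim amino-acid composition of the covered
#' residues, and by the centroid of their CA coordinates.
#'
#' @param p a `protein_structure`.
#' @param threshold mean-distance cutoff in Angstrom (default 15).
#' @param window,step window size and stride in residues (defaults 10 and 5).
#' @return object of class `substructure_set`: list with `reps` (matrix,
#'   one row per sub-structure, 120 columns), `centroids` (n x 3),
#'   `mean_dist`, `windows` (data.frame row_off, col_off).
#' @export
extract_substructures <- function(p, threshold = 15, window = 10L,
                                  step = 5L) {
  n <- nrow(p$residues)
  empty <- structure(list(
    reps = matrix(numeric(0), 0, window * window + 20L),
    centroids = matrix(numeric(0), 0, 3),
    mean_dist = numeric(0),
    windows = data.frame(row_off = integer(0), col_off = integer(0))),
    class = "substructure_set")
  if (n < window) return(empty)
  xyz <- ca_coords(p)
  d <- as.matrix(dist(xyz))
  offsets <- seq(0L, n - window, by = step)
  reps <- list()
  cents <- list()
  md <- numeric(0)
  rows <- integer(0)
  cols <- integer(0)
  for (i in offsets) {
    for (j in offsets) {
      if (i > j) next
      ri <- (i + 1L):(i + window)
      rj <- (j + 1L):(j + window)
      sub <- d[ri, rj, drop = FALSE]
      m <- mean(sub)
      if (m < threshold) {
        covered <- sort(unique(c(ri, rj)))
        aa <- p$residues$aa[covered]
        aac <- as.numeric(table(factor(aa, levels = AA20)))
        if (sum(aac) > 0) aac <- aac / sum(aac)
        reps[[length(reps) + 1L]] <- c(as.numeric(t(sub)), aac)
        cents[[length(cents) + 1L]] <-
          colMeans(xyz[covered, , drop = FALSE])
        md <- c(md, m)
        rows <- c(rows, i)
        cols <- c(cols, j)
      }
    }
  }
  if (!length(reps)) return(empty)
  structure(list(reps = do.call(rbind, reps),
                 centroids = do.call(rbind, cents),
                 mean_dist = md,
                 windows = data.frame(row_off = rows, col_off = cols)),
            class = "substructure_set")
}

# Agglomerative clustering (average linkage, Euclidean) cut at height h;
# returns the matrix of cluster mean vectors.
cluster_centroids <- function(reps, h) {
  if (nrow(reps) == 1L) return(reps)
  hc <- hclust(dist(reps), method = "average")
  cl <- cutree(hc, h = h)
  t(vapply(split(seq_len(nrow(reps)), cl),
           function(ix) colMeans(reps[ix, , drop = FALSE]),
           numeric(ncol(reps))))
}

#' Build the sub-structure codebook by two-step hierarchical clustering
#'
#' Step 1 clusters each protein's sub-structure representations individually
#' (average linkage, Euclidean, tree cut at `local_t`) and keeps the cluster
#' means. Step 2 clusters the pooled per-protein centroids cut at
#' `global_t`; the resulting means are the codebook.
#'
#' @param sub_list list of `substructure_set`, one per protein.
#' @param local_t,global_t cut heights for the two clustering steps.
#' @return object of class `substructure_codebook`: list with `centroids`
#'   matrix and `params`.
#' @export
build_codebook <- function(sub_list, local_t = 10, global_t = 20) {
  locals <- list()
  for (s in sub_list) {
    if (nrow(s$reps) == 0L) next
    locals[[length(locals) + 1L]] <- cluster_centroids(s$reps, local_t)
  }
  if (!length(locals)) stop("no sub-structures in any protein")
  pooled <- do.call(rbind, locals)
  centroids <- cluster_centroids(pooled, global_t)
  structure(list(centroids = centroids,
                 params = list(linkage = "average", metric = "euclidean",
                               local_t = local_t, global_t = global_t)),
            class = "substructure_codebook")
}

#' Sub-structure frequency descriptor
#'
#' Assigns each of a protein's sub-structures to the nearest codebook
#' centroid (Euclidean; ties broken by lowest centroid index) and returns
#' the vector of assignment proportions.
#'
#' @param subs a `substructure_set` for one protein.
#' @param codebook a `substructure_codebook`.
#' @return numeric vector, length = number of centroids; sums to 1 when the
#'   protein has at least one sub-structure, otherwise all zeros.
#' @export
substructure_frequency <- function(subs, codebook) {
  k <- nrow(codebook$centroids)
  if (k == 0L) stop("empty codebook")
  out <- numeric(k)
  names(out) <- paste0("cluster", seq_len(k))
  if (nrow(subs$reps) == 0L) return(out)
  for (r in seq_len(nrow(subs$reps))) {
    d2 <- colSums((t(codebook$centroids) - subs$reps[r, ])^2)
    out[which.min(d2)] <- out[which.min(d2)] + 1
  }
  out / nrow(subs$reps)
}
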