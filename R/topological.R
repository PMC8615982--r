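# Topological descriptors: generalized Gauss integrals of the backbone
# curve, and persistent-homology barcode statistics of the CA point cloud.

#' Generalized Gauss-integral descriptor (31 values)
#'
#' Treats the longest continuous backbone segment as a polygonal space
#' curve through its CA atoms and computes generalized Gauss integrals of
#' chord-pattern order up to 3. Component 1 is the writhe I(1,2), the exact
#' pairwise double sum of signed solid-angle contributions over edge pairs;
#' component 2 is its absolute-value counterpart (average crossing number);
#' components 3-14 are the order-2 integrals for the three chord patterns
#' (12)(34), (13)(24), (14)(23) in all four signed/absolute factor
#' combinations; components 15-29 are the 15 signed order-3 perfect
#' matchings of six edge positions; components 30-31 are fully-absolute
#' variants of the sequential (12)(34)(56) and fully crossing (14)(25)(36)
#' patterns.
#'
#' @param p a `protein_structure`.
#' @param max_link chain-break threshold (see [chain_break_segments()]).
#' @param max_vertices curves longer than this are uniformly subsampled
#'   before integration (default 150) to bound the order-3 cost.
#' @return named numeric vector of length 31.
#' @export
gauss_integrals <- function(p, max_link = 4.5, max_vertices = 150L) {
  segs <- chain_break_segments(p, max_link)
  seg <- segs[[which.max(lengths(segs))]]
  nm <- c("writhe", "acn",
          paste0(rep(c("o2_1234", "o2_1324", "o2_1423"), each = 4), "_",
                 rep(c("ss", "as", "sa", "aa"), 3)),
          paste0("o3_", apply(.order3_patterns(), 2, paste0, collapse = "")),
          "o3_123456_abs", "o3_142536_abs")
  if (length(seg) < 4L) {
    warning("longest segment shorter than 4 residues; zero Gauss descriptor")
    v <- numeric(31L)
    names(v) <- nm
    return(v)
  }
  xyz <- ca_coords(p)[seg, , drop = FALSE]
  if (nrow(xyz) > max_vertices) {
    keep <- unique(round(seq(1, nrow(xyz), length.out = max_vertices)))
    xyz <- xyz[keep, , drop = FALSE]
  }
  v <- gauss_integrals_cpp(xyz)
  names(v) <- nm
  v
}

.order3_patterns <- function() {
  matrix(c(1, 2, 3, 4, 5, 6,  1, 2, 3, 5, 4, 6,  1, 2, 3, 6, 4, 5,
           1, 3, 2, 4, 5, 6,  1, 3, 2, 5, 4, 6,  1, 3, 2, 6, 4, 5,
           1, 4, 2, 3, 5, 6,  1, 4, 2, 5, 3, 6,  1, 4, 2, 6, 3, 5,
           1, 5, 2, 3, 4, 6,  1, 5, 2, 4, 3, 6,  1, 5, 2, 6, 3, 4,
           1, 6, 2, 3, 4, 5,  1, 6, 2, 4, 3, 5,  1, 6, 2, 5, 3, 4),
         nrow = 6)
}

#' Persistent homology of the CA point cloud
#'
#' Vietoris-Rips filtration on the CA coordinates up to `max_radius`,
#' homology dimensions 0-2 (components, rings, cavities). Growing equal
#' balls around the CA atoms and linking them when they touch is exactly
#' this filtration. The single essential connected component has death
#' `Inf`.
#'
#' @param p a `protein_structure` (or an n x 3 coordinate matrix).
#' @param max_radius filtration cap in Angstrom (default 16).
#' @return object of class `barcodes`: list `h0`, `h1`, `h2` of two-column
#'   matrices (birth, death), sorted by birth.
#' @export
persistent_homology <- function(p, max_radius = 16) {
  xyz <- if (is.matrix(p)) p else ca_coords(p)
  if (nrow(xyz) < 2L) stop("need >= 2 points")
  d <- as.matrix(dist(xyz))
  out <- rips_persistence_cpp(d, max_radius, max_dim = 2L)
  for (h in seq_along(out)) {
    iv <- out[[h]]
    out[[h]] <- iv[order(iv[, "birth"], iv[, "death"]), , drop = FALSE]
  }
  structure(out, class = "barcodes", max_radius = max_radius)
}

#' @export
print.barcodes <- function(x, ...) {
  cat("barcodes: ", nrow(x$h0), " H0, ", nrow(x$h1), " H1, ",
      nrow(x$h2), " H2 intervals (max radius ",
      attr(x, "max_radius"), " A)\n", sep = "")
  invisible(x)
}

#' Barcode statistics descriptor (34 values)
#'
#' Per homology dimension (0, 1, 2): interval count (3 values), birth
#' counts in the radius bins (3 x 4 = 12), death counts in the radius bins
#' (12), minimum birth (3), maximum finite death (3); plus the total
#' interval count (1). Infinite deaths are capped at the filtration maximum
#' before binning and maxima; empty dimensions contribute zeros.
#'
#' @param b a `barcodes` object.
#' @param bins radius bin edges in Angstrom (default `c(0, 4, 8, 12, 16)`).
#' @return named numeric vector of length 34.
#' @export
ph_features <- function(b, bins = c(0, 4, 8, 12, 16)) {
  stopifnot(inherits(b, "barcodes"), length(bins) == 5L)
  cap <- max(bins)
  vals <- c()
  nms <- c()
  nb <- length(bins) - 1L
  total <- 0
  for (h in 0:2) {
    iv <- b[[paste0("h", h)]]
    birth <- iv[, "birth"]
    death <- pmin(iv[, "death"], cap)
    total <- total + nrow(iv)
    cnt <- nrow(iv)
    binned <- function(x) {
      tabulate(findInterval(pmin(pmax(x, bins[1]), cap), bins,
                            rightmost.closed = TRUE), nbins = nb)
    }
    bh <- if (cnt) binned(birth) else numeric(nb)
    dh <- if (cnt) binned(death) else numeric(nb)
    vals <- c(vals, cnt, bh, dh,
              if (cnt) min(birth) else 0,
              if (cnt) max(death) else 0)
    nms <- c(nms, paste0("h", h, "_count"),
             paste0("h", h, "_birth_bin", seq_len(nb)),
             paste0("h", h, "_death_bin", seq_len(nb)),
             paste0("h", h, "_min_birth"), paste0("h", h, "_max_death"))
  }
  vals <- c(vals, total)
  nms <- c(nms, "total_count")
  names(vals) <- nms
  vals
}
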