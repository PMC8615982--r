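# Surface-residue detection by 12-sector occupancy and the 42-dim surface
# composition + chemical-property expectation descriptor.

#' Default 22-property amino-acid table
#'
#' 20 rows (amino acids, alphabetical one-letter codes) x 22 named numeric
#' properties: published scales (Kyte-Doolittle hydropathy, Hopp-Woods
#' hydrophilicity, Grantham polarity, net charge at pH 7, Zamyatnin residue
#' volume, average residue mass, isoelectric point, Chou-Fasman
#' helix/sheet/turn propensities, Zimmerman bulkiness) completed with
#' explicitly defined chargeability and indicator properties. Replaceable
#' via [read_property_table()].
#'
#' @return 20 x 22 numeric matrix, rownames [AA20].
#' @export
default_property_table <- function() {
  # order: A C D E F G H I K L M N P Q R S T V W Y
  hydropathy_kd <- c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
                     1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)
  hydrophilicity_hw <- c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0,
                         -1.8, -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5,
                         -3.4, -2.3)
  polarity_grantham <- c(8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3,
                         4.9, 5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9,
                         5.4, 6.2)
  net_charge_ph7 <- c(0, 0, -1, -1, 0, 0, 0.1, 0, 1, 0,
                      0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  chargeability <- abs(net_charge_ph7)
  volume_a3 <- c(88.6, 108.5, 111.1, 138.4, 189.9, 60.1, 153.2, 166.7,
                 168.6, 166.7, 162.9, 114.1, 112.7, 143.8, 173.4, 89.0,
                 116.1, 140.0, 227.8, 193.6)
  residue_mass <- c(71.08, 103.14, 115.09, 129.12, 147.18, 57.05, 137.14,
                    113.16, 128.17, 113.16, 131.19, 114.10, 97.12, 128.13,
                    156.19, 87.08, 101.10, 99.13, 186.21, 163.18)
  isoelectric_point <- c(6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02,
                         9.74, 5.98, 5.74, 5.41, 6.30, 5.65, 10.76, 5.68,
                         5.60, 5.96, 5.89, 5.66)
  helix_propensity <- c(1.42, 0.70, 1.01, 1.51, 1.13, 0.57, 1.00, 1.08,
                        1.16, 1.21, 1.45, 0.67, 0.57, 1.11, 0.98, 0.77,
                        0.83, 1.06, 1.08, 0.69)
  sheet_propensity <- c(0.83, 1.19, 0.54, 0.37, 1.38, 0.75, 0.87, 1.60,
                        0.74, 1.30, 1.05, 0.89, 0.55, 1.10, 0.93, 0.75,
                        1.19, 1.70, 1.37, 1.47)
  turn_propensity <- c(0.66, 1.19, 1.46, 0.74, 0.60, 1.56, 0.95, 0.47,
                       1.01, 0.59, 0.60, 1.56, 1.52, 0.98, 0.95, 1.43,
                       0.96, 0.50, 0.96, 1.14)
  bulkiness <- c(11.50, 13.46, 11.68, 13.57, 19.80, 3.40, 13.69, 21.40,
                 15.71, 21.40, 16.25, 12.82, 17.43, 14.45, 14.28, 9.47,
                 15.77, 21.57, 21.67, 18.03)
  ind <- function(members) as.numeric(AA20 %in% members)
  tab <- cbind(
    hydropathy_kd = hydropathy_kd,
    hydrophilicity_hw = hydrophilicity_hw,
    polarity_grantham = polarity_grantham,
    net_charge_ph7 = net_charge_ph7,
    chargeability = chargeability,
    volume_a3 = volume_a3,
    residue_mass = residue_mass,
    isoelectric_point = isoelectric_point,
    helix_propensity = helix_propensity,
    sheet_propensity = sheet_propensity,
    turn_propensity = turn_propensity,
    bulkiness = bulkiness,
    aromatic = ind(c("F", "W", "Y", "H")),
    aliphatic = ind(c("A", "I", "L", "V")),
    polar_uncharged = ind(c("S", "T", "N", "Q", "Y")),
    sulfur_containing = ind(c("C", "M")),
    hydroxyl_containing = ind(c("S", "T", "Y")),
    amide_containing = ind(c("N", "Q")),
    positively_chargeable = ind(c("R", "K", "H")),
    negatively_chargeable = ind(c("D", "E")),
    small = as.numeric(volume_a3 < 117),
    beta_branched = ind(c("I", "T", "V"))
  )
  rownames(tab) <- AA20
  tab
}

#' Read / write a property table
#'
#' Delimited text: first column the one-letter amino-acid code (all 20
#' required), remaining columns named numeric properties.
#'
#' @param path file path.
#' @export
read_property_table <- function(path) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  aa <- as.character(x[[1]])
  if (!setequal(aa, AA20)) stop("property table must cover the 20 standard amino acids")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("property table contains non-numeric or missing cells")
  rownames(m) <- aa
  m[AA20, , drop = FALSE]
}

#' @rdname read_property_table
#' @param tab 20 x k numeric property matrix.
#' @export
write_property_table <- function(tab, path) {
  write.table(data.frame(aa = rownames(tab), tab, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 12 unit axes through the face centers of a regular dodecahedron
# (= icosahedron vertices): equal solid-angle partition of the sphere by
# nearest axis.
dodecahedron_axes <- function() {
  gr <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, gr), c(0, -1, gr), c(0, 1, -gr), c(0, -1, -gr),
    c(1, gr, 0), c(-1, gr, 0), c(1, -gr, 0), c(-1, -gr, 0),
    c(gr, 0, 1), c(gr, 0, -1), c(-gr, 0, 1), c(-gr, 0, -1)
  )
  v / sqrt(1 + gr^2)
}

# Deterministic orientation frame from the principal axes of the CA cloud.
# Axis signs follow the projection of the farthest-from-centroid point;
# the third axis is the cross product of the first two (right-handed).
principal_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3L) return(diag(3))
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(xc) / n, symmetric = TRUE)
  a1 <- ev$vectors[, 1]
  a2 <- ev$vectors[, 2]
  far <- xc[which.max(rowSums(xc^2)), ]
  if (sum(far * a1) < 0) a1 <- -a1
  if (sum(far * a2) < 0) a2 <- -a2
  a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
          a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  cbind(a1, a2, a3)
}

#' Surface-residue mask by 12-sector occupancy
#'
#' For each residue, neighbors are the other CA atoms within `radius`. The
#' sphere around the residue is divided into 12 equal solid-angle sectors
#' (dodecahedron face axes, nearest-axis assignment) expressed in the
#' structure's principal-axis frame so the mask is invariant to rigid
#' motions. A residue is on the surface iff at least one sector contains no
#' neighbor.
#'
#' @param p a `protein_structure`.
#' @param radius neighbor cutoff in Angstrom (default 12).
#' @return logical vector over residues.
#' @export
surface_residues <- function(p, radius = 12) {
  xyz <- ca_coords(p)
  n <- nrow(xyz)
  if (n == 0L) stop("empty structure")
  frame <- principal_frame(xyz)
  axes <- dodecahedron_axes() %*% t(frame) # axes in structure frame
  d <- as.matrix(dist(xyz))
  out <- logical(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] <= radius & seq_len(n) != i)
    if (length(nb) < 12L) {
      out[i] <- TRUE
      next
    }
    dirs <- sweep(xyz[nb, , drop = FALSE], 2, xyz[i, ])
    dirs <- dirs / sqrt(rowSums(dirs^2))
    sector <- max.col(dirs %*% t(axes), ties.method = "first")
    out[i] <- length(unique(sector)) < 12L
  }
  out
}

#' Surface composition and chemical-property expectation features
#'
#' First 20 entries: amino-acid composition alpha of the surface residues
#' (standard amino acids only). Last 22: for each property i, the
#' expectation f(i) = sum_j alpha_j * p_j(i) of the property over the
#' surface composition.
#'
#' @param p a `protein_structure`.
#' @param properties 20 x 22 property matrix
#'   (default [default_property_table()]).
#' @param radius neighbor cutoff passed to [surface_residues()].
#' @return named numeric vector of length 42.
#' @export
chemical_features <- function(p, properties = default_property_table(),
                              radius = 12) {
  stopifnot(nrow(properties) == 20L)
  surf <- surface_residues(p, radius)
  aa <- p$residues$aa[surf]
  aa <- aa[aa %in% AA20]
  k <- ncol(properties)
  out <- numeric(20L + k)
  names(out) <- c(paste0("surf_", AA20), colnames(properties))
  if (!length(aa)) {
    warning("no standard surface residues; returning zeros")
    return(out)
  }
  alpha <- as.numeric(table(factor(aa, levels = AA20))) / length(aa)
  out[seq_len(20L)] <- alpha
  out[20L + seq_len(k)] <- as.numeric(alpha %*% properties)
  out
}
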