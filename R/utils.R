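#' @useDynLib structloc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate cutree dist hclust predict pt quantile rnorm runif sd var
#' @importFrom utils read.delim write.table
NULL

#' One-letter codes of the 20 standard amino acids
#'
#' Alphabetical order; the canonical feature order used by every
#' composition-based descriptor.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Canonical ordering of the 210 unordered amino-acid pairs (i <= j,
# alphabetical one-letter codes), used to flatten the contact histogram.
aa_pair_index <- function() {
  pairs <- rbind(t(utils::combn(seq_len(20L), 2L)),
                 cbind(seq_len(20L), seq_len(20L)))
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  data.frame(i = pairs[, 1L], j = pairs[, 2L],
             name = paste0(AA20[pairs[, 1L]], AA20[pairs[, 2L]]))
}

#' Signed torsion angle of four points
#'
#' Standard signed dihedral about the b-c axis, returned in degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @keywords internal
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Random rigid motion (rotation + translation) for invariance checks.
random_rigid_motion <- function(rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- rnorm(3, sd = 25)
  list(R = R, t = t)
}

apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% t(motion$R), 2, -motion$t)
}

#' Write a per-protein feature table
#'
#' Delimited text, first column `id`, remaining columns named features.
#'
#' @param x data.frame with an `id` column.
#' @param path output file.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(is.data.frame(x), "id" %in% names(x))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-protein feature table written by [write_feature_table()]
#'
#' @param path input file.
#' @return data.frame with an `id` column (character) and numeric features.
#' @export
read_feature_table <- function(path) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!"id" %in% names(x)) {
    stop("feature table ", path, " has no 'id' column")
  }
  x$id <- as.character(x$id)
  bad <- names(x)[-1][!vapply(x[-1], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric feature columns in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  x
}

# Convert a feature data.frame (id + features) to a numeric matrix with
# rownames = id.
feature_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "id"), drop = FALSE])
  rownames(m) <- x$id
  storage.mode(m) <- "double"
  m
}
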