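#' Read a PDB file into a validated backbone representation
#'
#' Parses ATOM records (first model only, HETATM ignored) via bio3d and
#' reduces them to an ordered per-residue backbone: one-letter amino acid,
#' author residue number, and N/CA/C coordinates. Alternate locations are
#' resolved by highest occupancy, then first encountered. Residues without a
#' CA atom are dropped (with a message). Nonstandard residues are mapped to
#' "X"; they keep their geometry but are excluded from composition-based
#' descriptors downstream.
#'
#' @param path path to a PDB file.
#' @param chain optional one-character chain identifier. When `NULL`, the
#'   chain with the most CA atoms is selected.
#' @param id structure identifier; defaults to the file name without
#'   extension.
#' @return an object of class `protein_structure`: a list with `id`,
#'   `chain_id` and `residues` (data.frame with columns `aa`, `seq_num`,
#'   `ca_x`, `ca_y`, `ca_z`, `n_x`, `n_y`, `n_z`, `c_x`, `c_y`, `c_z`;
#'   N/C coordinates are `NA` when absent).
#' @export
read_pdb_structure <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                    verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)

  # altloc resolution: highest occupancy, ties/NA -> first encountered
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no usable CA atoms in ", path)

  if (is.null(chain)) {
    tab <- table(ca$chain)
    chain <- names(tab)[which.max(tab)]
  } else if (!any(ca$chain == chain)) {
    stop("chain '", chain, "' has no CA atoms in ", path)
  }
  at <- at[at$chain == chain, , drop = FALSE]

  rkey <- paste(at$resno, at$insert, sep = "\r")
  res_order <- unique(rkey[order(at$resno, at$insert)])
  n_all <- length(res_order)

  pick <- function(ele) {
    sub <- at[at$elety == ele, , drop = FALSE]
    m <- match(res_order, paste(sub$resno, sub$insert, sep = "\r"))
    cbind(sub$x[m], sub$y[m], sub$z[m])
  }
  ca_xyz <- pick("CA")
  n_xyz <- pick("N")
  c_xyz <- pick("C")
  first_at <- at[match(res_order, rkey), , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(first_at$resid))
  aa[is.na(aa) | !aa %in% AA20] <- "X"

  keep <- rowSums(is.na(ca_xyz)) == 0L & rowSums(is.finite(ca_xyz)) == 3L
  if (any(!keep)) {
    message(sum(!keep), " residue(s) without CA dropped from ",
            basename(path))
  }
  if (!any(keep)) stop("no usable CA atoms in chain ", chain, " of ", path)

  residues <- data.frame(
    aa = aa[keep],
    seq_num = first_at$resno[keep],
    ca_x = ca_xyz[keep, 1], ca_y = ca_xyz[keep, 2], ca_z = ca_xyz[keep, 3],
    n_x = n_xyz[keep, 1], n_y = n_xyz[keep, 2], n_z = n_xyz[keep, 3],
    c_x = c_xyz[keep, 1], c_y = c_xyz[keep, 2], c_z = c_xyz[keep, 3],
    stringsAsFactors = FALSE
  )
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  new_protein_structure(id, chain, residues)
}

new_protein_structure <- function(id, chain_id, residues) {
  stopifnot(is.data.frame(residues))
  structure(list(id = id, chain_id = chain_id, residues = residues),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure '", x$id, "' chain ", x$chain_id, ": ",
      nrow(x$residues), " residues\n", sep = "")
  invisible(x)
}

# n x 3 matrix of CA coordinates
ca_coords <- function(p) {
  as.matrix(p$residues[, c("ca_x", "ca_y", "ca_z")])
}

#' Split a backbone into continuous segments
#'
#' Consecutive residues whose CA-CA distance exceeds `max_link`, or whose
#' author numbering is non-consecutive, start a new segment. Dihedral and
#' Gauss-integral computations never span a break.
#'
#' @param p a `protein_structure`.
#' @param max_link maximum CA-CA virtual bond length in Angstrom (default
#'   4.5; the typical trans peptide CA-CA distance is about 3.8).
#' @return list of integer residue-index ranges (vectors of indices).
#' @export
chain_break_segments <- function(p, max_link = 4.5) {
  n <- nrow(p$residues)
  if (n == 0L) stop("empty structure")
  if (n == 1L) return(list(1L))
  xyz <- ca_coords(p)
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  gap <- d > max_link | diff(p$residues$seq_num) != 1L
  starts <- c(1L, which(gap) + 1L)
  ends <- c(which(gap), n)
  mapply(function(s, e) seq.int(s, e), starts, ends, SIMPLIFY = FALSE)
}

#' Serialize a backbone to PDB text
#'
#' Writes N/CA/C ATOM records (where present) so that synthetic structures
#' and fixtures round-trip through [read_pdb_structure()].
#'
#' @param p a `protein_structure`.
#' @param path output file.
#' @export
write_backbone_pdb <- function(p, path) {
  res <- p$residues
  aa3 <- bio3d::aa123(res$aa)
  aa3[res$aa == "X"] <- "UNK"
  xyz <- c()
  elety <- c()
  resno <- c()
  resid <- c()
  for (i in seq_len(nrow(res))) {
    for (ele in c("N", "CA", "C")) {
      v <- switch(ele,
                  N = c(res$n_x[i], res$n_y[i], res$n_z[i]),
                  CA = c(res$ca_x[i], res$ca_y[i], res$ca_z[i]),
                  C = c(res$c_x[i], res$c_y[i], res$c_z[i]))
      if (any(is.na(v))) next
      xyz <- c(xyz, v)
      elety <- c(elety, ele)
      resno <- c(resno, res$seq_num[i])
      resid <- c(resid, aa3[i])
    }
  }
  n_at <- length(elety)
  bio3d::write.pdb(file = path, xyz = round(xyz, 3),
                   type = rep("ATOM", n_at),
                   resno = resno, resid = resid,
                   eleno = seq_len(n_at), elety = elety,
                   chain = rep(p$chain_id, n_at),
                   o = rep(1, n_at), b = rep(0, n_at))
  invisible(path)
}
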