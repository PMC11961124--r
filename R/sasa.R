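#' Default van der Waals radius table (Angstrom)
#'
#' NACCESS-like radii for the elements found in protein crystal structures.
#' Swappable: any named numeric vector of per-element radii is accepted by
#' [shrake_rupley()].
#' @return named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    SE = 1.90, FE = 1.47, MG = 1.73, ZN = 1.39, MN = 1.61,
    NA. = 2.27, CL = 1.75, K = 2.75, CA = 2.31)
}

# Deterministic quasi-uniform unit-sphere lattice (golden spiral).
.sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface by sampling a
#' deterministic golden-spiral point lattice on each atom's expanded sphere
#' and counting points not occluded by any neighboring atom. Deterministic
#' for fixed `n_points`.
#'
#' @param s a `Structure` (polymer atoms only; solvent is excluded so waters
#'   do not occlude the protein surface) or an atom data.frame with columns
#'   `x`, `y`, `z`, `elesy` (and optionally residue identity columns).
#' @param probe_radius probe sphere radius in Angstrom (water: 1.4).
#' @param n_points lattice points per atom (>= 100; default 960).
#' @param vdw named per-element radius table, see [default_vdw_radii()].
#' @return object of class `SasaTable`: `probe_radius`, `n_points`,
#'   `atoms` (input atoms + `asa` column, Angstrom^2) and `per_residue`
#'   (chain, resno, insert, resid, `total`, `side_chain`, `sg`).
#' @export
shrake_rupley <- function(s, probe_radius = 1.4, n_points = 960,
                          vdw = default_vdw_radii()) {
  if (n_points < 100) stop("n_points < 100: below the quadrature quality floor")
  at <- if (inherits(s, "Structure")) s$atoms[!s$atoms$solvent, , drop = FALSE] else s
  if (nrow(at) == 0) stop("no atoms for SASA computation")
  el <- ifelse(at$elesy == "NA", "NA.", at$elesy)
  r <- vdw[el]
  if (anyNA(r)) stop("no van der Waals radius for element(s): ",
                     paste(unique(at$elesy[is.na(r)]), collapse = ", "))
  r <- as.numeric(r) + probe_radius
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  lattice <- .sphere_lattice(n_points)
  asa <- numeric(n)
  # neighbor prescreen in chunks to bound memory on large structures
  chunk <- 512L
  maxr <- max(r)
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    d2 <- outer(rowSums(xyz[lo:hi, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[lo:hi, , drop = FALSE] %*% t(xyz)
    for (ii in lo:hi) {
      di2 <- d2[ii - lo + 1L, ]
      cut2 <- (r[ii] + r)^2
      nb <- which(di2 < cut2 & seq_len(n) != ii)
      if (length(nb) == 0) { asa[ii] <- 4 * pi * r[ii]^2; next }
      pts <- sweep(lattice * r[ii], 2, xyz[ii, ], "+")
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- pts[free, , drop = FALSE]
        dj2 <- (dj[, 1] - xyz[j, 1])^2 + (dj[, 2] - xyz[j, 2])^2 + (dj[, 3] - xyz[j, 3])^2
        free[free] <- dj2 >= r[j]^2
      }
      asa[ii] <- 4 * pi * r[ii]^2 * sum(free) / n_points
    }
  }
  at$asa <- asa
  per_res <- NULL
  if (all(c("chain", "resno", "insert", "resid", "elety") %in% names(at))) {
    key <- paste(at$chain, at$resno, at$insert)
    first <- !duplicated(key)
    bb <- at$elety %in% c("N", "CA", "C", "O", "OXT")
    total <- tapply(at$asa, key, sum)
    side <- tapply(at$asa * !bb, key, sum)
    sg <- tapply(ifelse(at$elety == "SG", at$asa, NA), key, function(v)
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
    k1 <- key[first]
    per_res <- data.frame(chain = at$chain[first], resno = at$resno[first],
                          insert = at$insert[first], resid = at$resid[first],
                          total = as.numeric(total[k1]),
                          side_chain = as.numeric(side[k1]),
                          sg = as.numeric(sg[k1]),
                          stringsAsFactors = FALSE)
    rownames(per_res) <- NULL
  }
  structure(list(probe_radius = probe_radius, n_points = n_points,
                 atoms = at, per_residue = per_res),
            class = "SasaTable")
}

#' Classify residues as solvent-exposed or buried
#'
#' A residue is exposed iff its scoped accessible area strictly exceeds the
#' threshold (an area exactly at the threshold is buried).
#'
#' @param tab a `SasaTable`.
#' @param residues data.frame with `chain`, `resno` (and optionally `insert`)
#'   naming the residues to classify.
#' @param threshold area threshold in Angstrom^2 (default 0.05 on the SG
#'   scope: the smallest area classed exposed in the reference analysis is
#'   0.113 Angstrom^2, so any non-negligible area counts).
#' @param atom_scope `"SG"`, `"side_chain"` or `"residue"`.
#' @return data.frame `residues` + columns `asa` and `class`
#'   (`"exposed"`/`"buried"`).
#' @export
exposure_class <- function(tab, residues, threshold = 0.05,
                           atom_scope = c("SG", "side_chain", "residue")) {
  atom_scope <- match.arg(atom_scope)
  stopifnot(inherits(tab, "SasaTable"))
  pr <- tab$per_residue
  if (is.null(pr)) stop("SasaTable lacks residue identities")
  if (is.null(residues$insert)) residues$insert <- ""
  ix <- match(paste(residues$chain, residues$resno, residues$insert),
              paste(pr$chain, pr$resno, pr$insert))
  if (anyNA(ix))
    stop("residue(s) absent from SASA table: ",
         paste(residues$resno[is.na(ix)], collapse = ", "))
  col <- switch(atom_scope, SG = "sg", side_chain = "side_chain", residue = "total")
  asa <- pr[[col]][ix]
  residues$asa <- asa
  residues$class <- ifelse(!is.na(asa) & asa > threshold, "exposed", "buried")
  residues
}
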