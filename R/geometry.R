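# Average atomic masses for Rg mass weighting.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                     P = 30.974, SE = 78.971, FE = 55.845, MG = 24.305,
                     ZN = 65.38, MN = 54.938, NA. = 22.990, CL = 35.45, K = 39.098,
                     CA = 40.078)

#' Pair residues between two chains
#'
#' Builds the residue correspondence every cross-structure RMSD rests on:
#' either by shared author numbering or by global sequence alignment
#' (Needleman-Wunsch via Biostrings), so that numbering offsets between
#' homologs cannot corrupt residue identities.
#'
#' @param a,b `Structure` objects.
#' @param chain_a,chain_b chain identifiers in `a` and `b`.
#' @param mode `"by_sequence"` (default) or `"by_number"`.
#' @return data.frame of class `ChainAlignment` with columns `resno_a`,
#'   `insert_a`, `resno_b`, `insert_b`; attribute `mode`.
#' @export
pair_chains <- function(a, chain_a, b, chain_b,
                        mode = c("by_sequence", "by_number")) {
  mode <- match.arg(mode)
  sa <- chain_sequence(a, chain_a)
  sb <- chain_sequence(b, chain_b)
  if (mode == "by_number") {
    ka <- paste(sa$resno, sa$insert)
    kb <- paste(sb$resno, sb$insert)
    common <- intersect(ka, kb)
    if (length(common) == 0) stop("zero residue pairs between chains (by_number)")
    ia <- match(common, ka); ib <- match(common, kb)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      paste(sa$seq, collapse = ""), paste(sb$seq, collapse = ""),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ia <- integer(0); ib <- integer(0)
    i <- 0L; j <- 0L
    for (k in seq_along(ap)) {
      if (ap[k] != "-") i <- i + 1L
      if (as_[k] != "-") j <- j + 1L
      if (ap[k] != "-" && as_[k] != "-") { ia <- c(ia, i); ib <- c(ib, j) }
    }
    if (length(ia) == 0) stop("zero residue pairs between chains (by_sequence)")
  }
  out <- data.frame(resno_a = sa$resno[ia], insert_a = sa$insert[ia],
                    resno_b = sb$resno[ib], insert_b = sb$insert[ib],
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("ChainAlignment", class(out))
  out
}

.kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- t(R)  # x_new = x %*% rot, applied to centered moving coords
  moved <- P %*% rot
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  # degenerate (collinear/planar-with-symmetry) input: second singular value ~ 0
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  list(rotation = rot, center_moving = cm, center_fixed = cf,
       translation = cf - cm %*% rot, rmsd = rmsd, residuals = sqrt(rowSums((moved - Q)^2)),
       degenerate = degenerate)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation/translation of `moving` onto `fixed` with optional
#' iterative outlier trimming: pairs whose residual exceeds
#' `sigma_cutoff` standard deviations of the current residuals are dropped
#' and the fit repeated until stable or `max_cycles` is reached.
#' The rotation is always a proper rotation (det = +1), never a reflection.
#'
#' @param moving,fixed n x 3 matrices of paired coordinates.
#' @param trim NULL (no trimming) or a list with `max_cycles` (default 5) and
#'   `sigma_cutoff` (default 2.0).
#' @return object of class `Superposition`: `rotation` (3x3, applied on the
#'   right to row vectors), `translation`, `rmsd`, `rmsd_all` (untrimmed RMSD
#'   under the final transform), `n_atoms` (pairs retained),
#'   `retained_fraction`, `kept` (logical index), `degenerate` flag.
#' @export
superpose <- function(moving, fixed, trim = NULL) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("coordinate sets differ in length")
  if (nrow(moving) < 3) stop("superposition needs at least 3 paired atoms")
  keep <- rep(TRUE, nrow(moving))
  fit <- .kabsch(moving, fixed)
  if (!is.null(trim)) {
    max_cycles <- if (is.null(trim$max_cycles)) 5L else trim$max_cycles
    sigma_cutoff <- if (is.null(trim$sigma_cutoff)) 2.0 else trim$sigma_cutoff
    for (cyc in seq_len(max_cycles)) {
      res <- fit$residuals
      # align-style rejection: drop pairs deviating beyond sigma_cutoff times
      # the current RMSD (residuals are chi-distributed, so their SD
      # understates the scale and would cascade); absolute floor keeps
      # numerical noise on near-identical sets from triggering trimming
      thr <- max(sigma_cutoff * fit$rmsd, 1e-3)
      drop <- res > thr
      if (!any(drop) || sum(keep) - sum(drop) < 3) break
      keep[keep][drop] <- FALSE
      fit <- .kabsch(moving[keep, , drop = FALSE], fixed[keep, , drop = FALSE])
    }
  }
  all_moved <- sweep(sweep(moving, 2, fit$center_moving) %*% fit$rotation,
                     2, fit$center_fixed, "+")
  rmsd_all <- sqrt(mean(rowSums((all_moved - fixed)^2)))
  structure(list(rotation = fit$rotation,
                 translation = as.numeric(fit$center_fixed - fit$center_moving %*% fit$rotation),
                 rmsd = fit$rmsd, rmsd_all = rmsd_all,
                 n_atoms = sum(keep),
                 retained_fraction = mean(keep), kept = keep,
                 degenerate = fit$degenerate),
            class = "Superposition")
}

#' Apply a Superposition to coordinates
#' @param xyz n x 3 matrix.
#' @param sp a `Superposition`.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sp) {
  out <- sweep(as.matrix(xyz) %*% sp$rotation, 2, sp$translation, "+")
  dimnames(out) <- NULL
  out
}

.ca_coords_for_pairs <- function(s, chain, resno, insert, elety = "CA") {
  at <- chain_atoms(s, chain)
  at <- at[at$elety == elety, , drop = FALSE]
  key <- paste(at$resno, at$insert)
  ix <- match(paste(resno, insert), key)
  list(xyz = as.matrix(at[ix, c("x", "y", "z")]), found = !is.na(ix))
}

#' Superpose one chain onto another over paired CA atoms
#'
#' Convenience wrapper: [pair_chains()] then [superpose()] on CA coordinates.
#' The published cross-structure RMSD protocol is CA-only, sequence-paired,
#' with iterative trimming (sigma 2.0, 5 cycles); both trimmed and untrimmed
#' RMSD are reported.
#'
#' @inheritParams pair_chains
#' @param trim as in [superpose()]; `list()` selects the default trimming.
#' @return a `Superposition` (attribute `alignment` holds the residue pairing).
#' @export
superpose_chains <- function(a, chain_a, b, chain_b,
                             mode = c("by_sequence", "by_number"),
                             trim = list()) {
  mode <- match.arg(mode)
  al <- pair_chains(a, chain_a, b, chain_b, mode = mode)
  ca <- .ca_coords_for_pairs(a, chain_a, al$resno_a, al$insert_a)
  cb <- .ca_coords_for_pairs(b, chain_b, al$resno_b, al$insert_b)
  ok <- ca$found & cb$found
  if (sum(ok) < 3) stop("fewer than 3 paired CA atoms")
  sp <- superpose(ca$xyz[ok, , drop = FALSE], cb$xyz[ok, , drop = FALSE], trim = trim)
  attr(sp, "alignment") <- al[ok, , drop = FALSE]
  sp
}

#' Distance between two atoms
#' @param s a `Structure`.
#' @param sel_a,sel_b selections as in [resolve_selection()].
#' @return distance in Angstrom.
#' @export
atom_distance <- function(s, sel_a, sel_b) {
  a <- resolve_selection(s, sel_a)
  b <- resolve_selection(s, sel_b)
  sqrt(sum((c(a$x, a$y, a$z) - c(b$x, b$y, b$z))^2))
}

#' Radius of gyration
#'
#' sqrt(sum w_i |r_i - rbar|^2 / sum w_i) over non-hydrogen atoms, with mass
#' weighting by default (uniform offered for comparison with geometric
#' oracles).
#'
#' @param s a `Structure` or an atom data.frame.
#' @param weighting `"mass"` or `"uniform"`.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(s, weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  at <- if (inherits(s, "Structure")) s$atoms[!s$atoms$solvent, , drop = FALSE] else s
  if (nrow(at) == 0) stop("empty selection")
  w <- if (weighting == "uniform") rep(1, nrow(at)) else {
    m <- .element_masses[ifelse(at$elesy == "NA", "NA.", at$elesy)]
    if (anyNA(m)) stop("no mass for element(s): ",
                       paste(unique(at$elesy[is.na(m)]), collapse = ", "))
    as.numeric(m)
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

#' Per-residue mean b-factor profile
#'
#' Mean crystallographic b-factor over the non-hydrogen atoms of each modeled
#' residue, ordered by residue number; gaps in the numbering are reported,
#' not interpolated.
#'
#' @inheritParams chain_atoms
#' @return data.frame (`resno`, `insert`, `resid`, `b_mean`, `n_atoms`) with
#'   attribute `gaps` listing missing residue numbers in the modeled span.
#' @export
bfactor_profile <- function(s, chain) {
  at <- chain_atoms(s, chain)
  key <- paste(at$resno, at$insert)
  agg <- aggregate(at$b, by = list(key = key), FUN = mean)
  first <- at[!duplicated(key), c("resno", "insert", "resid")]
  first$key <- key[!duplicated(key)]
  out <- merge(first, agg, by = "key")
  out <- out[order(out$resno, out$insert), c("resno", "insert", "resid", "x")]
  names(out)[4] <- "b_mean"
  cnt <- table(key)
  out$n_atoms <- as.integer(cnt[paste(out$resno, out$insert)])
  rownames(out) <- NULL
  span <- seq(min(out$resno), max(out$resno))
  attr(out, "gaps") <- setdiff(span, out$resno)
  out
}
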