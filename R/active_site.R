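#' Map a catalytic pocket onto a target from a holo homolog
#'
#' Superposes the holo chain onto the target chain (CA atoms, sequence
#' pairing, iterative trimming), carries the ligand into the target frame,
#' and reports every target residue with any non-hydrogen atom within
#' `cutoff` of any ligand atom. Residue transfer goes through the sequence
#' alignment, so numbering offsets between homologs cannot corrupt the
#' mapping.
#'
#' @param target,holo `Structure` objects.
#' @param target_chain,holo_chain chain identifiers.
#' @param ligand_id list or string `chain:resno:resname` identifying the
#'   ligand residue in `holo` (HETATM residue, e.g. the co-crystallized
#'   bisphosphate).
#' @param cutoff proximity cutoff in Angstrom (default 4.0).
#' @param mode residue pairing mode for the superposition.
#' @return object of class `PocketMap`: `residues` data.frame (chain, resno,
#'   aa, min_distance), `ligand_id`, `cutoff`, `superposition`.
#' @export
map_pocket_from_holo <- function(target, target_chain, holo, holo_chain,
                                 ligand_id, cutoff = 4.0,
                                 mode = c("by_sequence", "by_number")) {
  mode <- match.arg(mode)
  if (is.character(ligand_id)) {
    parts <- strsplit(ligand_id, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("ligand_id must be 'chain:resno:resname'")
    ligand_id <- list(chain = parts[1], resno = as.integer(parts[2]), resid = parts[3])
  }
  at <- holo$atoms
  lig <- at[at$chain == ligand_id$chain & at$resno == ligand_id$resno &
              at$resid == ligand_id$resid, , drop = FALSE]
  if (nrow(lig) == 0)
    stop("ligand not found in holo structure: ",
         paste(ligand_id$chain, ligand_id$resno, ligand_id$resid, sep = ":"))
  sp <- superpose_chains(holo, holo_chain, target, target_chain,
                         mode = mode, trim = list())
  lig_xyz <- apply_superposition(as.matrix(lig[, c("x", "y", "z")]), sp)
  tat <- chain_atoms(target, target_chain)
  txyz <- as.matrix(tat[, c("x", "y", "z")])
  d2 <- outer(rowSums(txyz^2), rowSums(lig_xyz^2), "+") - 2 * txyz %*% t(lig_xyz)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  key <- paste(tat$resno, tat$insert)
  res_min <- tapply(mind, key, min)
  first <- !duplicated(key)
  res <- data.frame(chain = tat$chain[first], resno = tat$resno[first],
                    insert = tat$insert[first], resid = tat$resid[first],
                    min_distance = as.numeric(res_min[key[first]]),
                    stringsAsFactors = FALSE)
  res <- res[res$min_distance <= cutoff, , drop = FALSE]
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  aa1 <- suppressWarnings(bio3d::aa321(res$resid)); aa1[is.na(aa1)] <- "X"
  res$aa <- aa1
  rownames(res) <- NULL
  structure(list(residues = res[, c("chain", "resno", "insert", "resid", "aa", "min_distance")],
                 ligand_id = ligand_id, cutoff = cutoff, superposition = sp),
            class = "PocketMap")
}

#' Distances from residue groups to a reference atom
#'
#' Per-group min/mean/max CA-to-reference distances, e.g. from the
#' N- and C-terminal phosphosite clusters to the pocket-center water oxygen.
#' Group residues missing from the model are reported and excluded; a group
#' with no modeled residue is an error.
#'
#' @param s a `Structure`.
#' @param reference_atom selection as in [resolve_selection()], e.g.
#'   `"A:401:O"`.
#' @param groups named list of data.frames (or integer vectors, resolved on
#'   the reference atom's chain) giving `chain` and `resno` per group.
#' @param atom atom name measured per residue (default `"CA"`).
#' @return object of class `SiteDistanceReport`: per-group data.frame with
#'   `n`, `n_missing`, `min`, `mean`, `max` plus `per_residue` detail.
#' @export
site_distances <- function(s, reference_atom, groups, atom = "CA") {
  ref <- resolve_selection(s, reference_atom)
  refxyz <- c(ref$x, ref$y, ref$z)
  at <- s$atoms[!s$atoms$solvent & s$atoms$elety == atom, , drop = FALSE]
  stats_df <- NULL
  detail <- list()
  for (g in names(groups)) {
    grp <- groups[[g]]
    if (!is.data.frame(grp)) grp <- data.frame(chain = ref$chain, resno = grp)
    ix <- match(paste(grp$chain, grp$resno), paste(at$chain, at$resno))
    missing <- grp$resno[is.na(ix)]
    ok <- !is.na(ix)
    if (!any(ok)) stop("no residue of group '", g, "' is modeled")
    d <- sqrt((at$x[ix[ok]] - refxyz[1])^2 + (at$y[ix[ok]] - refxyz[2])^2 +
                (at$z[ix[ok]] - refxyz[3])^2)
    detail[[g]] <- data.frame(chain = grp$chain[ok], resno = grp$resno[ok],
                              distance = d, stringsAsFactors = FALSE)
    stats_df <- rbind(stats_df, data.frame(
      group = g, n = sum(ok), n_missing = length(missing),
      min = min(d), mean = mean(d), max = max(d), stringsAsFactors = FALSE))
  }
  structure(list(reference_atom = reference_atom, groups = stats_df,
                 per_residue = detail),
            class = "SiteDistanceReport")
}

#' @export
print.PocketMap <- function(x, ...) {
  cat("PocketMap:", nrow(x$residues), "residues within", x$cutoff,
      "A of ligand", paste(unlist(x$ligand_id), collapse = ":"), "\n")
  if (nrow(x$residues) > 0)
    cat(" ", paste0(x$residues$aa, x$residues$resno, collapse = ", "), "\n")
  invisible(x)
}
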