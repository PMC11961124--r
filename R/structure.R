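#' @importFrom stats aggregate coef lm median nls optim sd setNames weighted.mean
#' @importFrom utils head read.table tail
NULL

# Residue names routed to the solvent list (waters and monoatomic ions).
.solvent_resids <- c(
  "HOH", "WAT", "DOD", "H2O",
  "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "FE2", "CU", "NI", "CO",
  "CD", "SR", "BA", "CS", "LI", "BR", "IOD", "F"
)

#' Construct a Structure object
#'
#' A `Structure` is the coordinate container every geometry, accessibility and
#' interface computation reads: a flat atom table in file order plus a solvent
#' partition (waters and ions), in the style of a `bio3d` atom record.
#'
#' @param id identifier string.
#' @param atoms data.frame with columns `type`, `eleno`, `elety`, `alt`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`,
#'   and logical `solvent`.
#' @param metadata free-form named list.
#' @return object of class `Structure`.
#' @export
new_structure <- function(id, atoms, metadata = list()) {
  needed <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
              "insert", "x", "y", "z", "o", "b", "elesy", "solvent")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop("non-finite coordinates in atom table")
    if (any(is.na(atoms$elesy) | atoms$elesy == ""))
      stop("element symbol missing for some atoms")
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, atoms$solvent)
    if (anyDuplicated(key))
      stop("duplicate atom name within a residue after alt-loc resolution")
  }
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, metadata = metadata),
            class = "Structure")
}

.empty_atoms <- function() {
  data.frame(type = character(), eleno = integer(), elety = character(),
             alt = character(), resid = character(), chain = character(),
             resno = integer(), insert = character(),
             x = numeric(), y = numeric(), z = numeric(),
             o = numeric(), b = numeric(), elesy = character(),
             solvent = logical(), stringsAsFactors = FALSE)
}

# Guess the element symbol from a PDB atom name when the element column is
# blank (common in minimal fixtures).
.element_from_name <- function(elety) {
  nm <- gsub("[0-9']", "", toupper(trimws(elety)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CU", "NI", "CO", "SE"),
         two, substr(nm, 1, 1))
}

#' Parse a PDB or mmCIF structure
#'
#' Reads coordinates from PDB-format or mmCIF text (or a file path). Alternate
#' locations are resolved per policy, hydrogens are dropped, and waters/ions
#' are routed to a solvent partition kept separate from the polymer chains.
#'
#' @param content character: either a path to a coordinate file or the file
#'   content itself (one string or a vector of lines).
#' @param alt_loc_policy `"highest_occupancy"` (default; ties broken by file
#'   order) or `"first"`.
#' @param id identifier stored on the returned object; defaults to a best
#'   guess from the content.
#' @param keep_hydrogens keep hydrogen atoms (default FALSE; the crystal
#'   structures this pipeline targets contain none).
#' @return a [new_structure()] object.
#' @export
parse_structure <- function(content, alt_loc_policy = c("highest_occupancy", "first"),
                            id = NULL, keep_hydrogens = FALSE) {
  alt_loc_policy <- match.arg(alt_loc_policy)
  lines <- .content_lines(content)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty input: no coordinate content")
  is_cif <- any(grepl("^\\s*_atom_site\\.", lines)) || grepl("^data_", lines[1])
  tmp <- tempfile(fileext = if (is_cif) ".cif" else ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(tmp, verbose = FALSE)
    else bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unparseable coordinate content: ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atom records found")
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad) > 0)
    stop("unparseable atom record at atom serial ", at$eleno[bad[1]])

  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  no_el <- is.na(at$elesy) | at$elesy == ""
  at$elesy[no_el] <- .element_from_name(at$elety[no_el])
  at$elesy <- toupper(at$elesy)

  if (!keep_hydrogens) at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) stop("no non-hydrogen atoms found")

  # alt-loc resolution within (chain, resno, insert, atom name)
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
    ord <- seq_len(nrow(at))
    keep <- unlist(lapply(split(ord, key), function(ix) {
      if (length(ix) == 1) return(ix)
      if (alt_loc_policy == "first") return(ix[1])
      occ <- at$o[ix]
      ix[which.max(occ)]  # which.max breaks ties by file order
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
    at$alt <- ""
  }

  at$solvent <- toupper(at$resid) %in% .solvent_resids
  at <- at[, c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
               "insert", "x", "y", "z", "o", "b", "elesy", "solvent")]
  if (is.null(id)) id <- if (is.character(content) && length(content) == 1 &&
                             !grepl("\n", content) && file.exists(content))
    sub("\\.(pdb|cif|ent)$", "", basename(content)) else "structure"
  new_structure(id, at)
}

.content_lines <- function(content) {
  if (!is.character(content)) stop("content must be character")
  if (length(content) == 1 && !grepl("\n", content) && file.exists(content))
    return(readLines(content, warn = FALSE))
  unlist(strsplit(content, "\n", fixed = TRUE), use.names = FALSE)
}

#' Serialize a Structure to PDB-format text
#'
#' @param s a `Structure`.
#' @param file optional path; when given the text is also written there.
#' @return character vector of PDB lines, invisibly when `file` is given.
#' @export
write_structure <- function(s, file = NULL) {
  stopifnot(inherits(s, "Structure"))
  at <- s$atoms
  if (nrow(at) == 0) stop("cannot write an empty structure")
  if (any(nchar(at$chain) > 1)) stop("chain id longer than one character cannot be written as PDB")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = at$type, resno = at$resno, resid = at$resid,
                   eleno = at$eleno, elety = at$elety, chain = at$chain,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   o = at$o, b = at$b, elesy = at$elesy)
  out <- readLines(tmp, warn = FALSE)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Census of a structure's content
#'
#' @param s a `Structure`.
#' @return list with `n_chains`, `chain_ids`, `n_residues` (polymer),
#'   `n_atoms` (non-hydrogen, polymer + solvent), `n_waters`,
#'   `residues_per_chain`.
#' @export
structure_census <- function(s) {
  at <- s$atoms
  poly <- at[!at$solvent, , drop = FALSE]
  rkey <- unique(paste(poly$chain, poly$resno, poly$insert))
  per_chain <- table(sub(" .*", "", rkey))
  waters <- at[at$solvent & toupper(at$resid) %in% c("HOH", "WAT", "DOD", "H2O"), , drop = FALSE]
  list(n_chains = length(unique(poly$chain)),
       chain_ids = sort(unique(poly$chain)),
       n_residues = length(rkey),
       n_atoms = nrow(at),
       n_waters = length(unique(paste(waters$chain, waters$resno, waters$insert))),
       residues_per_chain = per_chain)
}

#' Extract the polymer atoms of one chain
#' @param s a `Structure`.
#' @param chain chain identifier.
#' @return atom data.frame.
#' @export
chain_atoms <- function(s, chain) {
  at <- s$atoms
  out <- at[!at$solvent & at$chain == chain, , drop = FALSE]
  if (nrow(out) == 0) stop("unknown chain: ", chain)
  out
}

#' One-letter sequence of a chain (X for non-standard residues)
#' @inheritParams chain_atoms
#' @return list with `seq` (character vector) and `resno`, `insert` per position.
#' @export
chain_sequence <- function(s, chain) {
  at <- chain_atoms(s, chain)
  key <- paste(at$resno, at$insert, sep = "_")
  first <- !duplicated(key)
  res <- at[first, c("resid", "resno", "insert")]
  aa1 <- suppressWarnings(bio3d::aa321(res$resid))
  aa1[is.na(aa1)] <- "X"
  list(seq = aa1, resno = res$resno, insert = res$insert)
}

#' Resolve a "chain:resno:atom" selection to atom rows
#'
#' Searches polymer and solvent atoms; `"A:401:O"` addresses the oxygen of
#' water 401 on chain A. An empty chain field matches any chain.
#'
#' @param s a `Structure`.
#' @param sel selection string `chain:resno:atomname`, or a list with fields
#'   `chain`, `resno`, `elety`.
#' @param require_unique error unless exactly one atom matches.
#' @return atom data.frame rows.
#' @export
resolve_selection <- function(s, sel, require_unique = TRUE) {
  if (is.character(sel)) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("selection must be 'chain:resno:atomname': ", sel)
    sel <- list(chain = parts[1], resno = as.integer(parts[2]), elety = parts[3])
  }
  at <- s$atoms
  hit <- at$resno == sel$resno & at$elety == sel$elety
  if (nzchar(sel$chain)) hit <- hit & at$chain == sel$chain
  out <- at[hit, , drop = FALSE]
  if (nrow(out) == 0)
    stop("selection matches no atom: ", paste(sel$chain, sel$resno, sel$elety, sep = ":"))
  if (require_unique && nrow(out) > 1)
    stop("selection ambiguous (", nrow(out), " atoms): ",
         paste(sel$chain, sel$resno, sel$elety, sep = ":"))
  out
}

#' Construct a Trajectory object
#'
#' @param topology `Structure` giving frame-invariant atom identities.
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @param times per-frame time stamps (microseconds), strictly increasing.
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, frames, times) {
  stopifnot(inherits(topology, "Structure"))
  n <- nrow(topology$atoms)
  for (k in seq_along(frames)) {
    if (!is.matrix(frames[[k]]) || nrow(frames[[k]]) != n || ncol(frames[[k]]) != 3)
      stop("frame ", k, " does not match topology atom count (", n, ")")
    dimnames(frames[[k]]) <- NULL
  }
  if (length(times) != length(frames)) stop("times length must equal frame count")
  if (length(times) > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "Trajectory")
}

#' Parse a multi-model PDB trajectory
#'
#' @param content path or PDB text with MODEL/ENDMDL blocks (a single-model
#'   file yields a 1-frame trajectory).
#' @param times explicit per-frame times (microseconds), or NULL.
#' @param total_time when `times` is NULL, frames are spaced uniformly over
#'   `[0, total_time]`; with neither given, times are `0, 1, 2, ...`.
#' @return a [new_trajectory()] object.
#' @export
parse_trajectory <- function(content, times = NULL, total_time = NULL) {
  lines <- .content_lines(content)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    blocks <- list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    blocks <- Map(function(a, b) lines[(a + 1):(b - 1)], starts, ends[seq_along(starts)])
  }
  topo <- parse_structure(paste(blocks[[1]], collapse = "\n"), id = "frame1")
  n <- nrow(topo$atoms)
  frames <- vector("list", length(blocks))
  frames[[1]] <- as.matrix(topo$atoms[, c("x", "y", "z")])
  if (length(blocks) > 1) {
    for (k in 2:length(blocks)) {
      sk <- parse_structure(paste(blocks[[k]], collapse = "\n"), id = paste0("frame", k))
      if (nrow(sk$atoms) != n)
        stop("atom-count mismatch in model ", k, ": ", nrow(sk$atoms), " vs ", n)
      frames[[k]] <- as.matrix(sk$atoms[, c("x", "y", "z")])
    }
  }
  nf <- length(frames)
  if (is.null(times)) {
    times <- if (!is.null(total_time)) seq(0, total_time, length.out = nf) else seq_len(nf) - 1
  }
  new_trajectory(topo, frames, times)
}

#' Construct a Chromatogram object
#'
#' @param volume elution volumes (mL), strictly increasing.
#' @param absorbance matching absorbance series (arbitrary units).
#' @param V0,Vc optional void and column volumes (mL) for Kav calibration.
#' @return object of class `Chromatogram`.
#' @export
new_chromatogram <- function(volume, absorbance, V0 = NULL, Vc = NULL) {
  if (length(volume) != length(absorbance)) stop("volume and absorbance lengths differ")
  if (length(volume) < 2) stop("chromatogram needs at least 2 points")
  if (any(diff(volume) <= 0)) stop("volume series must be strictly increasing")
  structure(list(volume = as.numeric(volume), absorbance = as.numeric(absorbance),
                 V0 = V0, Vc = Vc), class = "Chromatogram")
}

#' Parse a two-column volume/absorbance table
#'
#' Accepts comma- or tab/space-delimited text with an optional header line.
#'
#' @inheritParams parse_structure
#' @param V0,Vc optional column volumes attached to the result.
#' @return a [new_chromatogram()] object.
#' @export
parse_chromatogram <- function(content, V0 = NULL, Vc = NULL) {
  lines <- .content_lines(content)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty chromatogram input")
  sep <- if (grepl(",", lines[min(2, length(lines))])) "," else ""
  first_num <- suppressWarnings(!anyNA(as.numeric(strsplit(trimws(lines[1]),
                                                           if (sep == ",") "," else "[\t ]+")[[1]][1:2])))
  df <- read.table(text = paste(lines, collapse = "\n"), sep = sep,
                   header = !first_num, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chromatogram needs two columns (volume, absorbance)")
  new_chromatogram(as.numeric(df[[1]]), as.numeric(df[[2]]), V0 = V0, Vc = Vc)
}

#' @export
print.Structure <- function(x, ...) {
  cen <- structure_census(x)
  cat("Structure", x$id, "-", cen$n_chains, "chain(s),", cen$n_residues,
      "polymer residues,", cen$n_atoms, "non-H atoms,", cen$n_waters, "waters\n")
  invisible(x)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames x", nrow(x$topology$atoms),
      "atoms, t =", format(min(x$times)), "to", format(max(x$times)), "\n")
  invisible(x)
}
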