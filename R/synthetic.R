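#' Evaluate code under a local, named random stream
#'
#' Seeds the RNG for the duration of `code` and restores the caller's
#' `.Random.seed` afterwards, so seeded generators compose without touching
#' global state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

.unit <- function(v) v / sqrt(sum(v^2))

.rotation_matrix <- function(axis, angle_deg) {
  u <- .unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Closed-form optimal-superposition RMSD by the quaternion eigen-method;
# used to record generator ground truth independently of the Kabsch path.
.quaternion_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- crossprod(A, B)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# Backbone template offsets (Angstrom) relative to CA, loosely bond-plausible.
.bb_offsets <- list(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0),
                    C = c(1.52, 0.2, 0.0), O = c(2.15, 1.2, 0.0),
                    CB = c(0.2, -1.1, 1.0))

#' Generate a toy multi-chain structure with placed cysteines
#'
#' Poly-alanine chains laid on a smooth helical curve (5 heavy atoms per
#' residue: N, CA, C, O, CB), with cysteines substituted at requested
#' positions. Paired placements realize the requested SG-SG distance exactly
#' (well within 0.01 Angstrom) by placing both SG atoms on the CB-CB axis;
#' unpaired cysteines point their SG outward to solvent. Geometrically
#' plausible, not physically minimized: adequate for exercising geometry,
#' accessibility and interface code paths.
#'
#' @param n_chains number of chains (ids A, B, ...).
#' @param residues_per_chain residues per chain.
#' @param cys_placements list of placements; each is a list with `chain`,
#'   `resno`, and optionally `partner = c(chain, resno)` plus `distance`
#'   (Angstrom) for a thiol pair (state each pair once).
#' @param seed integer seed (jitter stream).
#' @param chain_offsets list of 3-vectors translating each chain; default
#'   spaces chains 60 Angstrom apart along x (non-contacting).
#' @param jitter_sd Gaussian coordinate noise, Angstrom (default 0).
#' @param b_factors optional named vector resno -> b (applied to all chains);
#'   default 20 everywhere.
#' @param resno_start first residue number (default 1).
#' @return a `Structure`; `metadata$truth` records intended disulfides and
#'   free thiols.
#' @export
make_toy_structure <- function(n_chains = 1, residues_per_chain = 30,
                               cys_placements = list(), seed = 1,
                               chain_offsets = NULL, jitter_sd = 0,
                               b_factors = NULL, resno_start = 1) {
  with_local_seed(seed, {
    chains <- LETTERS[seq_len(n_chains)]
    if (is.null(chain_offsets))
      chain_offsets <- lapply(seq_len(n_chains) - 1, function(k) c(60 * k, 0, 0))
    cys_by_chain <- list()
    for (p in cys_placements) {
      cys_by_chain[[p$chain]] <- c(cys_by_chain[[p$chain]], p$resno)
      if (!is.null(p$partner))
        cys_by_chain[[p$partner[1]]] <- c(cys_by_chain[[p$partner[1]]],
                                          as.integer(p$partner[2]))
    }
    rows <- list()
    eleno <- 0L
    dtheta <- 0.15; R0 <- 20; cpitch <- 2.33 / 0.15
    for (ci in seq_len(n_chains)) {
      off <- chain_offsets[[ci]]
      for (ri in seq_len(residues_per_chain)) {
        resno <- resno_start + ri - 1L
        th <- ri * dtheta
        ca <- c(R0 * cos(th), R0 * sin(th), cpitch * th) + off
        # local frame: tangent/radial so side chains point outward
        rad <- .unit(c(cos(th), sin(th), 0))
        tan_ <- .unit(c(-sin(th) * R0, cos(th) * R0, cpitch))
        up <- .unit(.cross3(rad, tan_))
        frame <- cbind(tan_, rad, up)
        is_cys <- !is.null(cys_by_chain[[chains[ci]]]) &&
          resno %in% cys_by_chain[[chains[ci]]]
        resid <- if (is_cys) "CYS" else "ALA"
        for (an in names(.bb_offsets)) {
          eleno <- eleno + 1L
          pos <- ca + as.numeric(frame %*% .bb_offsets[[an]])
          if (jitter_sd > 0) pos <- pos + stats::rnorm(3, 0, jitter_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            type = "ATOM", eleno = eleno, elety = an, alt = "",
            resid = resid, chain = chains[ci], resno = resno, insert = "",
            x = pos[1], y = pos[2], z = pos[3], o = 1,
            b = if (!is.null(b_factors) && as.character(resno) %in% names(b_factors))
              unname(b_factors[as.character(resno)]) else 20,
            elesy = substr(an, 1, 1), solvent = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
    at <- do.call(rbind, rows)
    # place SG atoms
    get_cb <- function(ch, rn) {
      ix <- which(at$chain == ch & at$resno == rn & at$elety == "CB")
      if (length(ix) != 1) stop("placement outside the chain: ", ch, rn)
      list(ix = ix, xyz = as.numeric(at[ix, c("x", "y", "z")]))
    }
    sg_rows <- list()
    add_sg <- function(ch, rn, pos) {
      eleno <<- eleno + 1L
      sg_rows[[length(sg_rows) + 1L]] <<- data.frame(
        type = "ATOM", eleno = eleno, elety = "SG", alt = "", resid = "CYS",
        chain = ch, resno = rn, insert = "", x = pos[1], y = pos[2], z = pos[3],
        o = 1, b = 20, elesy = "S", solvent = FALSE, stringsAsFactors = FALSE)
    }
    truth <- list(disulfides = NULL, free_thiols = NULL, pairs = NULL)
    placed <- character(0)
    for (p in cys_placements) {
      if (is.null(p$partner)) {
        cb <- get_cb(p$chain, p$resno)
        local <- cb$xyz - chain_offsets[[match(p$chain, chains)]]
        outward <- .unit(c(local[1], local[2], 0))  # radial: away from the helix axis
        add_sg(p$chain, p$resno, cb$xyz + 1.81 * outward)
        truth$free_thiols <- rbind(truth$free_thiols,
                                   data.frame(chain = p$chain, resno = p$resno))
        placed <- c(placed, paste(p$chain, p$resno))
      } else {
        cb1 <- get_cb(p$chain, p$resno)
        cb2 <- get_cb(p$partner[1], as.integer(p$partner[2]))
        u <- .unit(cb2$xyz - cb1$xyz)
        D <- sqrt(sum((cb2$xyz - cb1$xyz)^2))
        # SGs symmetric about the CB-CB midpoint: exact requested separation,
        # each SG within reach of its own CB
        mid <- (cb1$xyz + cb2$xyz) / 2
        sg1 <- mid - (p$distance / 2) * u
        sg2 <- mid + (p$distance / 2) * u
        if (abs(D - p$distance) / 2 > 6)
          stop("infeasible placement: requested SG-SG distance ", p$distance,
               " incompatible with CB separation ", round(D, 2))
        add_sg(p$chain, p$resno, sg1)
        add_sg(p$partner[1], as.integer(p$partner[2]), sg2)
        pair <- data.frame(chain_a = p$chain, resno_a = p$resno,
                           chain_b = p$partner[1],
                           resno_b = as.integer(p$partner[2]),
                           distance = p$distance)
        truth$pairs <- rbind(truth$pairs, pair)
        if (p$distance <= 2.3) truth$disulfides <- rbind(truth$disulfides, pair)
        else truth$free_thiols <- rbind(truth$free_thiols,
                                        data.frame(chain = c(p$chain, p$partner[1]),
                                                   resno = c(p$resno, as.integer(p$partner[2]))))
        placed <- c(placed, paste(p$chain, p$resno), paste(p$partner[1], p$partner[2]))
      }
    }
    if (length(sg_rows) > 0) at <- rbind(at, do.call(rbind, sg_rows))
    at <- at[order(match(at$chain, chains), at$resno, match(at$elety, c(names(.bb_offsets), "SG"))), ]
    at$eleno <- seq_len(nrow(at))
    new_structure("toy", at, metadata = list(truth = truth, seed = seed))
  })
}

# minimal cross product (avoids a dependency for one primitive)
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Generate a homolog pair related by a known rigid motion plus noise
#'
#' Copies `base`, applies the stated rotation/translation, perturbs each
#' coordinate with Gaussian noise, and optionally renumbers residues (to
#' exercise sequence-based pairing under numbering offsets). The realized
#' optimal-fit RMSD between the pair is recorded as ground truth by the
#' closed-form quaternion method, independent of the package's Kabsch path.
#'
#' @param base a `Structure`.
#' @param axis rotation axis (3-vector).
#' @param angle_deg rotation angle, degrees.
#' @param translation 3-vector, Angstrom.
#' @param noise_sd per-coordinate Gaussian noise, Angstrom.
#' @param seed integer seed.
#' @param renumber_offset added to residue numbers of the moved copy.
#' @return list `a` (the base), `b` (moved copy), `truth` (rotation matrix,
#'   translation, noise_sd, realized `rmsd`).
#' @export
make_homolog_pair <- function(base, axis = c(0, 0, 1), angle_deg = 0,
                              translation = c(0, 0, 0), noise_sd = 0,
                              seed = 1, renumber_offset = 0) {
  with_local_seed(seed, {
    R <- .rotation_matrix(axis, angle_deg)
    at <- base$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")])
    moved <- xyz %*% t(R) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
    if (noise_sd > 0) moved <- moved + matrix(stats::rnorm(length(moved), 0, noise_sd),
                                              nrow(xyz), 3)
    bt <- at
    bt[, c("x", "y", "z")] <- moved
    bt$resno <- bt$resno + renumber_offset
    b <- new_structure(paste0(base$id, "_moved"), bt, metadata = base$metadata)
    truth_rmsd <- .quaternion_rmsd(moved, xyz)
    list(a = base, b = b,
         truth = list(rotation = R, translation = translation,
                      noise_sd = noise_sd, rmsd = truth_rmsd,
                      renumber_offset = renumber_offset))
  })
}

#' Generate a trajectory with a planted abrupt concerted transition
#'
#' A rigid core plus a mobile motif: at `transition_time` every motif
#' residue steps along its own fixed random direction by its planted
#' amplitude, on top of Gaussian jitter; an optional random rigid tumbling
#' motion is applied per frame so core superposition is exercised.
#'
#' @param n_frames number of frames.
#' @param dt frame spacing, us.
#' @param core_size residues in the rigid core (numbered 1..core_size).
#' @param motif_size residues in the mobile motif (numbered after the core).
#' @param transition_time time of the planted step, us.
#' @param amplitudes per-motif-residue jump amplitudes, Angstrom (length
#'   `motif_size`; a residue with amplitude 0 stays flat).
#' @param noise_sd per-coordinate jitter, Angstrom.
#' @param seed integer seed.
#' @param tumbling apply a random global rigid motion per frame.
#' @return a `Trajectory`; `topology$metadata$truth` records
#'   `transition_time`, `transition_frame`, `amplitudes`, `motif_resno`,
#'   `core_resno`, `directions`.
#' @export
make_loop_trajectory <- function(n_frames = 200, dt = 0.1, core_size = 30,
                                 motif_size = 20, transition_time,
                                 amplitudes, noise_sd = 0.3, seed = 1,
                                 tumbling = TRUE) {
  if (length(amplitudes) != motif_size)
    stop("amplitudes length (", length(amplitudes), ") must equal motif size (",
         motif_size, ")")
  times <- (seq_len(n_frames) - 1) * dt
  if (transition_time < min(times) || transition_time > max(times))
    stop("transition_time outside the trajectory span")
  with_local_seed(seed, {
    topo <- make_toy_structure(n_chains = 1,
                               residues_per_chain = core_size + motif_size,
                               seed = seed)
    core_resno <- seq_len(core_size)
    motif_resno <- core_size + seq_len(motif_size)
    at <- topo$atoms
    X0 <- as.matrix(at[, c("x", "y", "z")])
    dirs <- t(vapply(seq_len(motif_size), function(i) .unit(stats::rnorm(3)),
                     numeric(3)))
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      X <- X0
      if (times[k] >= transition_time) {
        for (j in seq_len(motif_size)) {
          ix <- which(at$resno == motif_resno[j])
          X[ix, ] <- X[ix, ] + matrix(amplitudes[j] * dirs[j, ],
                                      length(ix), 3, byrow = TRUE)
        }
      }
      if (noise_sd > 0)
        X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X), 3)
      if (tumbling) {
        R <- .rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 15))
        X <- X %*% t(R) + matrix(stats::rnorm(3, 0, 2), nrow(X), 3, byrow = TRUE)
      }
      frames[[k]] <- X
    }
    topo$metadata$truth <- list(
      transition_time = transition_time,
      transition_frame = which(times >= transition_time)[1],
      amplitudes = amplitudes, motif_resno = motif_resno,
      core_resno = core_resno, directions = dirs, noise_sd = noise_sd)
    new_trajectory(topo, frames, times)
  })
}

#' Generate a chromatogram as a sum of Gaussian peaks
#'
#' @param peaks data.frame with `center` (mL), `width` (mL, Gaussian sd) and
#'   `area` per peak.
#' @param baseline constant baseline.
#' @param noise_sd Gaussian noise sd (absorbance units).
#' @param volumes volume grid (mL).
#' @param seed integer seed.
#' @param V0,Vc optional column volumes attached to the result.
#' @return a `Chromatogram`; attribute `truth` records the planted peaks.
#' @export
make_chromatogram <- function(peaks, baseline = 0, noise_sd = 0,
                              volumes = seq(8, 20, by = 0.02), seed = 1,
                              V0 = NULL, Vc = NULL) {
  stopifnot(all(peaks$width > 0))
  with_local_seed(seed, {
    y <- .gaussian_sum(volumes, peaks$center, peaks$width, peaks$area, baseline)
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    out <- new_chromatogram(volumes, y, V0 = V0, Vc = Vc)
    attr(out, "truth") <- list(peaks = peaks, baseline = baseline,
                               noise_sd = noise_sd)
    out
  })
}
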