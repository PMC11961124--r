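.traj_xyz <- function(t, frame) t$frames[[frame]]

# atom indices of a residue set (heavy atoms) in the topology
.residue_atom_index <- function(topo, chain, resno) {
  at <- topo$atoms
  which(!at$solvent & (if (is.null(chain)) TRUE else at$chain == chain) &
          at$resno %in% resno)
}

#' Superpose every frame onto the reference frame by a rigid core
#'
#' Removes global tumbling so mobile-motif series reflect internal motion:
#' each frame is least-squares fitted onto frame 1 over the core CA atoms.
#'
#' @param t a `Trajectory`.
#' @param core_resno residue numbers forming the rigid core; default NULL
#'   means all CA atoms.
#' @param chain restrict the core to one chain (default all).
#' @return the aligned `Trajectory`; attribute `core_rmsd` gives the
#'   per-frame core-CA RMSD after fitting.
#' @export
core_superpose <- function(t, core_resno = NULL, chain = NULL) {
  at <- t$topology$atoms
  core <- which(!at$solvent & at$elety == "CA" &
                  (if (is.null(chain)) TRUE else at$chain == chain) &
                  (if (is.null(core_resno)) TRUE else at$resno %in% core_resno))
  if (length(core) < 3) stop("core selection has fewer than 3 CA atoms")
  ref <- t$frames[[1]][core, , drop = FALSE]
  core_rmsd <- numeric(length(t$frames))
  frames <- t$frames
  for (k in seq_along(frames)) {
    sp <- superpose(frames[[k]][core, , drop = FALSE], ref)
    frames[[k]] <- apply_superposition(frames[[k]], sp)
    core_rmsd[k] <- sp$rmsd
  }
  out <- new_trajectory(t$topology, frames, t$times)
  attr(out, "core_rmsd") <- core_rmsd
  attr(out, "core_index") <- core
  out
}

#' Per-residue RMSD time series against a reference frame
#'
#' Heavy-atom RMSD of each residue versus its conformation in the reference
#' frame, computed in the aligned frame (no per-residue refitting), per
#' frame.
#'
#' @param t an aligned `Trajectory` (see [core_superpose()]).
#' @param residues residue numbers of the mobile motif.
#' @param chain restrict to one chain.
#' @param reference_frame index of the reference frame (default 1, the
#'   starting conformation).
#' @return object of class `SeriesResult`: `times`, `residues`, `values`
#'   (frames x residues matrix, Angstrom).
#' @export
residue_rmsd_series <- function(t, residues, chain = NULL, reference_frame = 1) {
  at <- t$topology$atoms
  idx <- lapply(residues, function(r) {
    ix <- .residue_atom_index(t$topology, chain, r)
    if (length(ix) == 0) stop("residue ", r, " not found in topology")
    ix
  })
  ref <- t$frames[[reference_frame]]
  vals <- matrix(0, nrow = length(t$frames), ncol = length(residues),
                 dimnames = list(NULL, residues))
  for (k in seq_along(t$frames)) {
    fr <- t$frames[[k]]
    for (j in seq_along(idx)) {
      dd <- fr[idx[[j]], , drop = FALSE] - ref[idx[[j]], , drop = FALSE]
      vals[k, j] <- sqrt(mean(rowSums(dd^2)))
    }
  }
  structure(list(times = t$times, residues = residues, values = vals,
                 reference_frame = reference_frame),
            class = "SeriesResult")
}

#' Inter-atomic distance time series
#'
#' @param t a `Trajectory`.
#' @param sel_a,sel_b atom selections as in [resolve_selection()], resolved
#'   on the topology.
#' @return numeric per-frame distances (Angstrom), named by time.
#' @export
pair_distance_series <- function(t, sel_a, sel_b) {
  find_ix <- function(sel) {
    row <- resolve_selection(t$topology, sel)
    at <- t$topology$atoms
    which(at$chain == row$chain & at$resno == row$resno & at$elety == row$elety &
            at$insert == row$insert & at$solvent == row$solvent)[1]
  }
  ia <- find_ix(sel_a); ib <- find_ix(sel_b)
  d <- vapply(t$frames, function(fr) sqrt(sum((fr[ia, ] - fr[ib, ])^2)), numeric(1))
  names(d) <- t$times
  d
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF about the window-mean position: per heavy atom,
#' sqrt(mean |r - rbar|^2) over the window frames, then averaged over the
#' residue's atoms. Isotropic per-coordinate jitter of width sigma gives
#' RMSF = sigma * sqrt(3).
#'
#' @param t an aligned `Trajectory`.
#' @param residues residue numbers.
#' @param chain restrict to one chain.
#' @param window frame indices to use (default all).
#' @return named numeric vector, Angstrom.
#' @export
rmsf <- function(t, residues, chain = NULL, window = NULL) {
  if (is.null(window)) window <- seq_along(t$frames)
  if (length(window) == 0) stop("empty frame window")
  out <- numeric(length(residues))
  for (j in seq_along(residues)) {
    ix <- .residue_atom_index(t$topology, chain, residues[j])
    if (length(ix) == 0) stop("residue ", residues[j], " not found in topology")
    X <- vapply(t$frames[window], function(fr) fr[ix, , drop = FALSE],
                matrix(0, length(ix), 3))
    X <- array(X, dim = c(length(ix), 3, length(window)))
    mu <- apply(X, c(1, 2), mean)
    dev2 <- apply((X - array(mu, dim = dim(X)))^2, c(1, 3), sum)
    out[j] <- mean(sqrt(rowMeans(dev2)))
  }
  names(out) <- residues
  out
}

# Binary segmentation on segment means: recursively split where the
# between-segment mean shift is largest, accepting splits whose jump reaches
# min_jump with both segments at least min_segment frames long.
.binseg <- function(x, min_jump, min_segment) {
  n <- length(x)
  splits <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2 * min_segment) return(invisible())
    best_k <- 0L; best_gain <- -Inf; best_jump <- 0
    cs <- cumsum(x[lo:hi]); tot <- cs[len]
    for (k in min_segment:(len - min_segment)) {
      m1 <- cs[k] / k; m2 <- (tot - cs[k]) / (len - k)
      gain <- k * (len - k) / len * (m1 - m2)^2
      if (gain > best_gain) { best_gain <- gain; best_k <- k; best_jump <- abs(m2 - m1) }
    }
    if (best_k == 0L || best_jump < min_jump) return(invisible())
    splits <<- c(splits, lo + best_k - 1L)
    recurse(lo, lo + best_k - 1L)
    recurse(lo + best_k, hi)
  }
  recurse(1L, n)
  sort(splits)
}

#' Detect abrupt per-residue transitions and concerted events
#'
#' Change points per residue by binary segmentation on mean shift; a
#' transition is retained when the segment-mean jump reaches `min_jump` with
#' both segments at least `min_segment` frames. Transition times are then
#' clustered across residues: times within `concert_window` of a cluster
#' join it, and an event is concerted when the participating fraction of the
#' mobile residues reaches `concert_fraction`.
#'
#' @param series a `SeriesResult`.
#' @param min_jump minimum segment-mean shift, Angstrom (default 1.0).
#' @param min_segment minimum segment length, frames (default 5; >= 2
#'   required).
#' @param concert_window clustering window on transition times, us
#'   (default 0.5).
#' @param concert_fraction participating fraction declaring an event
#'   concerted (default 0.75).
#' @return object of class `ChangePointResult`: `per_residue` data.frame
#'   (residue, time, jump), `events` data.frame (time, n_residues, fraction,
#'   concerted).
#' @export
detect_transitions <- function(series, min_jump = 1.0, min_segment = 5,
                               concert_window = 0.5, concert_fraction = 0.75) {
  stopifnot(inherits(series, "SeriesResult"))
  if (min_segment < 2) stop("min_segment must be at least 2")
  if (nrow(series$values) < 2 * min_segment)
    stop("series too short for the requested min_segment")
  per <- NULL
  for (j in seq_len(ncol(series$values))) {
    x <- series$values[, j]
    sp <- .binseg(x, min_jump, min_segment)
    for (spl in sp) {
      seg_lo <- max(1, spl - min_segment + 1)
      seg_hi <- min(length(x), spl + min_segment)
      jump <- abs(mean(x[(spl + 1):seg_hi]) - mean(x[seg_lo:spl]))
      per <- rbind(per, data.frame(residue = series$residues[j],
                                   time = series$times[spl + 1],
                                   frame = spl + 1, jump = jump))
    }
  }
  n_mobile <- ncol(series$values)
  if (is.null(per)) {
    events <- data.frame(time = numeric(), n_residues = integer(),
                         fraction = numeric(), concerted = logical())
    return(structure(list(per_residue = data.frame(residue = integer(),
                                                   time = numeric(),
                                                   frame = integer(),
                                                   jump = numeric()),
                          events = events, n_mobile = n_mobile),
                     class = "ChangePointResult"))
  }
  per <- per[order(per$time), , drop = FALSE]
  rownames(per) <- NULL
  # single-linkage clustering of transition times within the window
  cl <- cumsum(c(1, diff(per$time) > concert_window))
  events <- do.call(rbind, lapply(split(per, cl), function(g) {
    data.frame(time = median(g$time), n_residues = length(unique(g$residue)),
               fraction = length(unique(g$residue)) / n_mobile)
  }))
  events$concerted <- events$fraction >= concert_fraction
  rownames(events) <- NULL
  structure(list(per_residue = per, events = events, n_mobile = n_mobile),
            class = "ChangePointResult")
}

#' Representative conformation of a time block
#'
#' Medoid frame of the window: the frame minimizing summed pairwise
#' heavy-atom RMSD to the other window frames (ties broken by the earliest
#' frame).
#'
#' @param t an aligned `Trajectory`.
#' @param window two-element time window (us), inclusive.
#' @param atoms optional atom index subset (default all non-solvent heavy
#'   atoms).
#' @return object of class `BlockRepresentative`: `window`, `medoid_frame`
#'   (index into the trajectory), `medoid_time`, `mean_pairwise_rmsd`.
#' @export
block_representative <- function(t, window, atoms = NULL) {
  inw <- which(t$times >= window[1] & t$times <= window[2])
  if (length(inw) == 0) stop("no frames in the requested window")
  if (is.null(atoms)) atoms <- which(!t$topology$atoms$solvent)
  n <- length(inw)
  if (n == 1) {
    return(structure(list(window = window, medoid_frame = inw,
                          medoid_time = t$times[inw], mean_pairwise_rmsd = 0),
                     class = "BlockRepresentative"))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dd <- t$frames[[inw[i]]][atoms, , drop = FALSE] -
      t$frames[[inw[j]]][atoms, , drop = FALSE]
    D[i, j] <- D[j, i] <- sqrt(mean(rowSums(dd^2)))
  }
  sums <- rowSums(D)
  med <- which.min(sums)  # which.min takes the earliest on ties
  structure(list(window = window, medoid_frame = inw[med],
                 medoid_time = t$times[inw[med]],
                 mean_pairwise_rmsd = mean(D[upper.tri(D)])),
            class = "BlockRepresentative")
}

#' @export
print.ChangePointResult <- function(x, ...) {
  cat("ChangePointResult:", nrow(x$per_residue), "per-residue transitions,",
      nrow(x$events), "event(s)\n")
  if (nrow(x$events) > 0) print(x$events)
  invisible(x)
}
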