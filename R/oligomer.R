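# Average residue masses (Da) for the 20 standard amino acids, and the
# standard 280 nm extinction coefficients (M^-1 cm^-1).
.residue_masses <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.01528

#' Interface buried area between two chains
#'
#' PISA-style buried area: ASA(A alone) + ASA(B alone) - ASA(AB complex),
#' all three computed with identical Shrake-Rupley parameters. Contacting
#' residues are those with any-atom cross-chain distance within
#' `contact_cutoff`.
#'
#' @param s a `Structure` containing both chains.
#' @param chain_a,chain_b chain identifiers.
#' @param probe_radius,n_points,vdw passed to [shrake_rupley()].
#' @param contact_cutoff any-atom distance (Angstrom) defining contacting
#'   residues (default 5.0).
#' @return object of class `InterfaceReport`: `buried_area` (Angstrom^2,
#'   clipped at 0), per-chain contributions, `contacts` residue table.
#' @export
buried_area <- function(s, chain_a, chain_b, probe_radius = 1.4,
                        n_points = 960, vdw = default_vdw_radii(),
                        contact_cutoff = 5.0) {
  ata <- chain_atoms(s, chain_a)
  atb <- chain_atoms(s, chain_b)
  xa <- as.matrix(ata[, c("x", "y", "z")])
  xb <- as.matrix(atb[, c("x", "y", "z")])
  # distance prescreen: chains farther than the largest possible occlusion
  # reach cannot bury area
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  mind <- sqrt(max(min(d2), 0))
  reach <- 2 * (max(unlist(vdw)) + probe_radius)
  if (mind > max(reach, contact_cutoff)) {
    contacts <- data.frame(chain = character(), resno = integer(),
                           resid = character(), stringsAsFactors = FALSE)
    return(structure(list(chain_a = chain_a, chain_b = chain_b,
                          buried_area = 0, contribution_a = 0, contribution_b = 0,
                          asa_a = NA_real_, asa_b = NA_real_, asa_ab = NA_real_,
                          contacts = contacts),
                     class = "InterfaceReport"))
  }
  sr <- function(at) sum(shrake_rupley(at, probe_radius = probe_radius,
                                       n_points = n_points, vdw = vdw)$atoms$asa)
  asa_a <- sr(ata); asa_b <- sr(atb)
  ab <- rbind(ata, atb)
  tab_ab <- shrake_rupley(ab, probe_radius = probe_radius, n_points = n_points, vdw = vdw)
  asa_ab <- sum(tab_ab$atoms$asa)
  ba <- max(asa_a + asa_b - asa_ab, 0)
  in_a <- seq_len(nrow(ata))
  contrib_a <- asa_a - sum(tab_ab$atoms$asa[in_a])
  contrib_b <- asa_b - sum(tab_ab$atoms$asa[-in_a])
  near <- which(d2 <= contact_cutoff^2, arr.ind = TRUE)
  contacts <- unique(rbind(
    data.frame(chain = chain_a, resno = ata$resno[near[, 1]],
               resid = ata$resid[near[, 1]], stringsAsFactors = FALSE),
    data.frame(chain = chain_b, resno = atb$resno[near[, 2]],
               resid = atb$resid[near[, 2]], stringsAsFactors = FALSE)))
  contacts <- contacts[order(contacts$chain, contacts$resno), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 buried_area = ba, contribution_a = contrib_a,
                 contribution_b = contrib_b,
                 asa_a = asa_a, asa_b = asa_b, asa_ab = asa_ab,
                 contacts = contacts),
            class = "InterfaceReport")
}

#' Infer oligomeric assemblies from pairwise buried areas
#'
#' Scores every unordered chain pair, links pairs whose buried area reaches
#' the assembly threshold, and labels connected components by size
#' (monomer/dimer/trimer/tetramer/other).
#'
#' @param s a `Structure`.
#' @param threshold buried-area threshold in Angstrom^2 (default 500: well
#'   below a biological dimer interface, above crystal-packing noise).
#' @param ... passed to [buried_area()].
#' @return object of class `AssemblyGraph`: `edges` (pairs with areas),
#'   `components` (list of chain-id vectors), `labels`.
#' @export
detect_assemblies <- function(s, threshold = 500, ...) {
  chains <- structure_census(s)$chain_ids
  edges <- NULL
  if (length(chains) >= 2) {
    cmb <- utils::combn(chains, 2)
    for (k in seq_len(ncol(cmb))) {
      ir <- buried_area(s, cmb[1, k], cmb[2, k], ...)
      edges <- rbind(edges, data.frame(chain_a = cmb[1, k], chain_b = cmb[2, k],
                                       buried_area = ir$buried_area,
                                       stringsAsFactors = FALSE))
    }
  }
  # union-find over linked pairs
  parent <- stats::setNames(chains, chains)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (!is.null(edges)) {
    for (k in which(edges$buried_area >= threshold)) {
      ra <- find(edges$chain_a[k]); rb <- find(edges$chain_b[k])
      if (ra != rb) parent[[rb]] <- ra
    }
  }
  roots <- vapply(chains, find, character(1))
  comps <- split(chains, roots)
  names(comps) <- NULL
  comps <- comps[order(vapply(comps, function(x) x[1], character(1)))]
  size_label <- function(n) switch(as.character(n), "1" = "monomer", "2" = "dimer",
                                   "3" = "trimer", "4" = "tetramer", "other")
  labels <- vapply(comps, function(x) size_label(length(x)), character(1))
  structure(list(edges = edges, components = comps, labels = labels,
                 threshold = threshold),
            class = "AssemblyGraph")
}

#' Calibrate a size-exclusion column
#'
#' Least-squares line of log10(mass, kDa) against elution volume, or against
#' the partition coefficient Kav = (Ve - V0)/(Vc - V0) when column volumes
#' are supplied. On a valid standard set larger species elute earlier, so
#' the slope is negative; a positive slope is flagged, not an error.
#'
#' @param standards data.frame with columns `Ve` (mL) and `mass` (kDa).
#' @param V0,Vc optional void and column volumes (mL).
#' @return object of class `CalibrationCurve`: `slope`, `intercept`,
#'   `r_squared`, `on` ("Ve" or "Kav"), `V0`, `Vc`, `warning_positive_slope`.
#' @export
sec_calibrate <- function(standards, V0 = NULL, Vc = NULL) {
  if (nrow(standards) < 2) stop("need at least 2 standards")
  if (anyDuplicated(standards$Ve)) stop("duplicate elution volumes in standards")
  use_kav <- !is.null(V0) && !is.null(Vc)
  x <- if (use_kav) (standards$Ve - V0) / (Vc - V0) else standards$Ve
  fit <- lm(log10(standards$mass) ~ x)
  y <- log10(standards$mass)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  slope <- unname(coef(fit)[2])
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2, on = if (use_kav) "Kav" else "Ve",
                 V0 = V0, Vc = Vc,
                 Ve_range = range(standards$Ve),
                 warning_positive_slope = slope >= 0),
            class = "CalibrationCurve")
}

#' Apparent mass from a calibration curve
#'
#' @param curve a `CalibrationCurve`.
#' @param Ve elution volume(s), mL.
#' @return apparent mass in kDa (attribute `extrapolated` flags volumes
#'   outside the standard range).
#' @export
apparent_mass <- function(curve, Ve) {
  x <- if (curve$on == "Kav") (Ve - curve$V0) / (curve$Vc - curve$V0) else Ve
  m <- 10^(curve$slope * x + curve$intercept)
  attr(m, "extrapolated") <- Ve < curve$Ve_range[1] | Ve > curve$Ve_range[2]
  m
}

.gaussian_sum <- function(v, center, width, area, baseline) {
  y <- rep(baseline, length(v))
  for (k in seq_along(center))
    y <- y + area[k] / (width[k] * sqrt(2 * pi)) * exp(-(v - center[k])^2 / (2 * width[k]^2))
  y
}

#' Deconvolve a chromatogram into Gaussian peaks
#'
#' Nonlinear least squares (Levenberg-Marquardt) of a sum of symmetric
#' Gaussians plus a constant baseline; peak areas are constrained
#' non-negative. Non-convergence is flagged on the result, never thrown.
#'
#' @param chrom a `Chromatogram`.
#' @param n_peaks number of peaks to fit.
#' @param init_centers starting peak centers (mL), length `n_peaks`, within
#'   the volume range.
#' @param init_widths optional starting widths (mL); default 1/30 of the
#'   volume span.
#' @return object of class `PeakModel`: `peaks` data.frame (center, width,
#'   area), `baseline`, `residual_norm`, `converged`, `fitted`.
#' @export
deconvolve <- function(chrom, n_peaks, init_centers, init_widths = NULL) {
  stopifnot(inherits(chrom, "Chromatogram"), n_peaks >= 1)
  v <- chrom$volume; y <- chrom$absorbance
  if (length(init_centers) != n_peaks) stop("init_centers must have length n_peaks")
  if (any(init_centers < min(v) | init_centers > max(v)))
    stop("init centers outside the volume range")
  span <- diff(range(v))
  if (is.null(init_widths)) init_widths <- rep(span / 30, n_peaks)
  amp0 <- pmax(stats::approx(v, y, xout = init_centers)$y - min(y), 1e-3 * max(abs(y)))
  start <- c(init_centers, init_widths, amp0 * init_widths * sqrt(2 * pi), min(y))
  names(start) <- c(paste0("c", seq_len(n_peaks)), paste0("w", seq_len(n_peaks)),
                    paste0("a", seq_len(n_peaks)), "b0")
  lower <- c(rep(min(v) - span, n_peaks), rep(span * 1e-4, n_peaks),
             rep(0, n_peaks), -Inf)
  upper <- c(rep(max(v) + span, n_peaks), rep(span, n_peaks), rep(Inf, n_peaks), Inf)
  model_fn <- function(p) {
    .gaussian_sum(v, p[seq_len(n_peaks)], p[n_peaks + seq_len(n_peaks)],
                  p[2 * n_peaks + seq_len(n_peaks)], p[length(p)])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(p) y - model_fn(p),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    peaks <- data.frame(center = init_centers, width = init_widths,
                        area = rep(0, n_peaks))
    return(structure(list(peaks = peaks, baseline = min(y),
                          residual_norm = sqrt(sum((y - min(y))^2)),
                          converged = FALSE, fitted = rep(min(y), length(y))),
                     class = "PeakModel"))
  }
  p <- coef(fit)
  ord <- order(p[seq_len(n_peaks)])
  peaks <- data.frame(center = unname(p[seq_len(n_peaks)][ord]),
                      width = unname(p[n_peaks + seq_len(n_peaks)][ord]),
                      area = unname(p[2 * n_peaks + seq_len(n_peaks)][ord]))
  conv <- fit$info %in% 1:4
  structure(list(peaks = peaks, baseline = unname(p[length(p)]),
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = conv, fitted = model_fn(p)),
            class = "PeakModel")
}

#' Species repartition from fitted peak areas
#'
#' Percentages are proportional to peak area (mass-proportional absorbance
#' reading); a height-based mode is available for sensitivity analysis.
#'
#' @param model a `PeakModel`.
#' @param labels one species label per peak, in peak order.
#' @param by `"area"` (default) or `"height"`.
#' @return object of class `SpeciesRepartition`: data.frame `species`,
#'   `percent` (sums to 100).
#' @export
repartition <- function(model, labels, by = c("area", "height")) {
  by <- match.arg(by)
  stopifnot(inherits(model, "PeakModel"))
  if (length(labels) != nrow(model$peaks)) stop("one label per peak required")
  w <- if (by == "area") model$peaks$area
       else model$peaks$area / (model$peaks$width * sqrt(2 * pi))
  if (sum(w) <= 0) stop("zero total peak area")
  out <- data.frame(species = labels, percent = 100 * w / sum(w),
                    stringsAsFactors = FALSE)
  class(out) <- c("SpeciesRepartition", class(out))
  out
}

#' Sequence mass and 280 nm extinction coefficient
#'
#' Average molecular mass (residue masses + one water) and the standard
#' extinction coefficients: 5500 per Trp + 1490 per Tyr, plus 125 per
#' cystine pair in the disulfide-paired variant (all cysteines paired two
#' by two, rounded down).
#'
#' @param sequence one-letter protein sequence (string or character vector).
#' @return list: `mass` (Da), `epsilon_reduced`, `epsilon_cystine`
#'   (M^-1 cm^-1), residue counts `n_trp`, `n_tyr`, `n_cys`.
#' @export
mass_extinction <- function(sequence) {
  aa <- if (length(sequence) == 1) strsplit(toupper(sequence), "")[[1]] else toupper(sequence)
  aa <- aa[aa != ""]
  if (length(aa) == 0) stop("empty sequence")
  bad <- setdiff(unique(aa), names(.residue_masses))
  if (length(bad) > 0) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  mass <- sum(.residue_masses[aa]) + .water_mass
  n_trp <- sum(aa == "W"); n_tyr <- sum(aa == "Y"); n_cys <- sum(aa == "C")
  eps_red <- 5500 * n_trp + 1490 * n_tyr
  list(mass = unname(mass),
       epsilon_reduced = eps_red,
       epsilon_cystine = eps_red + 125 * (n_cys %/% 2),
       n_trp = n_trp, n_tyr = n_tyr, n_cys = n_cys)
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat("Interface", x$chain_a, "/", x$chain_b, "- buried area",
      round(x$buried_area, 1), "A^2 (", nrow(x$contacts), "contacting residues )\n")
  invisible(x)
}

#' @export
print.AssemblyGraph <- function(x, ...) {
  cat("AssemblyGraph (threshold", x$threshold, "A^2):\n")
  for (k in seq_along(x$components))
    cat("  ", x$labels[k], ":", paste(x$components[[k]], collapse = "+"), "\n")
  invisible(x)
}
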