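#' Detect disulfide bridges from SG-SG geometry
#'
#' Reports cysteine SG pairs within the covalent cutoff, intra- and
#' inter-chain. Each SG is assigned at most one partner by greedy
#' nearest-first matching, so three mutually close thiols cannot yield an
#' over-bonded census.
#'
#' @param s a `Structure`.
#' @param bond_cutoff SG-SG distance cutoff in Angstrom (default 2.3:
#'   covalent S-S is ~2.05 plus coordinate error at ~3 Angstrom resolution).
#' @return data.frame with `chain_a`, `resno_a`, `chain_b`, `resno_b`,
#'   `distance`; zero rows when no cysteines or none bonded.
#' @export
detect_disulfides <- function(s, bond_cutoff = 2.3) {
  stopifnot(bond_cutoff > 0)
  at <- s$atoms
  sg <- at[!at$solvent & at$resid == "CYS" & at$elety == "SG", , drop = FALSE]
  empty <- data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(sg) < 2) return(empty)
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  pairs <- which(d <= bond_cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(empty)
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(sg))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used[i] && !used[j]) { keep[k] <- TRUE; used[i] <- used[j] <- TRUE }
  }
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(chain_a = sg$chain[pairs[, 1]], resno_a = sg$resno[pairs[, 1]],
                    chain_b = sg$chain[pairs[, 2]], resno_b = sg$resno[pairs[, 2]],
                    distance = d[pairs], stringsAsFactors = FALSE)
  # canonical order: chain then resno
  flip <- out$chain_a > out$chain_b | (out$chain_a == out$chain_b & out$resno_a > out$resno_b)
  tmp <- out[flip, c("chain_b", "resno_b", "chain_a", "resno_a")]
  out[flip, c("chain_a", "resno_a", "chain_b", "resno_b")] <- tmp
  out[order(out$chain_a, out$resno_a), , drop = FALSE]
}

#' Cysteine census, classification and exchange candidates
#'
#' Every cysteine of the chosen chain is classified into exactly one of
#' `disulfide` (SG bonded to a partner SG), `exposed_free` (free thiol whose
#' SG area exceeds the exposure threshold), `buried_free`, or `unresolved`
#' (SG not modeled). Free-thiol pairs are tiered as dithiol/disulfide
#' exchange candidates: "direct" when the thiol-thiol distance permits
#' exchange without backbone motion, "rearrangement" when a main-chain
#' rearrangement would be required. The predicted DTNB-reactive count is the
#' number of exposed free thiols.
#'
#' @param s a `Structure`.
#' @param tab a `SasaTable` computed on `s` (same atom census). The reference
#'   analysis computes it in the biological-dimer context.
#' @param chain chain to report on (default: all chains).
#' @param bond_cutoff disulfide SG-SG cutoff (Angstrom).
#' @param direct_exchange_cutoff free thiol-thiol distance for a "direct"
#'   exchange candidate (default 5.0, covering observed 3.5 and 4.6 pairs).
#' @param rearrangement_cutoff distance for a "rearrangement"-tier candidate
#'   (default 11.0, covering observed 10.1 and 10.5 pairs).
#' @param exposure_threshold SG-area threshold (Angstrom^2) for exposed.
#' @return object of class `CysteineReport`: `cysteines` data.frame (chain,
#'   resno, sg_present, partner, nearest thiol + distance, exchange tier,
#'   sg_asa, class), `disulfides`, and `summary` with per-class counts and
#'   `predicted_reactive`.
#' @export
cysteine_report <- function(s, tab, chain = NULL, bond_cutoff = 2.3,
                            direct_exchange_cutoff = 5.0,
                            rearrangement_cutoff = 11.0,
                            exposure_threshold = 0.05) {
  stopifnot(inherits(s, "Structure"), inherits(tab, "SasaTable"))
  at <- s$atoms[!s$atoms$solvent, , drop = FALSE]
  if (!all(paste(tab$atoms$chain, tab$atoms$resno, tab$atoms$elety) %in%
           paste(at$chain, at$resno, at$elety)))
    stop("SasaTable does not match the structure")
  cys <- at[at$resid == "CYS", , drop = FALSE]
  key <- paste(cys$chain, cys$resno, cys$insert)
  first <- !duplicated(key)
  cysres <- cys[first, c("chain", "resno", "insert")]
  if (!is.null(chain)) cysres <- cysres[cysres$chain %in% chain, , drop = FALSE]
  ss <- detect_disulfides(s, bond_cutoff = bond_cutoff)
  sg <- cys[cys$elety == "SG", , drop = FALSE]
  sgkey <- paste(sg$chain, sg$resno, sg$insert)

  n <- nrow(cysres)
  entry <- data.frame(chain = cysres$chain, resno = cysres$resno,
                      insert = cysres$insert,
                      sg_present = logical(n),
                      partner_chain = rep(NA_character_, n),
                      partner_resno = rep(NA_integer_, n),
                      nearest_thiol_chain = rep(NA_character_, n),
                      nearest_thiol_resno = rep(NA_integer_, n),
                      nearest_thiol_distance = rep(NA_real_, n),
                      exchange_tier = rep(NA_character_, n),
                      sg_asa = rep(NA_real_, n), class = rep(NA_character_, n),
                      stringsAsFactors = FALSE)
  in_ss <- function(ch, rn) {
    hit <- (ss$chain_a == ch & ss$resno_a == rn) | (ss$chain_b == ch & ss$resno_b == rn)
    if (!any(hit)) return(NULL)
    r <- ss[which(hit)[1], ]
    if (r$chain_a == ch && r$resno_a == rn) c(r$chain_b, r$resno_b) else c(r$chain_a, r$resno_a)
  }
  bonded <- unique(c(paste(ss$chain_a, ss$resno_a), paste(ss$chain_b, ss$resno_b)))
  pr <- tab$per_residue
  for (i in seq_len(n)) {
    ch <- entry$chain[i]; rn <- entry$resno[i]; ic <- entry$insert[i]
    me <- which(sgkey == paste(ch, rn, ic))
    entry$sg_present[i] <- length(me) == 1
    if (!entry$sg_present[i]) { entry$class[i] <- "unresolved"; next }
    pix <- match(paste(ch, rn, ic), paste(pr$chain, pr$resno, pr$insert))
    entry$sg_asa[i] <- if (!is.na(pix)) pr$sg[pix] else NA_real_
    p <- in_ss(ch, rn)
    if (!is.null(p)) {
      entry$partner_chain[i] <- p[1]
      entry$partner_resno[i] <- as.integer(p[2])
      entry$class[i] <- "disulfide"
    } else {
      entry$class[i] <- if (!is.na(entry$sg_asa[i]) && entry$sg_asa[i] > exposure_threshold)
        "exposed_free" else "buried_free"
    }
    # nearest free thiol neighbor (among SGs not in a disulfide, excluding self)
    free_ix <- which(!(sgkey %in% bonded) & sgkey != paste(ch, rn, ic))
    if (length(free_ix) > 0) {
      dx <- sqrt((sg$x[free_ix] - sg$x[me])^2 + (sg$y[free_ix] - sg$y[me])^2 +
                   (sg$z[free_ix] - sg$z[me])^2)
      j <- free_ix[which.min(dx)]
      entry$nearest_thiol_chain[i] <- sg$chain[j]
      entry$nearest_thiol_resno[i] <- sg$resno[j]
      entry$nearest_thiol_distance[i] <- min(dx)
      if (entry$class[i] != "disulfide") {
        d <- min(dx)
        entry$exchange_tier[i] <- if (d <= direct_exchange_cutoff) "direct"
        else if (d <= rearrangement_cutoff) "rearrangement" else "none"
      }
    }
  }
  counts <- table(factor(entry$class,
                         levels = c("disulfide", "exposed_free", "buried_free", "unresolved")))
  summary <- list(n_cysteines = n,
                  n_disulfide = unname(counts["disulfide"]),
                  n_exposed_free = unname(counts["exposed_free"]),
                  n_buried_free = unname(counts["buried_free"]),
                  n_unresolved = unname(counts["unresolved"]),
                  predicted_reactive = unname(counts["exposed_free"]))
  structure(list(cysteines = entry, disulfides = ss, summary = summary,
                 parameters = list(bond_cutoff = bond_cutoff,
                                   direct_exchange_cutoff = direct_exchange_cutoff,
                                   rearrangement_cutoff = rearrangement_cutoff,
                                   exposure_threshold = exposure_threshold)),
            class = "CysteineReport")
}

#' DTNB (Ellman) thiol stoichiometry
#'
#' Free reactive thiols per protein monomer from the TNB- absorbance:
#' `A412 / (epsilon * path_length * protein_conc)`.
#'
#' @param A412 absorbance at 412 nm.
#' @param path_length cuvette path length, cm.
#' @param protein_conc protein concentration, mM.
#' @param epsilon TNB- molar extinction coefficient, mM^-1 cm^-1
#'   (default 14.15).
#' @return thiols per monomer (dimensionless).
#' @export
dtnb_stoichiometry <- function(A412, path_length = 1, protein_conc,
                               epsilon = 14.15) {
  if (protein_conc <= 0) stop("protein concentration must be positive")
  if (path_length <= 0) stop("path length must be positive")
  A412 / (epsilon * path_length * protein_conc)
}

#' Reconcile predicted reactive cysteines with a thiol titration
#'
#' Verdict is "consistent" iff the structure-predicted reactive count lies
#' within two standard deviations of the measured thiols-per-monomer.
#'
#' @param report a `CysteineReport`.
#' @param measured titrated thiols per monomer.
#' @param sd standard deviation of the measurement.
#' @return list with `predicted`, `measured`, `sd`, `interval`, `verdict`.
#' @export
reconcile_titration <- function(report, measured, sd) {
  stopifnot(inherits(report, "CysteineReport"))
  if (sd < 0) stop("sd must be non-negative")
  pred <- report$summary$predicted_reactive
  lo <- measured - 2 * sd; hi <- measured + 2 * sd
  list(predicted = pred, measured = measured, sd = sd,
       interval = c(lo, hi),
       verdict = if (pred >= lo && pred <= hi) "consistent" else "inconsistent")
}

#' Specific activity from a coupled NADP+ reduction assay
#'
#' Converts the A340 slope of the coupled phosphatase assay into
#' umol(NADPH) min^-1 mg^-1: `dA340 / (epsilon * l)` is the NADPH production
#' rate in mM/min; multiplied by the assay volume in mL (mM x mL = umol) and
#' divided by the enzyme mass in mg.
#'
#' @param dA340_per_min absorbance slope at 340 nm, min^-1 (negative values
#'   are clipped to zero with a warning).
#' @param epsilon_NADPH NADPH extinction coefficient, mM^-1 cm^-1
#'   (default 6.22).
#' @param path_length cm.
#' @param assay_volume mL.
#' @param enzyme_mass mg of enzyme in the assay.
#' @return specific activity, umol(NADPH) min^-1 mg^-1.
#' @export
specific_activity <- function(dA340_per_min, epsilon_NADPH = 6.22,
                              path_length = 1, assay_volume, enzyme_mass) {
  if (enzyme_mass <= 0) stop("enzyme mass must be positive")
  if (dA340_per_min < 0) {
    warning("negative slope clipped to zero")
    dA340_per_min <- 0
  }
  (dA340_per_min / (epsilon_NADPH * path_length)) * assay_volume / enzyme_mass
}

#' @export
print.CysteineReport <- function(x, ...) {
  s <- x$summary
  cat("CysteineReport:", s$n_cysteines, "cysteines |",
      s$n_disulfide, "disulfide,", s$n_exposed_free, "exposed free,",
      s$n_buried_free, "buried free,", s$n_unresolved, "unresolved |",
      "predicted reactive:", s$predicted_reactive, "\n")
  invisible(x)
}
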