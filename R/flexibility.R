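# Per-atom RMSF, per-residue B-factors, and flexibility hotspot selection.
#
# B-factors (atomic displacement parameters) report the positional
# smearing of atoms from thermal motion: B = (8 pi^2 / 3) <|dr|^2>. The
# residue with the largest B-factor over a simulated ensemble is the
# flexibility hotspot nominated for saturation mutagenesis.

BFACTOR_CONST <- 8 * pi^2 / 3

#' Root-mean-square fluctuation of each atom over an ensemble
#'
#' RMSF_i = sqrt(mean over frames of |r_i - <r_i>|^2). With
#' `superpose_first` (the default) every frame is first optimally
#' superposed onto the running mean structure, iterated until the mean
#' coordinates move by less than `tol` or `max_iter` rounds — this removes
#' global rigid-body drift so only internal motion is counted.
#'
#' @param ensemble an `xf_ensemble` with at least two frames.
#' @param selection,resno,chain passed to [select_atoms()].
#' @param superpose_first iteratively superpose frames onto the mean
#'   structure before measuring fluctuations (requires >= 3 selected
#'   atoms).
#' @param tol convergence threshold on the mean coordinates (Angstrom).
#' @param max_iter maximum superposition rounds.
#' @return Named numeric vector of per-atom RMSF (Angstrom), in selection
#'   order, with attribute `n_frames`.
#' @export
compute_rmsf <- function(ensemble, selection = "all", resno = NULL,
                         chain = NULL, superpose_first = TRUE,
                         tol = 1e-6, max_iter = 50) {
  sub <- select_atoms(ensemble, selection, resno = resno, chain = chain)
  nf <- n_frames(sub)
  if (nf < 2) stop("fluctuation undefined: ensemble has a single frame")
  coords <- sub$coords
  na <- dim(coords)[1]
  if (superpose_first) {
    if (na < 3) {
      stop("superposition requires >= 3 atoms; use superpose_first = FALSE")
    }
    mean_xyz <- apply(coords, c(1, 2), mean)
    for (iter in seq_len(max_iter)) {
      for (k in seq_len(nf)) {
        fit <- kabsch(coords[, , k], mean_xyz)
        coords[, , k] <- apply_transform(coords[, , k], fit)
      }
      new_mean <- apply(coords, c(1, 2), mean)
      delta <- max(abs(new_mean - mean_xyz))
      mean_xyz <- new_mean
      if (delta < tol) break
    }
  } else {
    mean_xyz <- apply(coords, c(1, 2), mean)
  }
  dev2 <- (coords - array(mean_xyz, dim = dim(coords)))^2
  rmsf <- sqrt(apply(dev2, 1, sum) / nf)
  names(rmsf) <- paste(sub$topology$atoms$chain, sub$topology$atoms$resno,
                       sub$topology$atoms$name, sep = ":")
  attr(rmsf, "n_frames") <- nf
  attr(rmsf, "topology") <- sub$topology
  rmsf
}

#' Convert RMSF to a crystallographic B-factor
#'
#' B = (8 pi^2 / 3) * RMSF^2, in Angstrom squared.
#'
#' @param rmsf non-negative fluctuation(s), Angstrom.
#' @return B-factor(s), Angstrom squared.
#' @export
rmsf_to_bfactor <- function(rmsf) {
  if (any(rmsf < 0)) stop("rmsf must be non-negative")
  BFACTOR_CONST * rmsf^2
}

#' Convert a B-factor back to an RMSF
#' @param bfactor non-negative B-factor(s), Angstrom squared.
#' @return RMSF, Angstrom.
#' @export
bfactor_to_rmsf <- function(bfactor) {
  if (any(bfactor < 0)) stop("bfactor must be non-negative")
  sqrt(bfactor / BFACTOR_CONST)
}

#' Aggregate per-atom B-factors into a per-residue flexibility profile
#'
#' @param bfactors per-atom B-factors as returned by
#'   [rmsf_to_bfactor()] applied to [compute_rmsf()] output (the topology
#'   travels along as an attribute), Angstrom squared.
#' @param topology an `xf_structure` matching `bfactors` element-wise;
#'   taken from the attribute when omitted.
#' @param aggregation `"ca"` (the C-alpha atom's value; default),
#'   `"mean-heavy"` (mean over non-hydrogen atoms) or `"max"`.
#' @return An `xf_flex_profile`: data.frame with `residue_number`,
#'   `residue_name`, `chain`, `bfactor` (A^2), `rmsf` (A); attributes
#'   `aggregation` and `n_frames`.
#' @export
residue_profile <- function(bfactors, topology = NULL,
                            aggregation = c("ca", "mean-heavy", "max")) {
  aggregation <- match.arg(aggregation)
  if (is.null(topology)) topology <- attr(bfactors, "topology")
  if (is.null(topology)) stop("topology must be supplied")
  atoms <- topology$atoms
  if (length(bfactors) != nrow(atoms)) {
    stop("bfactors length does not match topology atom count")
  }
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  res_ids <- unique(key)
  rows <- lapply(res_ids, function(id) {
    idx <- which(key == id)
    sub <- atoms[idx, ]
    b <- switch(aggregation,
      "ca" = {
        ca <- idx[sub$name == "CA"]
        if (length(ca) == 0) {
          stop(sprintf("residue %s %d (%s) has no CA atom",
                       sub$chain[1], sub$resno[1], sub$resname[1]))
        }
        bfactors[ca[1]]
      },
      "mean-heavy" = {
        hv <- idx[toupper(sub$element) != "H"]
        if (length(hv) == 0) {
          stop(sprintf("residue %s %d has no heavy atoms",
                       sub$chain[1], sub$resno[1]))
        }
        mean(bfactors[hv])
      },
      "max" = max(bfactors[idx])
    )
    data.frame(residue_number = sub$resno[1], residue_name = sub$resname[1],
               chain = sub$chain[1], bfactor = unname(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rmsf <- bfactor_to_rmsf(out$bfactor)
  rownames(out) <- NULL
  class(out) <- c("xf_flex_profile", "data.frame")
  attr(out, "aggregation") <- aggregation
  attr(out, "n_frames") <- attr(bfactors, "n_frames")
  out
}

#' One-shot per-residue flexibility profile from an ensemble
#'
#' Convenience wrapper: [compute_rmsf()] on the chosen atoms, conversion to
#' B-factors, then [residue_profile()]. With the default `"ca"`
#' aggregation the RMSF is computed on C-alpha atoms only.
#'
#' @inheritParams compute_rmsf
#' @inheritParams residue_profile
#' @return An `xf_flex_profile`.
#' @export
flexibility_profile <- function(ensemble,
                                aggregation = c("ca", "mean-heavy", "max"),
                                superpose_first = TRUE) {
  aggregation <- match.arg(aggregation)
  selection <- if (aggregation == "ca") "ca" else "heavy"
  rmsf <- compute_rmsf(ensemble, selection = selection,
                       superpose_first = superpose_first)
  residue_profile(rmsf_to_bfactor(rmsf), aggregation = aggregation)
}

#' Select the top-k flexibility hotspots of a profile
#'
#' Residues ranked by B-factor, descending; ties broken deterministically
#' in favour of the lower residue number.
#'
#' @param profile an `xf_flex_profile`.
#' @param k number of residues to return (default 1).
#' @return Integer vector of residue numbers, length `k`.
#' @export
select_hotspot <- function(profile, k = 1) {
  if (nrow(profile) == 0) stop("empty flexibility profile")
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(profile)) {
    stop(sprintf("k (%d) exceeds the number of residues (%d)",
                 k, nrow(profile)))
  }
  ord <- order(-profile$bfactor, profile$residue_number)
  profile$residue_number[ord[seq_len(k)]]
}
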