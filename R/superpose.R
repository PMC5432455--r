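# Rigid-body superposition (Kabsch) and C-alpha RMSD trajectory analysis.
#
# RMSD of a frame from a reference, after optimal superposition, is the
# classic rigidity readout of high-temperature simulations: a variant whose
# post-equilibration RMSD stays below the wild type's is predicted to be
# the more thermostable protein.

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (optionally weighted) RMSD between `mobile` and `target`:
#' mapped coordinates are `(mobile - centroid_m) %*% R + centroid_t`.
#' Reflections are excluded: if the raw SVD solution is improper, the
#' singular direction with the smallest singular value is sign-flipped so
#' that `det(R) = +1`.
#'
#' @param mobile n x 3 coordinate matrix to move.
#' @param target n x 3 coordinate matrix to match.
#' @param weights optional non-negative per-point weights.
#' @return A list with `rotation` (3 x 3, det +1), `translation`
#'   (length-3), and `rmsd` (Angstrom), the minimum over all rigid motions.
#' @export
kabsch <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) {
    stop("mobile and target must have the same number of points")
  }
  if (nrow(mobile) < 3) stop("at least 3 points are required")
  if (ncol(mobile) != 3 || ncol(target) != 3) stop("coordinates must be n x 3")
  n <- nrow(mobile)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  H <- crossprod(P * w, Q)            # t(P) %*% diag(w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  moved <- P %*% R
  rmsd <- sqrt(sum(w * rowSums((moved - Q)^2)))
  list(rotation = R, translation = ct - as.numeric(cm %*% R), rmsd = rmsd)
}

#' Apply a Kabsch fit to coordinates
#' @param coords n x 3 matrix.
#' @param fit result of [kabsch()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, fit$translation, "+")
}

#' RMSD of an ensemble against a reference, frame by frame
#'
#' Each frame is first optimally superposed onto the reference by
#' [kabsch()], so global rigid motion contributes nothing. The default
#' reference is the first frame (the "original configuration"); an external
#' reference structure may be supplied instead. The default selection is
#' C-alpha atoms.
#'
#' @param ensemble an `xf_ensemble`.
#' @param reference `"first-frame"` or `"structure"`.
#' @param ref_structure an `xf_structure` used when
#'   `reference = "structure"`; its selected atom count must match.
#' @param selection,resno,chain passed to [select_atoms()].
#' @param times optional per-frame time stamps (e.g. ns); defaults to
#'   frame indices starting at 0.
#' @return An `xf_rmsd_series`: list with `times`, `values` (Angstrom),
#'   `reference`, `selection`.
#' @export
rmsd_series <- function(ensemble, reference = c("first-frame", "structure"),
                        ref_structure = NULL, selection = "ca",
                        resno = NULL, chain = NULL, times = NULL) {
  reference <- match.arg(reference)
  sub <- select_atoms(ensemble, selection, resno = resno, chain = chain)
  nf <- n_frames(sub)
  if (reference == "structure") {
    if (is.null(ref_structure)) stop("ref_structure must be supplied")
    ref_sub <- select_atoms(ref_structure, selection, resno = resno,
                            chain = chain)
    ref <- coords_matrix(ref_sub)
    ref_label <- sprintf("structure '%s'", ref_structure$identifier)
  } else {
    ref <- frame_coords(sub, 1)
    ref_label <- "first frame"
  }
  if (nrow(ref) != dim(sub$coords)[1]) {
    stop("reference atom count does not match the selection")
  }
  values <- vapply(seq_len(nf), function(k) {
    kabsch(frame_coords(sub, k), ref)$rmsd
  }, numeric(1))
  if (is.null(times)) times <- seq_len(nf) - 1
  structure(list(times = times, values = values, reference = ref_label,
                 selection = selection),
            class = "xf_rmsd_series")
}

#' @export
print.xf_rmsd_series <- function(x, ...) {
  cat(sprintf("<RMSD series: %d frames vs %s (%s atoms); mean %.3f A>\n",
              length(x$values), x$reference, x$selection, mean(x$values)))
  invisible(x)
}

#' Compare the post-equilibration stability of two RMSD series
#'
#' The series with the lower mean RMSD after the equilibration point is
#' called the more stable; means closer than `tolerance` (relative to the
#' larger mean) are indistinguishable. `pointwise = TRUE` additionally
#' requires strict frame-by-frame dominance over the post-equilibration
#' window for a verdict (the stricter "lower at any time" reading).
#'
#' @param series_a,series_b `xf_rmsd_series` objects (or numeric vectors).
#' @param equilibration_start 1-based index of the first equilibrated
#'   frame; default discards the first `equil_frac` of frames.
#' @param equil_frac fraction of initial frames treated as equilibration
#'   when `equilibration_start` is not given (default 0.2).
#' @param tolerance relative mean difference below which the verdict is
#'   `"indistinguishable"` (default 0.05).
#' @param pointwise require strict pointwise dominance as well.
#' @return An `xf_stability`: list with `mean_a`, `mean_b`,
#'   `equilibration_start`, `verdict` in `{"a_more_stable",
#'   "b_more_stable", "indistinguishable"}`.
#' @export
compare_stability <- function(series_a, series_b, equilibration_start = NULL,
                              equil_frac = 0.2, tolerance = 0.05,
                              pointwise = FALSE) {
  va <- if (inherits(series_a, "xf_rmsd_series")) series_a$values else series_a
  vb <- if (inherits(series_b, "xf_rmsd_series")) series_b$values else series_b
  n <- min(length(va), length(vb))
  if (is.null(equilibration_start)) {
    equilibration_start <- floor(n * equil_frac) + 1
  }
  if (equilibration_start > length(va) || equilibration_start > length(vb)) {
    stop("equilibration_start beyond series length")
  }
  pa <- va[equilibration_start:length(va)]
  pb <- vb[equilibration_start:length(vb)]
  ma <- mean(pa)
  mb <- mean(pb)
  rel <- abs(ma - mb) / max(ma, mb, .Machine$double.eps)
  verdict <- if (rel < tolerance) {
    "indistinguishable"
  } else if (ma < mb) "a_more_stable" else "b_more_stable"
  if (pointwise && verdict != "indistinguishable") {
    m <- min(length(pa), length(pb))
    dom_a <- all(pa[seq_len(m)] < pb[seq_len(m)])
    dom_b <- all(pb[seq_len(m)] < pa[seq_len(m)])
    if (verdict == "a_more_stable" && !dom_a) verdict <- "indistinguishable"
    if (verdict == "b_more_stable" && !dom_b) verdict <- "indistinguishable"
  }
  structure(list(mean_a = ma, mean_b = mb,
                 equilibration_start = equilibration_start,
                 verdict = verdict),
            class = "xf_stability")
}

#' @export
print.xf_stability <- function(x, ...) {
  cat(sprintf(
    "<stability: mean A %.3f A vs mean B %.3f A (frames >= %d) -> %s>\n",
    x$mean_a, x$mean_b, x$equilibration_start, x$verdict))
  invisible(x)
}
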