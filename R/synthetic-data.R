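# Seeded synthetic-data generators with planted ground truth.
#
# These stand in for the inputs the workflow normally takes from molecular
# dynamics (coordinate ensembles), homology modelling (wild-type/variant
# structure pairs), sequence databases (homolog alignments) and assay
# plates (kinetics, decay, melting and activity-profile readouts). Every
# generator is deterministic under its seed and returns the planted truth
# alongside the data so tests never re-derive it.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

backbone_template <- function(n_residues, resnames) {
  # residues laid on a gentle helix-like curve, ~3.8 A CA-CA spacing,
  # with N/CA/C/O (+CB for non-Gly) pseudo-atoms
  t <- seq_len(n_residues)
  ca <- cbind(8 * cos(t / 3), 8 * sin(t / 3), 1.5 * t)
  rows <- lapply(t, function(i) {
    base <- ca[i, ]
    names_i <- c("N", "CA", "C", "O")
    offs <- rbind(c(-1.2, 0.5, 0), c(0, 0, 0), c(1.2, 0.4, 0.3),
                  c(1.6, 1.5, 0.3))
    if (resnames[i] != "GLY") {
      names_i <- c(names_i, "CB")
      offs <- rbind(offs, c(-0.5, -1.3, 0.5))
    }
    data.frame(name = names_i,
               element = substr(names_i, 1, 1),
               resname = resnames[i], resno = i, chain = "A", het = FALSE,
               x = base[1] + offs[, 1], y = base[2] + offs[, 2],
               z = base[3] + offs[, 3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a coordinate ensemble with a planted flexibility hotspot
#'
#' Residues sit on a smooth backbone; every atom of residue `i` jitters
#' i.i.d. Gaussian (per axis) with that residue's planted sigma —
#' `hotspot_sigma` at the hotspot, `background_sigma` elsewhere.
#' Optionally each frame is additionally moved by a random global
#' rigid-body rotation and translation, which superposition must undo.
#'
#' @param n_residues chain length (default 30).
#' @param n_frames frames to draw (default 500).
#' @param hotspot planted hotspot residue number (default 21).
#' @param hotspot_sigma per-axis jitter at the hotspot, Angstrom
#'   (default 1.0).
#' @param background_sigma per-axis jitter elsewhere, Angstrom
#'   (default 0.3; a 2x amplitude contrast would be 0.5 vs 1.0).
#' @param rigid_motion superimpose a random global rotation/translation
#'   per frame (default TRUE).
#' @param seed RNG seed.
#' @return List with `ensemble` (an `xf_ensemble`) and `truth` (list:
#'   `hotspot`, `sigma` per residue, `expected_bfactor` per residue).
#' @export
gen_ensemble <- function(n_residues = 30, n_frames = 500, hotspot = 21,
                         hotspot_sigma = 1.0, background_sigma = 0.3,
                         rigid_motion = TRUE, seed = 1) {
  if (n_residues < 2 || n_frames < 2) stop("need >= 2 residues and frames")
  if (hotspot_sigma < 0 || background_sigma < 0) {
    stop("jitter amplitudes must be non-negative")
  }
  with_seed(seed, {
    resnames <- rep("ALA", n_residues)
    resnames[hotspot] <- "GLY"
    atoms <- backbone_template(n_residues, resnames)
    topo <- new_structure(atoms, identifier = "synthetic-ensemble")
    base <- coords_matrix(topo)
    sigma <- rep(background_sigma, n_residues)
    sigma[hotspot] <- hotspot_sigma
    atom_sigma <- sigma[atoms$resno]
    na <- nrow(atoms)
    coords <- array(NA_real_, dim = c(na, 3, n_frames))
    for (k in seq_len(n_frames)) {
      frame <- base + matrix(stats::rnorm(na * 3, sd = atom_sigma), na, 3)
      if (rigid_motion) {
        R <- random_rotation()
        shift <- stats::runif(3, -20, 20)
        frame <- sweep(frame %*% R, 2, shift, "+")
      }
      coords[, , k] <- frame
    }
    list(ensemble = new_ensemble(topo, coords),
         truth = list(hotspot = hotspot, sigma = sigma,
                      expected_bfactor = BFACTOR_CONST * 3 * sigma^2))
  })
}

# named side-chain carbon pools per hydrophobic residue type
SC_CARBON_POOL <- list(ILE = c("CB", "CG1", "CG2", "CD1"),
                       LEU = c("CB", "CG", "CD1", "CD2"),
                       VAL = c("CB", "CG1", "CG2"))

default_lost_pairs <- function() list(c(3, 16), c(58, 74))
default_gained_pairs <- function() {
  list(c(21, 41), c(34, 172), c(71, 74), c(73, 87), c(74, 172),
       c(102, 115), c(113, 115), c(115, 162), c(157, 160))
}

#' Generate a wild-type/variant structure pair with a planted
#' interaction diff
#'
#' Backbone C-alpha atoms sit on a sparse lattice; each planted contact
#' gets a dedicated, well-separated "zone" in which one side-chain carbon
#' (or the acidic O / basic N of the planted salt bridge) from each
#' partner residue is placed `contact_distance` apart — inside the
#' detection cutoff, while every non-planted atom pair stays outside the
#' cutoffs by a wide margin. Structure A carries `shared + lost`
#' contacts, structure B `shared + gained` (plus the salt bridge), so
#' [diff_interactions()] must recover the planted lists exactly.
#'
#' @param lost_hydrophobic,gained_hydrophobic lists of residue-number
#'   pairs planted only in A (lost) or only in B (gained); defaults mirror
#'   a two-lost/nine-gained engineering scenario.
#' @param gained_salt list of residue pairs planted as salt bridges in B
#'   only (default one, Glu84-Arg120).
#' @param shared_hydrophobic residue pairs present in both structures.
#' @param contact_distance planted atom-atom distance for hydrophobic
#'   contacts, Angstrom (default 4.0; salt bridges use 3.0).
#' @param seed RNG seed (small positional jitter only).
#' @return List with `wild_type`, `variant` (both `xf_structure`) and
#'   `truth` (planted pair lists).
#' @export
gen_structure_pair <- function(lost_hydrophobic = default_lost_pairs(),
                               gained_hydrophobic = default_gained_pairs(),
                               gained_salt = list(c(84, 120)),
                               shared_hydrophobic = list(c(34, 71),
                                                         c(102, 113)),
                               contact_distance = 4.0, seed = 1) {
  if (contact_distance >= 5.0 || contact_distance < 1.5) {
    stop("contact_distance must lie in [1.5, 5.0)")
  }
  with_seed(seed, {
    hyd_a <- c(shared_hydrophobic, lost_hydrophobic)
    hyd_b <- c(shared_hydrophobic, gained_hydrophobic)
    all_pairs <- c(hyd_a, hyd_b, gained_salt)
    if (any(vapply(all_pairs, function(p) abs(p[1] - p[2]) < 2, logical(1)))) {
      stop("planted pairs must respect the minimum sequence separation of 2")
    }
    hyd_res <- sort(unique(unlist(c(hyd_a, hyd_b))))
    salt_res <- sort(unique(unlist(gained_salt)))
    if (length(intersect(hyd_res, salt_res)) > 0) {
      stop("a residue cannot be planted both hydrophobic and charged")
    }
    all_res <- sort(unique(c(hyd_res, salt_res)))
    # degree check against the side-chain atom pool
    build <- function(hyd_pairs, salt_pairs, label) {
      degree <- table(factor(unlist(hyd_pairs), levels = hyd_res))
      resname <- stats::setNames(rep("ALA", length(all_res)),
                                 all_res)
      resname[as.character(hyd_res)] <- "ILE"
      for (sp in salt_pairs) {
        resname[as.character(sp[1])] <- "GLU"
        resname[as.character(sp[2])] <- "ARG"
      }
      if (any(degree > 4)) {
        stop("infeasible placement: a residue participates in more than 4 contacts")
      }
      # backbone lattice, 14 A spacing, far from the contact zones
      rows <- lapply(seq_along(all_res), function(i) {
        r <- all_res[i]
        data.frame(name = "CA", element = "C",
                   resname = unname(resname[as.character(r)]), resno = r,
                   chain = "A", het = FALSE,
                   x = 14 * (i %% 8), y = 14 * (i %/% 8), z = -60,
                   stringsAsFactors = FALSE)
      })
      used <- stats::setNames(integer(length(all_res)), all_res)
      zone <- 0
      plant <- function(pair, d, name_fun_a, name_fun_b) {
        zone <<- zone + 1
        centre <- c(16 * (zone %% 10), 16 * (zone %/% 10), 40)
        jitter <- stats::runif(3, -0.2, 0.2)
        centre <- centre + jitter
        lapply(seq_along(pair), function(j) {
          r <- pair[j]
          used[as.character(r)] <<- used[as.character(r)] + 1
          nm <- if (j == 1) name_fun_a(r) else name_fun_b(r)
          pos <- centre + c((if (j == 1) -d / 2 else d / 2), 0, 0)
          data.frame(name = nm, element = substr(nm, 1, 1),
                     resname = unname(resname[as.character(r)]), resno = r,
                     chain = "A", het = FALSE,
                     x = pos[1], y = pos[2], z = pos[3],
                     stringsAsFactors = FALSE)
        })
      }
      sc_name <- function(r) {
        pool <- SC_CARBON_POOL[["ILE"]]
        pool[used[as.character(r)]]
      }
      planted <- list()
      for (p in hyd_pairs) {
        planted <- c(planted, plant(p, contact_distance, sc_name, sc_name))
      }
      for (p in salt_pairs) {
        planted <- c(planted,
                     plant(p, 3.0, function(r) "OE1", function(r) "NH1"))
      }
      atoms <- do.call(rbind, c(rows, planted))
      atoms$element <- ifelse(substr(atoms$name, 1, 1) == "O", "O",
                              ifelse(substr(atoms$name, 1, 1) == "N", "N",
                                     "C"))
      atoms <- atoms[order(atoms$resno), , drop = FALSE]
      new_structure(atoms, identifier = label)
    }
    wt <- build(hyd_a, list(), "synthetic-wild-type")
    mut <- build(hyd_b, gained_salt, "synthetic-variant")
    list(wild_type = wt, variant = mut,
         truth = list(lost_hydrophobic = lost_hydrophobic,
                      gained_hydrophobic = gained_hydrophobic,
                      gained_salt = gained_salt,
                      shared_hydrophobic = shared_hydrophobic))
  })
}

#' Generate a homolog alignment with planted consensus candidates
#'
#' Homolog rows derive from a common consensus sequence with a small
#' per-column substitution rate; at each planted position the target
#' carries `target_residue` while a planted fraction of homologs carry
#' `consensus_residue`. Optional insert columns (target gapped) shift
#' alignment columns away from ungapped target positions to exercise the
#' position mapping.
#'
#' @param n_homologs homolog rows besides the target (default 7).
#' @param length_aa ungapped target length (default 40).
#' @param planted list of planted candidates, each a list with `pos`
#'   (ungapped target position), `target_residue`, `consensus_residue`,
#'   `support` (fraction of homologs).
#' @param substitution_rate background per-column homolog substitution
#'   rate (default 0.05).
#' @param n_insert_columns columns where the target is gapped
#'   (default 2).
#' @param seed RNG seed.
#' @return List with `alignment` (an `xf_alignment`, target first) and
#'   `truth` (planted candidates).
#' @export
gen_msa <- function(n_homologs = 7, length_aa = 40,
                    planted = list(list(pos = 13, target_residue = "Y",
                                        consensus_residue = "F",
                                        support = 6 / 7)),
                    substitution_rate = 0.05, n_insert_columns = 2,
                    seed = 1) {
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
  with_seed(seed, {
    consensus <- sample(aa20, length_aa, replace = TRUE)
    planted_pos <- vapply(planted, `[[`, numeric(1), "pos")
    target <- consensus
    rows <- replicate(n_homologs, {
      r <- consensus
      flip <- stats::runif(length_aa) < substitution_rate &
        !(seq_len(length_aa) %in% planted_pos)
      r[flip] <- vapply(which(flip), function(i) {
        sample(setdiff(aa20, consensus[i]), 1)
      }, character(1))
      r
    }, simplify = FALSE)
    for (p in planted) {
      i <- p$pos
      target[i] <- p$target_residue
      n_carry <- round(p$support * n_homologs)
      other <- setdiff(aa20, c(p$consensus_residue, p$target_residue))
      for (h in seq_len(n_homologs)) {
        rows[[h]][i] <- if (h <= n_carry) p$consensus_residue else
          sample(other, 1)
      }
    }
    # insert target-gap columns at random interior points
    if (n_insert_columns > 0) {
      at <- sort(sample(seq_len(length_aa - 1), n_insert_columns))
      insert <- function(v, fill) {
        out <- v
        for (j in rev(seq_along(at))) {
          out <- append(out, fill(), after = at[j])
        }
        out
      }
      target <- insert(target, function() "-")
      rows <- lapply(rows, function(r) {
        insert(r, function() sample(aa20, 1))
      })
    }
    aln <- new_alignment(
      names = c("target", paste0("homolog", seq_len(n_homologs))),
      rows = vapply(c(list(target), rows), paste, character(1),
                    collapse = ""),
      target_name = "target"
    )
    list(alignment = aln, truth = list(planted = planted))
  })
}

#' Generate a Michaelis-Menten rate curve
#'
#' @param Km,Vmax planted parameters (mg/mL, U/mg).
#' @param substrate concentration grid, mg/mL (default 1 to 10, the usual
#'   xylan assay range).
#' @param noise_cv multiplicative Gaussian noise CV on rates (default
#'   0.003, emulating replicate-averaged rates).
#' @param seed RNG seed.
#' @return List with `data` (data.frame `S`, `v`) and `truth`.
#' @export
gen_mm_curve <- function(Km = 2.32, Vmax = 100,
                         substrate = seq(1, 10, length.out = 10),
                         noise_cv = 0.003, seed = 1) {
  with_seed(seed, {
    v <- Vmax * substrate / (Km + substrate)
    v <- v * (1 + stats::rnorm(length(v), sd = noise_cv))
    list(data = data.frame(S = substrate, v = v),
         truth = list(Km = Km, Vmax = Vmax))
  })
}

#' Generate a first-order thermal-inactivation decay curve
#'
#' @param t_half planted half-life, min.
#' @param times sampling times, min (default 8 points over 1.5
#'   half-lives, starting at 0).
#' @param noise_cv multiplicative noise CV on residuals after time zero
#'   (default 0.01).
#' @param seed RNG seed.
#' @return List with `data` (data.frame `time`, `residual`) and `truth`.
#' @export
gen_decay_curve <- function(t_half = 240,
                            times = seq(0, 1.5 * t_half, length.out = 8),
                            noise_cv = 0.01, seed = 1) {
  with_seed(seed, {
    residual <- exp(-log(2) * times / t_half)
    eps <- stats::rnorm(length(times), sd = noise_cv)
    eps[times == 0] <- 0
    residual <- pmin(residual * (1 + eps), 1)
    list(data = data.frame(time = times, residual = residual),
         truth = list(t_half = t_half, k = log(2) / t_half))
  })
}

#' Generate a thermal-shift melting curve (Boltzmann sigmoid)
#'
#' `F(T) = baseline + amplitude / (1 + exp((tm - T)/slope)) + noise`; the
#' planted `tm` is the sigmoid midpoint, i.e. the derivative-curve peak.
#' The default grid mirrors a 30-80 degC scan at 0.5 degC resolution.
#'
#' @param tm planted melting temperature, degC.
#' @param slope sigmoid slope parameter, degC (default 1.5).
#' @param temperature scan grid (default `seq(30, 80, by = 0.5)`).
#' @param baseline,amplitude fluorescence baseline and transition height.
#' @param noise_sd additive Gaussian noise SD (default 0.003, i.e. 0.3%
#'   of the default amplitude).
#' @param seed RNG seed.
#' @return List with `data` (data.frame `temperature`, `fluorescence`)
#'   and `truth`.
#' @export
gen_melt_curve <- function(tm = 61.3, slope = 1.5,
                           temperature = seq(30, 80, by = 0.5),
                           baseline = 0, amplitude = 1, noise_sd = 0.003,
                           seed = 1) {
  with_seed(seed, {
    f <- baseline + amplitude / (1 + exp((tm - temperature) / slope)) +
      stats::rnorm(length(temperature), sd = noise_sd)
    list(data = data.frame(temperature = temperature, fluorescence = f),
         truth = list(tm = tm, slope = slope))
  })
}

#' Generate a bell-shaped pH or temperature activity profile
#'
#' Gaussian bell around the planted optimum, renormalized to 100% at the
#' peak, with multiplicative noise. The planted stable range is computed
#' from the noiseless curve at the retention threshold.
#'
#' @param optimum planted optimum (pH units or degC).
#' @param width Gaussian width (same units).
#' @param x measurement grid.
#' @param noise_cv multiplicative noise CV (default 0.01).
#' @param retention_threshold threshold defining the planted stable
#'   range (default 0.85).
#' @param seed RNG seed.
#' @return List with `data` (data.frame `x`, `activity`) and `truth`
#'   (`optimum`, `stable_range`).
#' @export
gen_activity_profile <- function(optimum = 60, width = 8,
                                 x = seq(40, 70, by = 2.5),
                                 noise_cv = 0.01,
                                 retention_threshold = 0.85, seed = 1) {
  with_seed(seed, {
    clean <- 100 * exp(-(x - optimum)^2 / (2 * width^2))
    ok <- clean >= 100 * retention_threshold
    opt_i <- which.max(clean)
    lo <- opt_i; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    hi <- opt_i; while (hi < length(x) && ok[hi + 1]) hi <- hi + 1
    act <- clean * (1 + stats::rnorm(length(x), sd = noise_cv))
    list(data = data.frame(x = x, activity = act),
         truth = list(optimum = x[opt_i], stable_range = c(x[lo], x[hi])))
  })
}

#' Generate a two-stage saturation-library screening table
#'
#' Stage 1 mimics a short heat challenge that a handful of substitutions
#' survive (> 80% residual activity); stage 2 extends the challenge for
#' the stage-1 survivors. The default stage-2 residuals plant Ile as the
#' best variant.
#'
#' @param stage1 named residual-activity fractions for the stage-1 panel.
#' @param stage2 named residual-activity fractions for the stage-2
#'   survivors.
#' @param position mutated residue number used in variant labels
#'   (default 21).
#' @param wild_type_residue 1-letter code of the wild-type residue
#'   (default "G").
#' @return List with `records` (data.frame `variant`, `residual`,
#'   `stage`) and `truth` (`best`, `stage1_survivors`).
#' @export
gen_screen_table <- function(stage1 = c(F = 0.92, V = 0.88, L = 0.90,
                                        R = 0.83, Y = 0.85, H = 0.82,
                                        I = 0.95, A = 0.40, S = 0.25,
                                        G = 0.05),
                             stage2 = c(F = 0.393, V = 0.305, L = 0.371,
                                        I = 0.573),
                             position = 21, wild_type_residue = "G") {
  label <- function(aa) paste0(wild_type_residue, position, aa)
  records <- rbind(
    data.frame(variant = label(names(stage1)), residual = unname(stage1),
               stage = 1L, stringsAsFactors = FALSE),
    data.frame(variant = label(names(stage2)), residual = unname(stage2),
               stage = 2L, stringsAsFactors = FALSE)
  )
  best <- label(names(stage2)[which.max(stage2)])
  list(records = records,
       truth = list(best = best,
                    stage1_survivors = label(names(stage1)[stage1 > 0.8])))
}

#' Write a full set of synthetic assay inputs with a truth sidecar
#'
#' Emits CSV files (`mm.csv`, `decay.csv`, `melt.csv`, `profile.csv`,
#' `screen.csv`) plus `truth.json` into `dir`, in the two-column formats
#' the characterization functions read.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param ... overrides forwarded to the individual generators as
#'   list-arguments `mm`, `decay`, `melt`, `profile`, `screen`.
#' @return Invisibly, the list of planted truths.
#' @export
gen_assay_curves <- function(dir, seed = 1, ...) {
  dots <- list(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mm <- do.call(gen_mm_curve, c(list(seed = seed), dots$mm))
  decay <- do.call(gen_decay_curve, c(list(seed = seed + 1), dots$decay))
  melt <- do.call(gen_melt_curve, c(list(seed = seed + 2), dots$melt))
  prof <- do.call(gen_activity_profile, c(list(seed = seed + 3),
                                          dots$profile))
  scr <- do.call(gen_screen_table, dots$screen %||% list())
  utils::write.csv(mm$data, file.path(dir, "mm.csv"), row.names = FALSE)
  utils::write.csv(decay$data, file.path(dir, "decay.csv"),
                   row.names = FALSE)
  utils::write.csv(melt$data, file.path(dir, "melt.csv"),
                   row.names = FALSE)
  utils::write.csv(prof$data, file.path(dir, "profile.csv"),
                   row.names = FALSE)
  utils::write.csv(scr$records, file.path(dir, "screen.csv"),
                   row.names = FALSE)
  truth <- list(mm = mm$truth, decay = decay$truth, melt = melt$truth,
                profile = prof$truth, screen = scr$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
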