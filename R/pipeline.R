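# Workflow orchestration: run the stages named in a config, collect one
# design report, and write it as JSON plus readable text.
#
# Stages are independently optional and run in dependency order:
# flexibility -> consensus -> library -> stability -> interactions ->
# enzymology/screening. Every number in the report traces to a module
# output, and each input file is recorded with its md5 checksum.

#' Read a sectioned key = value configuration file
#'
#' Minimal flat format: `[section]` headers, `key = value` lines, `#`
#' comments. Values are auto-converted to numeric where possible.
#'
#' @param path config file.
#' @return Nested named list, one element per section.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- cfg[[section]] %||% list()
    } else if (grepl("=", ln)) {
      if (is.null(section)) stop("key outside a [section]: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      num <- suppressWarnings(as.numeric(val))
      cfg[[section]][[key]] <- if (!is.na(num)) num else val
    } else {
      stop("unparseable config line: ", ln)
    }
  }
  cfg
}

checksum_of <- function(path) {
  unname(tools::md5sum(path))
}

#' Run the thermostabilization design pipeline
#'
#' `config` is a nested list (or the path of a file readable by
#' [read_pipeline_config()]) with any of the sections below; each section
#' runs one stage and contributes one block to the report.
#'
#' * `flexibility`: `ensemble` (multi-model PDB/XYZ path), optional
#'   `aggregation`, `top`.
#' * `stability`: `ensemble_a`, `ensemble_b`, optional `equil_frac`.
#' * `consensus`: `alignment` (path), optional `target`, `min_identity`,
#'   `min_support`.
#' * `interactions`: `pdb_a`, `pdb_b` (or only `pdb_a` for a single
#'   structure), optional `hydrophobic_cutoff`, `saltbridge_cutoff`.
#' * `library`: `codon` (IUPAC triad), optional `confidence`.
#' * `screen`: `csv` (columns variant, residual, stage), optional
#'   `threshold`.
#' * `kinetics`: `csv` (columns S, v), optional `mw_kda`, and optional
#'   `reference_kcat`/`reference_km` for fold comparisons.
#' * `halflife`: `csv` (columns time, residual), optional `mode`,
#'   `reference_t_half`.
#' * `tm`: `csv` (columns temperature, fluorescence).
#' * `profile`: `csv` (columns x, activity), optional `threshold`.
#'
#' @param config nested list or config-file path.
#' @param out_json optional path for the JSON report.
#' @param out_text optional path for the human-readable report.
#' @return The design report, an `xf_report` (nested list), invisibly
#'   when written to file.
#' @export
run_pipeline <- function(config, out_json = NULL, out_text = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.list(config) || length(config) == 0) {
    stop("usage: config must name at least one stage section")
  }
  report <- list(inputs = list())
  note_input <- function(label, path) {
    report$inputs[[label]] <<- list(path = path, md5 = checksum_of(path))
  }

  if (!is.null(config$flexibility)) {
    cf <- config$flexibility
    if (is.null(cf$ensemble)) stop("flexibility stage: 'ensemble' input missing")
    note_input("flexibility.ensemble", cf$ensemble)
    ens <- read_ensemble(cf$ensemble)
    prof <- flexibility_profile(ens,
                                aggregation = cf$aggregation %||% "ca")
    top <- select_hotspot(prof, k = cf$top %||% 1)
    report$hotspot <- list(
      residues = top,
      bfactor = prof$bfactor[match(top, prof$residue_number)],
      aggregation = attr(prof, "aggregation"),
      n_frames = attr(prof, "n_frames"))
    report$flexibility_profile <- as.data.frame(prof)
  }

  if (!is.null(config$stability)) {
    cf <- config$stability
    if (is.null(cf$ensemble_a) || is.null(cf$ensemble_b)) {
      stop("stability stage: 'ensemble_a'/'ensemble_b' inputs missing")
    }
    note_input("stability.ensemble_a", cf$ensemble_a)
    note_input("stability.ensemble_b", cf$ensemble_b)
    sa <- rmsd_series(read_ensemble(cf$ensemble_a))
    sb <- rmsd_series(read_ensemble(cf$ensemble_b))
    cmp <- compare_stability(sa, sb, equil_frac = cf$equil_frac %||% 0.2)
    report$stability <- list(mean_a = cmp$mean_a, mean_b = cmp$mean_b,
                             equilibration_start = cmp$equilibration_start,
                             verdict = cmp$verdict)
  }

  if (!is.null(config$consensus)) {
    cf <- config$consensus
    if (is.null(cf$alignment)) stop("consensus stage: 'alignment' input missing")
    note_input("consensus.alignment", cf$alignment)
    aln <- read_alignment(cf$alignment, target_name = cf$target)
    if (!is.null(cf$min_identity)) {
      aln <- filter_homologs(aln, cf$min_identity)
    }
    cand <- consensus_scan(aln, min_support = cf$min_support %||% 0.5)
    report$consensus_candidates <- as.data.frame(cand)
  }

  if (!is.null(config$interactions)) {
    cf <- config$interactions
    if (is.null(cf$pdb_a)) stop("interactions stage: 'pdb_a' input missing")
    note_input("interactions.pdb_a", cf$pdb_a)
    hc <- cf$hydrophobic_cutoff %||% 5.0
    sc <- cf$saltbridge_cutoff %||% 4.0
    ia <- detect_interactions(read_structure(cf$pdb_a),
                              hydrophobic_cutoff = hc,
                              saltbridge_cutoff = sc)
    if (!is.null(cf$pdb_b)) {
      note_input("interactions.pdb_b", cf$pdb_b)
      ib <- detect_interactions(read_structure(cf$pdb_b),
                                hydrophobic_cutoff = hc,
                                saltbridge_cutoff = sc)
      d <- diff_interactions(ia, ib)
      clusters <- hydrophobic_clusters(
        ib[ib$kind == "hydrophobic", , drop = FALSE])
      report$interaction_diff <- list(
        n_lost = nrow(d$lost), n_gained = nrow(d$gained),
        n_shared = nrow(d$shared),
        lost = as.data.frame(d$lost), gained = as.data.frame(d$gained),
        cluster_sizes = vapply(clusters, `[[`, integer(1), "size"))
    } else {
      report$interactions <- as.data.frame(ia)
    }
  }

  if (!is.null(config$library)) {
    cf <- config$library
    if (is.null(cf$codon)) stop("library stage: 'codon' input missing")
    dc <- expand_degenerate(cf$codon)
    conf <- cf$confidence %||% 0.95
    report$library <- list(
      codon = dc$triad, n_codons = length(dc$codons),
      n_amino_acids = sum(names(dc$aa_counts) != "*"),
      n_stop = dc$n_stop,
      confidence = conf,
      n_full_coverage = transformants_for_coverage(dc, conf,
                                                   "full-coverage"),
      n_expected_fraction = transformants_for_coverage(dc, conf,
                                                       "expected-fraction"),
      n_per_variant = transformants_for_coverage(
        dc, conf, "per-variant",
        variant = names(which.min(dc$aa_counts[names(dc$aa_counts) != "*"]))))
  }

  if (!is.null(config$screen)) {
    cf <- config$screen
    if (is.null(cf$csv)) stop("screen stage: 'csv' input missing")
    note_input("screen.csv", cf$csv)
    rec <- utils::read.csv(cf$csv, stringsAsFactors = FALSE)
    thr <- cf$threshold %||% 0.8
    stages <- if ("stage" %in% names(rec)) sort(unique(rec$stage)) else NA
    last <- utils::tail(stages, 1)
    report$screen <- list(
      threshold = thr,
      survivors = screen_select(rec, thr,
                                stage = if (!is.na(last)) stages[1] else NULL),
      best = best_variant(rec, stage = if (!is.na(last)) last else NULL))
  }

  characterization <- list()
  if (!is.null(config$kinetics)) {
    cf <- config$kinetics
    if (is.null(cf$csv)) stop("kinetics stage: 'csv' input missing")
    note_input("kinetics.csv", cf$csv)
    d <- utils::read.csv(cf$csv, stringsAsFactors = FALSE)
    fit <- fit_michaelis_menten(d$S, d$v, mw_kda = cf$mw_kda)
    characterization$Km <- fit$Km
    characterization$Vmax <- fit$Vmax
    characterization$r_squared <- fit$r_squared
    if (!is.na(fit$kcat)) {
      characterization$kcat <- fit$kcat
      characterization$kcat_over_Km <- catalytic_efficiency(fit$kcat,
                                                            fit$Km)
    }
    if (!is.null(cf$reference_kcat) && !is.null(cf$reference_km) &&
        !is.na(fit$kcat)) {
      ref_eff <- catalytic_efficiency(cf$reference_kcat, cf$reference_km)
      characterization$efficiency_fold <-
        fold_change(characterization$kcat_over_Km, ref_eff)
      characterization$Km_percent_change <-
        percent_change(fit$Km, cf$reference_km)
    }
  }
  if (!is.null(config$halflife)) {
    cf <- config$halflife
    if (is.null(cf$csv)) stop("halflife stage: 'csv' input missing")
    note_input("halflife.csv", cf$csv)
    d <- utils::read.csv(cf$csv, stringsAsFactors = FALSE)
    fit <- fit_inactivation(d$time, d$residual,
                            mode = cf$mode %||% "first-order")
    characterization$t_half <- fit$t_half
    characterization$k_inact <- fit$k
    if (!is.null(cf$reference_t_half)) {
      characterization$t_half_fold <- fold_change(fit$t_half,
                                                  cf$reference_t_half)
    }
  }
  if (!is.null(config$tm)) {
    cf <- config$tm
    if (is.null(cf$csv)) stop("tm stage: 'csv' input missing")
    note_input("tm.csv", cf$csv)
    d <- utils::read.csv(cf$csv, stringsAsFactors = FALSE)
    characterization$tm <- call_tm(d$temperature, d$fluorescence)$tm
  }
  if (!is.null(config$profile)) {
    cf <- config$profile
    if (is.null(cf$csv)) stop("profile stage: 'csv' input missing")
    note_input("profile.csv", cf$csv)
    d <- utils::read.csv(cf$csv, stringsAsFactors = FALSE)
    prof <- profile_analysis(d$x, d$activity,
                             retention_threshold = cf$threshold %||% 0.85)
    characterization$optimum <- prof$optimum
    characterization$stable_range <- prof$stable_range
  }
  if (length(characterization) > 0) {
    report$characterization <- characterization
  }

  class(report) <- "xf_report"
  if (!is.null(out_json)) {
    tmp <- paste0(out_json, ".tmp")
    jsonlite::write_json(unclass(report), tmp, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    file.rename(tmp, out_json)
  }
  if (!is.null(out_text)) {
    tmp <- paste0(out_text, ".tmp")
    writeLines(format_report(report), tmp)
    file.rename(tmp, out_text)
  }
  if (is.null(out_json) && is.null(out_text)) report else invisible(report)
}

format_report <- function(report) {
  out <- c("thermostabilization design report",
           "=================================")
  if (!is.null(report$hotspot)) {
    out <- c(out, "", sprintf(
      "flexibility hotspot: residue %s (B = %s A^2; %s aggregation, %d frames)",
      paste(report$hotspot$residues, collapse = ", "),
      paste(sprintf("%.2f", report$hotspot$bfactor), collapse = ", "),
      report$hotspot$aggregation, report$hotspot$n_frames))
  }
  if (!is.null(report$stability)) {
    s <- report$stability
    out <- c(out, "", sprintf(
      "stability: mean RMSD A %.3f vs B %.3f (frames >= %d) -> %s",
      s$mean_a, s$mean_b, s$equilibration_start, s$verdict))
  }
  if (!is.null(report$consensus_candidates)) {
    cc <- report$consensus_candidates
    out <- c(out, "", sprintf("consensus candidates: %d", nrow(cc)))
    for (i in seq_len(nrow(cc))) {
      out <- c(out, sprintf(
        "  %s%d%s (support %.2f, n = %d)", cc$target_residue[i],
        cc$target_position[i], cc$consensus_residue[i],
        cc$support_fraction[i], cc$n_homologs[i]))
    }
  }
  if (!is.null(report$interaction_diff)) {
    d <- report$interaction_diff
    out <- c(out, "", sprintf(
      "interaction diff: %d lost, %d gained; hydrophobic cluster sizes %s",
      d$n_lost, d$n_gained,
      paste(d$cluster_sizes, collapse = ", ")))
  }
  if (!is.null(report$library)) {
    l <- report$library
    out <- c(out, "", sprintf(
      "library %s: %d codons, %d amino acids, %d stop; n for %.0f%%: %d (full coverage), %d (expected fraction), %d (rarest variant)",
      l$codon, l$n_codons, l$n_amino_acids, l$n_stop,
      100 * l$confidence, l$n_full_coverage, l$n_expected_fraction,
      l$n_per_variant))
  }
  if (!is.null(report$screen)) {
    out <- c(out, "", sprintf(
      "screen: survivors %s; best %s",
      paste(report$screen$survivors, collapse = ", "),
      report$screen$best))
  }
  if (!is.null(report$characterization)) {
    ch <- report$characterization
    out <- c(out, "", "characterization:")
    for (nm in names(ch)) {
      out <- c(out, sprintf("  %s = %s", nm,
                            paste(sprintf("%.4g", ch[[nm]]),
                                  collapse = " .. ")))
    }
  }
  out
}

#' @export
print.xf_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
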