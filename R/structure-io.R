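# Coordinate data model and PDB/XYZ input-output.
#
# A structure is a list with an `atoms` data.frame (one row per atom) and an
# `identifier`; an ensemble adds a (n_atoms x 3 x n_frames) coordinate array
# over a shared topology. Coordinates are Angstrom throughout and residue
# numbering is taken verbatim from input files (1-based, mature-protein
# convention).

STANDARD_AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Construct a molecular structure
#'
#' Low-level constructor used by the readers and the synthetic-data
#' generators. `atoms` must have columns `name`, `element`, `resname`,
#' `resno`, `chain`, `het`, `x`, `y`, `z`. Atom order is preserved; residues
#' must form contiguous groups in atom order and `(chain, resno, name)`
#' triples must be unique among non-HETATM records.
#'
#' @param atoms data.frame of atom records.
#' @param identifier free-text identifier for the structure.
#' @return An object of class `xf_structure`.
#' @export
new_structure <- function(atoms, identifier = "") {
  required <- c("name", "element", "resname", "resno", "chain", "het",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  if (nrow(atoms) == 0) stop("structure must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (any(atoms$resno < 1)) stop("residue numbers must be >= 1")
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
  dup <- duplicated(key[!atoms$het])
  if (any(dup)) {
    stop("duplicate (chain, residue_number, name) atom records: ",
         paste(unique(key[!atoms$het][dup]), collapse = ", "))
  }
  # residues must be contiguous blocks in atom order
  res_key <- paste(atoms$chain, atoms$resno, sep = "|")
  blocks <- rle(res_key)$values
  if (anyDuplicated(blocks)) {
    stop("residues are not contiguous in atom order: ",
         blocks[duplicated(blocks)][1])
  }
  nonstd <- setdiff(unique(atoms$resname[!atoms$het]), STANDARD_AA3)
  obj <- structure(
    list(atoms = atoms, identifier = identifier),
    class = "xf_structure"
  )
  attr(obj, "nonstandard_residues") <- nonstd
  obj
}

#' @export
print.xf_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure '%s': %d atoms, %d residues, chains %s>\n",
              x$identifier, nrow(a),
              length(unique(paste(a$chain, a$resno))),
              paste(sort(unique(a$chain)), collapse = "")))
  invisible(x)
}

#' Construct a coordinate ensemble
#'
#' @param topology an `xf_structure` giving the shared atom identities.
#' @param coords numeric array of dimension `(n_atoms, 3, n_frames)`, or a
#'   list of `n_atoms x 3` matrices.
#' @return An object of class `xf_ensemble`.
#' @export
new_ensemble <- function(topology, coords) {
  stopifnot(inherits(topology, "xf_structure"))
  if (is.list(coords)) {
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3, length(coords)))
  }
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an (n_atoms, 3, n_frames) array")
  }
  if (dim(coords)[1] != nrow(topology$atoms)) {
    stop("coordinate array does not match topology atom count")
  }
  if (dim(coords)[3] < 1) stop("ensemble must contain at least one frame")
  structure(list(topology = topology, coords = coords),
            class = "xf_ensemble")
}

#' @export
print.xf_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble: %d frames x %d atoms ('%s')>\n",
              n_frames(x), nrow(x$topology$atoms), x$topology$identifier))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `xf_ensemble`.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Extract one frame of an ensemble as an n x 3 coordinate matrix
#' @param ensemble an `xf_ensemble`.
#' @param i frame index (1-based).
#' @export
frame_coords <- function(ensemble, i) {
  ensemble$coords[, , i, drop = TRUE]
}

#' Coordinate matrix of a structure
#' @param x an `xf_structure`.
#' @export
coords_matrix <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

infer_element <- function(name) {
  # first alphabetic character of the atom name; good enough for the
  # heavy-atom protein scope (no two-letter elements occur there)
  substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", name)), 1, 1)
}

parse_pdb_atoms <- function(lines, lineno, path) {
  rec <- substr(lines, 1, 6)
  name <- trimws(substr(lines, 13, 16))
  altloc <- substr(lines, 17, 17)
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resno_s <- trimws(substr(lines, 23, 26))
  icode <- substr(lines, 27, 27)
  xs <- trimws(substr(lines, 31, 38))
  ys <- trimws(substr(lines, 39, 46))
  zs <- trimws(substr(lines, 47, 54))
  element <- trimws(substr(lines, 77, 78))

  bad_icode <- which(icode != " " & icode != "")
  if (length(bad_icode) > 0) {
    stop(sprintf("insertion codes are not supported (%s line %d)",
                 path, lineno[bad_icode[1]]))
  }
  for (vals in list(xs, ys, zs, resno_s)) {
    suppressWarnings(num <- as.numeric(vals))
    bad <- which(is.na(num) | vals == "")
    if (length(bad) > 0) {
      stop(sprintf("malformed coordinate/number field in %s at line %d: '%s'",
                   path, lineno[bad[1]],
                   lines[bad[1]]))
    }
  }
  atoms <- data.frame(
    name = name,
    element = ifelse(element == "", infer_element(name), element),
    resname = resname,
    resno = as.integer(resno_s),
    chain = ifelse(chain == " ", "A", chain),
    het = rec == "HETATM",
    x = as.numeric(xs), y = as.numeric(ys), z = as.numeric(zs),
    stringsAsFactors = FALSE
  )
  # altloc: keep the first-listed conformer of each atom, warn
  has_alt <- altloc != " " & altloc != ""
  if (any(has_alt)) {
    key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
    keep <- !duplicated(key) | !has_alt
    dropped <- sum(!keep)
    if (dropped > 0) {
      warning(sprintf("kept first-listed altloc; dropped %d alternate location record(s)",
                      dropped))
      atoms <- atoms[keep, , drop = FALSE]
    }
  }
  atoms
}

#' Read a structure from a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records. `HETATM` atoms are read and
#' flagged (`het = TRUE`) but excluded from all downstream analyses by
#' default. Alternate-location indicators keep the first-listed conformer
#' (with a warning); insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @return An `xf_structure`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records found in ", path)
  atoms <- parse_pdb_atoms(lines[sel], which(sel), path)
  st <- new_structure(atoms, identifier = sub("\\.pdb$", "", basename(path)))
  nonstd <- attr(st, "nonstandard_residues")
  if (length(nonstd) > 0) {
    message("non-standard residue name(s): ", paste(nonstd, collapse = ", "))
  }
  st
}

format_pdb_atom <- function(a, serial) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$het, "HETATM", "ATOM"), serial,
          ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
          a$resname, a$chain, a$resno, a$x, a$y, a$z, 1.0, 0.0, a$element)
}

#' Write a structure to a PDB file
#'
#' @param x an `xf_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "xf_structure"))
  a <- x$atoms
  lines <- vapply(seq_len(nrow(a)),
                  function(i) format_pdb_atom(a[i, ], i), character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a coordinate ensemble (multi-model PDB or XYZ)
#'
#' Multi-model PDB frames are ordered by `MODEL` index; XYZ frames by block
#' order. All frames must share the atom count and identities of the first.
#' An XYZ file carries no residue information, so its topology assigns each
#' atom to its own pseudo-residue.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return An `xf_ensemble`.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "xyz") return(read_ensemble_xyz(path))
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    st <- read_structure(path)
    return(new_ensemble(st, array(coords_matrix(st),
                                  dim = c(nrow(st$atoms), 3, 1))))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records in ", path)
  }
  frames <- vector("list", length(model_starts))
  topo_atoms <- NULL
  for (k in seq_along(model_starts)) {
    idx <- (model_starts[k] + 1):(model_ends[k] - 1)
    idx <- idx[grepl("^(ATOM  |HETATM)", lines[idx])]
    atoms <- parse_pdb_atoms(lines[idx], idx, path)
    if (k == 1) {
      topo_atoms <- atoms
    } else {
      if (nrow(atoms) != nrow(topo_atoms)) {
        stop(sprintf("frame %d atom count (%d) differs from frame 1 (%d)",
                     k, nrow(atoms), nrow(topo_atoms)))
      }
      if (!identical(paste(atoms$chain, atoms$resno, atoms$name),
                     paste(topo_atoms$chain, topo_atoms$resno,
                           topo_atoms$name))) {
        stop(sprintf("frame %d atom identities differ from frame 1", k))
      }
    }
    frames[[k]] <- as.matrix(atoms[, c("x", "y", "z")])
  }
  topo <- new_structure(topo_atoms,
                        identifier = sub("\\.pdb$", "", basename(path)))
  new_ensemble(topo, frames)
}

read_ensemble_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(trimws(lines) != ""), 0))]
  frames <- list()
  topo_el <- NULL
  i <- 1
  k <- 0
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("malformed XYZ atom-count line ", i)
    k <- k + 1
    block <- lines[(i + 2):(i + 1 + n)]
    if (length(block) < n || anyNA(block)) {
      stop(sprintf("frame %d atom count: expected %d atoms", k, n))
    }
    parts <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      if (anyNA(v)) stop("malformed XYZ coordinate in frame ", k)
      v
    }, numeric(3)))
    if (is.null(topo_el)) {
      topo_el <- el
    } else if (length(el) != length(topo_el)) {
      stop(sprintf("frame %d atom count (%d) differs from frame 1 (%d)",
                   k, length(el), length(topo_el)))
    }
    frames[[k]] <- xyz
    i <- i + 2 + n
  }
  topo <- new_structure(data.frame(
    name = topo_el, element = topo_el, resname = "UNK",
    resno = seq_along(topo_el), chain = "A", het = FALSE,
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
    stringsAsFactors = FALSE
  ), identifier = sub("\\.xyz$", "", basename(path)))
  new_ensemble(topo, frames)
}

#' Write an ensemble as a multi-model PDB or XYZ file
#'
#' @param ensemble an `xf_ensemble`.
#' @param path output path.
#' @param format `"pdb"` (multi-model) or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  a <- ensemble$topology$atoms
  nf <- n_frames(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    for (k in seq_len(nf)) {
      xyz <- ensemble$coords[, , k, drop = FALSE]
      writeLines(as.character(nrow(a)), con)
      writeLines(sprintf("frame %d", k), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                         a$element, xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1]),
                 con)
    }
  } else {
    for (k in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      ak <- a
      ak$x <- ensemble$coords[, 1, k]
      ak$y <- ensemble$coords[, 2, k]
      ak$z <- ensemble$coords[, 3, k]
      writeLines(vapply(seq_len(nrow(ak)),
                        function(i) format_pdb_atom(ak[i, ], i),
                        character(1)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Select a subset of atoms from a structure or ensemble
#'
#' Selections compose: the named `selection` keyword, an inclusive residue
#' range and a chain filter are intersected. Atom order is preserved and,
#' for ensembles, the subset applies identically to every frame. HETATM
#' records are dropped unless `keep_het = TRUE`.
#'
#' @param x an `xf_structure` or `xf_ensemble`.
#' @param selection one of `"all"`, `"heavy"` (non-hydrogen), `"ca"`
#'   (C-alpha only).
#' @param resno optional length-2 inclusive residue-number range, or a
#'   vector of residue numbers.
#' @param chain optional chain identifier(s).
#' @param keep_het keep HETATM records (default drops them).
#' @return Object of the same class restricted to the selected atoms.
#' @export
select_atoms <- function(x, selection = "all", resno = NULL, chain = NULL,
                         keep_het = FALSE) {
  UseMethod("select_atoms")
}

atom_mask <- function(atoms, selection, resno, chain, keep_het) {
  selection <- match.arg(selection, c("all", "heavy", "ca"))
  keep <- rep(TRUE, nrow(atoms))
  if (!keep_het) keep <- keep & !atoms$het
  if (selection == "heavy") keep <- keep & toupper(atoms$element) != "H"
  if (selection == "ca") keep <- keep & atoms$name == "CA"
  if (!is.null(resno)) {
    rng <- if (length(resno) == 2) seq(resno[1], resno[2]) else resno
    keep <- keep & atoms$resno %in% rng
  }
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!any(keep)) stop("empty selection")
  keep
}

#' @export
select_atoms.xf_structure <- function(x, selection = "all", resno = NULL,
                                      chain = NULL, keep_het = FALSE) {
  keep <- atom_mask(x$atoms, selection, resno, chain, keep_het)
  new_structure(x$atoms[keep, , drop = FALSE], identifier = x$identifier)
}

#' @export
select_atoms.xf_ensemble <- function(x, selection = "all", resno = NULL,
                                     chain = NULL, keep_het = FALSE) {
  keep <- atom_mask(x$topology$atoms, selection, resno, chain, keep_het)
  topo <- new_structure(x$topology$atoms[keep, , drop = FALSE],
                        identifier = x$topology$identifier)
  new_ensemble(topo, x$coords[keep, , , drop = FALSE])
}
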