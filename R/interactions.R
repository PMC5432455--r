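# Geometric detection of intramolecular interactions: hydrophobic
# side-chain contacts and salt bridges, wild-type/variant diffing, and
# hydrophobic cluster extraction.
#
# Criteria are classic residue-contact geometry: a hydrophobic interaction
# is any side-chain carbon of one apolar residue within `cutoff` of any
# side-chain carbon of another; a salt bridge pairs an acidic side-chain
# oxygen (Asp OD1/OD2, Glu OE1/OE2) with a basic side-chain nitrogen
# (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2). Pairs are reported once at
# residue level with the minimum realizing distance.

HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE",
                          "TRP", "PRO", "TYR")
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

empty_interactions <- function() {
  out <- data.frame(kind = character(0), chain_a = character(0),
                    resno_a = integer(0), resname_a = character(0),
                    chain_b = character(0), resno_b = integer(0),
                    resname_b = character(0), min_distance = numeric(0),
                    atom_a = character(0), atom_b = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("xf_interactions", "data.frame")
  out
}

# minimum-distance residue pairing between two atom tables
pair_min_distance <- function(atoms_a, atoms_b, cutoff, min_seq_sep, kind) {
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0) return(empty_interactions())
  d <- sqrt(outer(atoms_a$x, atoms_b$x, "-")^2 +
            outer(atoms_a$y, atoms_b$y, "-")^2 +
            outer(atoms_a$z, atoms_b$z, "-")^2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_interactions())
  ai <- hit[, 1]
  bi <- hit[, 2]
  same_chain <- atoms_a$chain[ai] == atoms_b$chain[bi]
  sep_ok <- !same_chain |
    abs(atoms_a$resno[ai] - atoms_b$resno[bi]) >= min_seq_sep
  keep <- sep_ok
  if (!any(keep)) return(empty_interactions())
  ai <- ai[keep]; bi <- bi[keep]
  df <- data.frame(
    kind = kind,
    chain_a = atoms_a$chain[ai], resno_a = atoms_a$resno[ai],
    resname_a = atoms_a$resname[ai], atom_a = atoms_a$name[ai],
    chain_b = atoms_b$chain[bi], resno_b = atoms_b$resno[bi],
    resname_b = atoms_b$resname[bi], atom_b = atoms_b$name[bi],
    min_distance = d[cbind(ai, bi)], stringsAsFactors = FALSE
  )
  # orient each pair so residue_a < residue_b under (chain, resno)
  flip <- df$chain_a > df$chain_b |
    (df$chain_a == df$chain_b & df$resno_a > df$resno_b)
  if (any(flip)) {
    tmp <- df[flip, ]
    df[flip, c("chain_a", "resno_a", "resname_a", "atom_a")] <-
      tmp[, c("chain_b", "resno_b", "resname_b", "atom_b")]
    df[flip, c("chain_b", "resno_b", "resname_b", "atom_b")] <-
      tmp[, c("chain_a", "resno_a", "resname_a", "atom_a")]
  }
  # drop self-pairs, deduplicate at residue-pair level keeping the minimum
  df <- df[!(df$chain_a == df$chain_b & df$resno_a == df$resno_b), ,
           drop = FALSE]
  if (nrow(df) == 0) return(empty_interactions())
  key <- paste(df$chain_a, df$resno_a, df$chain_b, df$resno_b, sep = "|")
  df <- df[order(key, df$min_distance), , drop = FALSE]
  df <- df[!duplicated(paste(df$chain_a, df$resno_a, df$chain_b,
                             df$resno_b, sep = "|")), , drop = FALSE]
  df <- df[order(df$chain_a, df$resno_a, df$chain_b, df$resno_b), ,
           drop = FALSE]
  df <- df[, c("kind", "chain_a", "resno_a", "resname_a", "chain_b",
               "resno_b", "resname_b", "min_distance", "atom_a", "atom_b")]
  rownames(df) <- NULL
  class(df) <- c("xf_interactions", "data.frame")
  df
}

sidechain_carbons <- function(atoms) {
  atoms[toupper(atoms$element) == "C" & !atoms$name %in% BACKBONE_ATOMS &
          !atoms$het, , drop = FALSE]
}

#' Detect hydrophobic side-chain contacts
#'
#' @param x an `xf_structure`.
#' @param cutoff maximum side-chain carbon-carbon distance, Angstrom
#'   (default 5.0).
#' @param min_seq_sep minimum |residue-number difference| for same-chain
#'   pairs (default 2; inter-chain pairs are always eligible).
#' @param residue_set 3-letter codes counted as hydrophobic (default
#'   Ala, Val, Leu, Ile, Met, Phe, Trp, Pro, Tyr).
#' @return An `xf_interactions` data.frame (possibly empty), one row per
#'   residue pair with the minimum realizing distance and atom names.
#' @export
hydrophobic_pairs <- function(x, cutoff = 5.0, min_seq_sep = 2,
                              residue_set = HYDROPHOBIC_RESIDUES) {
  atoms <- x$atoms[x$atoms$resname %in% residue_set & !x$atoms$het, ,
                   drop = FALSE]
  sc <- sidechain_carbons(atoms)
  pair_min_distance(sc, sc, cutoff, min_seq_sep, "hydrophobic")
}

#' Detect salt bridges
#'
#' @param x an `xf_structure`.
#' @param cutoff maximum acidic-oxygen to basic-nitrogen distance,
#'   Angstrom (default 4.0).
#' @param min_seq_sep minimum |residue-number difference| for same-chain
#'   pairs (default 2).
#' @param include_his count His (ND1/NE2) as basic (default TRUE;
#'   protonation is not knowable from geometry alone).
#' @return An `xf_interactions` data.frame (possibly empty).
#' @export
salt_bridges <- function(x, cutoff = 4.0, min_seq_sep = 2,
                         include_his = TRUE) {
  basic <- BASIC_ATOMS
  if (!include_his) basic$HIS <- NULL
  atoms <- x$atoms[!x$atoms$het, , drop = FALSE]
  pick <- function(map) {
    keep <- rep(FALSE, nrow(atoms))
    for (res in names(map)) {
      keep <- keep | (atoms$resname == res & atoms$name %in% map[[res]])
    }
    atoms[keep, , drop = FALSE]
  }
  pair_min_distance(pick(ACIDIC_ATOMS), pick(basic), cutoff, min_seq_sep,
                    "salt_bridge")
}

#' Detect all interactions (hydrophobic contacts plus salt bridges)
#'
#' @inheritParams hydrophobic_pairs
#' @param hydrophobic_cutoff,saltbridge_cutoff kind-specific distance
#'   cutoffs, Angstrom.
#' @param include_his passed to [salt_bridges()].
#' @return An `xf_interactions` data.frame.
#' @export
detect_interactions <- function(x, hydrophobic_cutoff = 5.0,
                                saltbridge_cutoff = 4.0, min_seq_sep = 2,
                                include_his = TRUE) {
  out <- rbind(
    hydrophobic_pairs(x, cutoff = hydrophobic_cutoff,
                      min_seq_sep = min_seq_sep),
    salt_bridges(x, cutoff = saltbridge_cutoff, min_seq_sep = min_seq_sep,
                 include_his = include_his)
  )
  class(out) <- c("xf_interactions", "data.frame")
  out
}

interaction_key <- function(df) {
  paste(df$kind, df$chain_a, df$resno_a, df$chain_b, df$resno_b, sep = "|")
}

#' Diff the interactions of two structures (e.g. wild type vs variant)
#'
#' Interactions are identified by `(kind, chain/residue-number pair)` —
#' residue names are deliberately excluded so a substitution at the
#' mutated position does not block matching elsewhere.
#'
#' @param structure_a,structure_b `xf_structure` objects, or
#'   precomputed `xf_interactions` tables.
#' @param ... detection parameters passed to [detect_interactions()].
#' @return An `xf_interaction_diff`: list with `lost` (in A only),
#'   `gained` (in B only) and `shared` interaction tables.
#' @export
diff_interactions <- function(structure_a, structure_b, ...) {
  ia <- if (inherits(structure_a, "xf_interactions")) structure_a else
    detect_interactions(structure_a, ...)
  ib <- if (inherits(structure_b, "xf_interactions")) structure_b else
    detect_interactions(structure_b, ...)
  ka <- interaction_key(ia)
  kb <- interaction_key(ib)
  out <- list(lost = ia[!ka %in% kb, , drop = FALSE],
              gained = ib[!kb %in% ka, , drop = FALSE],
              shared = ia[ka %in% kb, , drop = FALSE])
  out <- lapply(out, function(d) {
    rownames(d) <- NULL
    class(d) <- c("xf_interactions", "data.frame")
    d
  })
  class(out) <- "xf_interaction_diff"
  out
}

#' @export
print.xf_interaction_diff <- function(x, ...) {
  cat(sprintf("<interaction diff: %d lost, %d gained, %d shared>\n",
              nrow(x$lost), nrow(x$gained), nrow(x$shared)))
  invisible(x)
}

#' Connected hydrophobic clusters of an interaction set
#'
#' Builds the residue graph whose edges are the supplied hydrophobic
#' interactions and returns its connected components (size >= 2), largest
#' first.
#'
#' @param interactions an `xf_interactions` table, all of kind
#'   `"hydrophobic"`.
#' @return List of clusters, each a list with `members` (sorted
#'   `chain:resno` labels) and `size`.
#' @export
hydrophobic_clusters <- function(interactions) {
  if (nrow(interactions) == 0) return(list())
  if (any(interactions$kind != "hydrophobic")) {
    stop("hydrophobic_clusters expects interactions of kind 'hydrophobic' only")
  }
  va <- paste(interactions$chain_a, interactions$resno_a, sep = ":")
  vb <- paste(interactions$chain_b, interactions$resno_b, sep = ":")
  g <- igraph::graph_from_data_frame(data.frame(va, vb), directed = FALSE)
  comp <- igraph::components(g)
  clusters <- lapply(seq_len(comp$no), function(i) {
    members <- names(comp$membership)[comp$membership == i]
    members <- members[order(as.integer(sub("^.*:", "", members)))]
    list(members = members, size = length(members))
  })
  clusters <- clusters[vapply(clusters, `[[`, integer(1), "size") >= 2]
  clusters[order(-vapply(clusters, `[[`, integer(1), "size"))]
}
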