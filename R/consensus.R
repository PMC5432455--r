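# Multiple-sequence-alignment handling, pairwise identity, homolog panel
# filtering, and back-to-consensus mutation scanning.
#
# The consensus approach proposes substituting a target residue with the
# residue predominant at the same alignment column among thermophilic
# homologs (e.g. a Tyr at target position 13 facing Phe in most homologs
# suggests Tyr13Phe).

AA_ALPHABET <- c(LETTERS[!LETTERS %in% c("B", "J", "O", "U", "Z")], "X")
GAP_CHARS <- c("-", ".")

#' Construct an alignment object
#'
#' @param names sequence identifiers.
#' @param rows equal-length gapped amino-acid sequences (uppercase; `-`
#'   for gaps).
#' @param target_name identifier of the engineering target (default: the
#'   first sequence).
#' @return An `xf_alignment`: list with `names`, `rows`, `target_name`.
#' @export
new_alignment <- function(names, rows, target_name = names[1]) {
  if (length(names) != length(rows)) stop("names/rows length mismatch")
  if (length(rows) < 2) stop("alignment needs at least 2 sequences")
  rows <- toupper(rows)
  rows <- chartr(".", "-", rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "))
  }
  bad <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1]]),
                 c(AA_ALPHABET, "-", "*"))
  if (length(bad) > 0) {
    stop("unknown alignment characters: ", paste(bad, collapse = ", "))
  }
  if (!target_name %in% names) {
    stop("target '", target_name, "' not present in the alignment")
  }
  structure(list(names = names, rows = rows, target_name = target_name),
            class = "xf_alignment")
}

#' @export
print.xf_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d sequences x %d columns, target '%s'>\n",
              length(x$rows), nchar(x$rows[1]), x$target_name))
  invisible(x)
}

read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1])) {
    stop("not a Clustal file (missing CLUSTAL header): ", path)
  }
  body <- lines[-1]
  body <- body[nchar(trimws(body)) > 0]
  body <- body[!grepl("^\\s", body)]     # conservation lines
  seqs <- list()
  order_seen <- character(0)
  for (ln in body) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2) stop("unparseable Clustal line: ", ln)
    nm <- parts[1]
    if (!nm %in% order_seen) order_seen <- c(order_seen, nm)
    seqs[[nm]] <- paste0(seqs[[nm]] %||% "", parts[2])
  }
  list(names = order_seen, rows = unlist(seqs[order_seen],
                                         use.names = FALSE))
}

#' Read a multiple sequence alignment (aligned FASTA or Clustal)
#'
#' Aligned-FASTA parsing is delegated to [seqinr::read.alignment()];
#' Clustal files are read by a small in-package parser (name + block
#' lines, conservation rows skipped). Rows are case-normalized to
#' uppercase and `.` gaps converted to `-`. Ragged rows or characters
#' outside the amino-acid alphabet are errors.
#'
#' @param path alignment file.
#' @param format `"auto"` (by extension), `"fasta"` or `"clustal"`.
#' @param target_name designated engineering target (default: first
#'   sequence).
#' @return An `xf_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal"),
                           target_name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(aln|clustal|clw)$", path, ignore.case = TRUE)) {
      "clustal"
    } else "fasta"
  }
  if (format == "clustal") {
    parsed <- read_clustal(path)
    rows <- parsed$rows
    nm <- parsed$names
  } else {
    aln <- seqinr::read.alignment(path, format = "fasta",
                                  forceToLower = FALSE)
    rows <- unlist(aln$seq, use.names = FALSE)
    nm <- unlist(aln$nam, use.names = FALSE)
  }
  if (is.null(target_name)) target_name <- nm[1]
  new_alignment(nm, rows, target_name)
}

#' Write an alignment as aligned FASTA or Clustal
#'
#' @param alignment an `xf_alignment`.
#' @param path output file.
#' @param format `"fasta"` or `"clustal"`.
#' @param width characters per line.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, format = c("fasta", "clustal"),
                            width = 60) {
  format <- match.arg(format)
  rows <- alignment$rows
  nm <- alignment$names
  if (format == "fasta") {
    out <- unlist(lapply(seq_along(rows), function(i) {
      seq <- rows[i]
      starts <- seq(1, nchar(seq), by = width)
      c(paste0(">", nm[i]),
        vapply(starts, function(s) substr(seq, s, s + width - 1),
               character(1)))
    }))
    writeLines(out, path)
  } else {
    pad <- max(nchar(nm)) + 3
    out <- c("CLUSTAL W multiple sequence alignment", "")
    starts <- seq(1, nchar(rows[1]), by = width)
    for (s in starts) {
      block <- vapply(seq_along(rows), function(i) {
        sprintf("%-*s%s", pad, nm[i], substr(rows[i], s, s + width - 1))
      }, character(1))
      out <- c(out, block, "")
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Percent identity between two aligned rows
#'
#' Matches are counted only at columns where both rows are non-gap. The
#' denominator is either the number of such comparable columns
#' (`"aligned-columns"`, the default) or the shorter ungapped sequence
#' length (`"shorter-ungapped"`).
#'
#' @param row_a,row_b equal-length gapped sequences.
#' @param denominator identity convention (see above).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(row_a, row_b,
                              denominator = c("aligned-columns",
                                              "shorter-ungapped")) {
  denominator <- match.arg(denominator)
  a <- strsplit(toupper(row_a), "")[[1]]
  b <- strsplit(toupper(row_b), "")[[1]]
  if (length(a) != length(b)) stop("rows must be equal length")
  gap_a <- a %in% GAP_CHARS
  gap_b <- b %in% GAP_CHARS
  comparable <- !gap_a & !gap_b
  matches <- sum(a[comparable] == b[comparable])
  denom <- switch(denominator,
    "aligned-columns" = sum(comparable),
    "shorter-ungapped" = min(sum(!gap_a), sum(!gap_b))
  )
  if (denom == 0) stop("zero-length denominator: no comparable positions")
  100 * matches / denom
}

#' Restrict an alignment to homologs meeting an identity threshold
#'
#' Identity is computed against the target row; the target itself is
#' always retained and row order is preserved.
#'
#' @param alignment an `xf_alignment`.
#' @param min_identity_pct threshold in percent, `[0, 100]`.
#' @param denominator passed to [pairwise_identity()].
#' @return A filtered `xf_alignment`.
#' @export
filter_homologs <- function(alignment, min_identity_pct,
                            denominator = "aligned-columns") {
  if (min_identity_pct < 0 || min_identity_pct > 100) {
    stop("min_identity_pct must be in [0, 100]")
  }
  t_idx <- match(alignment$target_name, alignment$names)
  target_row <- alignment$rows[t_idx]
  keep <- vapply(seq_along(alignment$rows), function(i) {
    if (i == t_idx) return(TRUE)
    pairwise_identity(alignment$rows[i], target_row,
                      denominator = denominator) > min_identity_pct
  }, logical(1))
  if (sum(keep) < 2) {
    stop("all homologs fall below the identity threshold")
  }
  new_alignment(alignment$names[keep], alignment$rows[keep],
                alignment$target_name)
}

#' Scan an alignment for back-to-consensus mutation candidates
#'
#' A column yields a candidate when (i) the target is non-gap there,
#' (ii) the plurality residue among non-gap homolog rows is unique (ties
#' cannot name a consensus), (iii) its support — the fraction of non-gap
#' homolog rows carrying it — is at least `min_support`, and (iv) it
#' differs from the target residue. Candidates are sorted by descending
#' support, then target position.
#'
#' @param alignment an `xf_alignment` with at least two homolog rows
#'   besides the target.
#' @param min_support minimum support fraction in `(0, 1]` (default 0.5).
#' @param region optional length-2 inclusive range of ungapped target
#'   positions to scan.
#' @return An `xf_consensus` data.frame with columns `target_position`,
#'   `column`, `target_residue`, `consensus_residue`, `support_fraction`,
#'   `n_homologs`.
#' @export
consensus_scan <- function(alignment, min_support = 0.5, region = NULL) {
  if (min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]")
  }
  t_idx <- match(alignment$target_name, alignment$names)
  target <- strsplit(alignment$rows[t_idx], "")[[1]]
  homologs <- lapply(alignment$rows[-t_idx], function(s) strsplit(s, "")[[1]])
  if (length(homologs) < 2) {
    stop("consensus_scan needs at least 2 homolog rows besides the target")
  }
  ungapped_pos <- cumsum(!target %in% GAP_CHARS)
  out <- list()
  for (col in seq_along(target)) {
    t_res <- target[col]
    if (t_res %in% GAP_CHARS) next
    pos <- ungapped_pos[col]
    if (!is.null(region) && (pos < region[1] || pos > region[2])) next
    col_res <- vapply(homologs, `[`, character(1), col)
    col_res <- col_res[!col_res %in% GAP_CHARS]
    if (length(col_res) == 0) next
    tab <- table(col_res)
    top <- max(tab)
    modes <- names(tab)[tab == top]
    if (length(modes) != 1) next          # plurality tie: no consensus
    support <- top / length(col_res)
    if (support < min_support) next
    if (modes == t_res) next
    out[[length(out) + 1]] <- data.frame(
      target_position = pos, column = col, target_residue = t_res,
      consensus_residue = modes, support_fraction = support,
      n_homologs = length(col_res), stringsAsFactors = FALSE
    )
  }
  res <- if (length(out) == 0) {
    data.frame(target_position = integer(0), column = integer(0),
               target_residue = character(0),
               consensus_residue = character(0),
               support_fraction = numeric(0), n_homologs = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  res <- res[order(-res$support_fraction, res$target_position), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("xf_consensus", "data.frame")
  res
}
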