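# Degenerate-codon saturation-library design and screening statistics.
#
# A single-site saturation library built with the NNK triad (N = A/C/G/T,
# K = G/T) spans 32 codons encoding all 20 amino acids plus one stop
# (TAG). Coverage statistics answer "how many transformants must be picked
# so that every amino acid is represented?"; the screening helpers encode
# the two-stage heat-challenge selection of the most thermostable variant.

#' Expand a degenerate codon triad
#'
#' Expands a 3-letter IUPAC nucleotide string into its literal codons
#' (lexicographic order) and translates each with the standard genetic
#' code. Stop codons are tracked separately under `"*"`.
#'
#' @param triad 3-character IUPAC string, e.g. `"NNK"`.
#' @return An `xf_codon`: list with `triad`, `codons`, `aa_counts` (named
#'   integer vector, amino acids by 1-letter code plus `"*"`), `n_stop`.
#' @export
expand_degenerate <- function(triad) {
  triad <- toupper(triad)
  if (nchar(triad) != 3) stop("triad must have exactly 3 characters")
  letters3 <- strsplit(triad, "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- letters3[!letters3 %in% names(map)]
  if (length(bad) > 0) {
    stop("invalid IUPAC nucleotide code: ", paste(unique(bad), collapse = ", "))
  }
  per_pos <- lapply(letters3, function(ch) strsplit(map[[ch]], "")[[1]])
  grid <- expand.grid(per_pos[[3]], per_pos[[2]], per_pos[[1]],
                      stringsAsFactors = FALSE)
  codons <- sort(paste0(grid[[3]], grid[[2]], grid[[1]]))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa_counts <- table(factor(aa, levels = sort(unique(aa))))
  aa_counts <- stats::setNames(as.integer(aa_counts), names(aa_counts))
  structure(list(triad = triad, codons = codons, aa_counts = aa_counts,
                 n_stop = sum(aa == "*")),
            class = "xf_codon")
}

#' @export
print.xf_codon <- function(x, ...) {
  cat(sprintf("<degenerate codon %s: %d codons, %d amino acids, %d stop>\n",
              x$triad, length(x$codons),
              sum(names(x$aa_counts) != "*"), x$n_stop))
  invisible(x)
}

required_counts <- function(aa_counts) {
  if (inherits(aa_counts, "xf_codon")) aa_counts <- aa_counts$aa_counts
  if (any(aa_counts <= 0)) stop("codon counts must be positive")
  list(total = sum(aa_counts),
       req = aa_counts[names(aa_counts) != "*"])
}

#' Probability that n transformants cover every amino acid
#'
#' Exact inclusion-exclusion over amino-acid subsets on the codon
#' multinomial: `P = sum_S (-1)^|S| ((C - c(S)) / C)^n`, with `C` the total
#' codon count and `c(S)` the codons encoding the missed set `S`. Stop
#' codons count toward `C` (library dead-weight) but are never required
#' observations. The signed subset sum is evaluated exactly by dynamic
#' programming over `c(S)`.
#'
#' @param aa_counts named codon counts per amino acid (1-letter codes,
#'   `"*"` for stop), or an `xf_codon`.
#' @param n_transformants number of independently drawn transformants.
#' @return Probability in `[0, 1]`.
#' @export
coverage_probability <- function(aa_counts, n_transformants) {
  rc <- required_counts(aa_counts)
  if (length(rc$req) > 25) {
    stop("more than 25 amino-acid categories: inclusion-exclusion refused")
  }
  if (n_transformants < 0) stop("n_transformants must be >= 0")
  if (length(rc$req) == 0) return(1)
  if (n_transformants == 0) return(0)
  C <- rc$total
  # signed[s+1] = sum over subsets S with c(S) = s of (-1)^|S|
  signed <- numeric(C + 1)
  signed[1] <- 1
  for (ci in rc$req) {
    shifted <- c(numeric(ci), signed[seq_len(C + 1 - ci)])
    signed <- signed - shifted
  }
  s <- 0:C
  p <- sum(signed * ((C - s) / C)^n_transformants)
  min(max(p, 0), 1)
}

#' Expected fraction of amino acids observed among n transformants
#'
#' @inheritParams coverage_probability
#' @return Expected fraction in `[0, 1]`.
#' @export
expected_coverage_fraction <- function(aa_counts, n_transformants) {
  rc <- required_counts(aa_counts)
  mean(1 - ((rc$total - rc$req) / rc$total)^n_transformants)
}

#' Probability that one specific variant appears among n transformants
#'
#' @inheritParams coverage_probability
#' @param variant 1-letter amino-acid code of the variant of interest.
#' @return Probability in `[0, 1]`.
#' @export
variant_probability <- function(aa_counts, n_transformants, variant) {
  rc <- required_counts(aa_counts)
  if (!variant %in% names(rc$req)) {
    stop("variant '", variant, "' is not encoded by this codon set")
  }
  1 - ((rc$total - rc$req[[variant]]) / rc$total)^n_transformants
}

#' Minimum transformant count reaching a coverage confidence
#'
#' Smallest integer `n` whose mode-dependent statistic meets `confidence`:
#' full-coverage probability ([coverage_probability()]), expected fraction
#' of amino acids observed, or the probability that one named variant is
#' present. Found by doubling then bisection on the monotone statistic.
#'
#' @inheritParams coverage_probability
#' @param confidence target in `(0, 1)`.
#' @param mode `"full-coverage"` (default), `"expected-fraction"` or
#'   `"per-variant"`.
#' @param variant required for `"per-variant"` mode.
#' @return Minimum `n` (integer).
#' @export
transformants_for_coverage <- function(aa_counts, confidence,
                                       mode = c("full-coverage",
                                                "expected-fraction",
                                                "per-variant"),
                                       variant = NULL) {
  mode <- match.arg(mode)
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)")
  }
  stat <- switch(mode,
    "full-coverage" = function(n) coverage_probability(aa_counts, n),
    "expected-fraction" = function(n)
      expected_coverage_fraction(aa_counts, n),
    "per-variant" = {
      if (is.null(variant)) stop("per-variant mode requires 'variant'")
      function(n) variant_probability(aa_counts, n, variant)
    }
  )
  hi <- 1
  while (stat(hi) < confidence) {
    hi <- hi * 2
    if (hi > 1e9) stop("confidence unreachable")
  }
  lo <- 0
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (stat(mid) >= confidence) hi <- mid else lo <- mid
  }
  hi
}

check_screen_records <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no screening records supplied")
  }
  if (!all(c("variant", "residual") %in% names(records))) {
    stop("records must have columns 'variant' and 'residual'")
  }
  if (any(records$residual < 0)) stop("residual activities must be >= 0")
  records
}

#' Select variants surviving a residual-activity threshold
#'
#' Survivors retain *strictly more* than `residual_threshold` of their
#' original activity after the heat challenge.
#'
#' @param records data.frame with columns `variant`, `residual`
#'   (fraction of original activity) and optionally `stage`.
#' @param residual_threshold survival threshold as a fraction
#'   (default 0.8).
#' @param stage optional stage filter.
#' @return Character vector of surviving variant labels (possibly empty).
#' @export
screen_select <- function(records, residual_threshold = 0.8, stage = NULL) {
  records <- check_screen_records(records)
  if (!is.null(stage) && "stage" %in% names(records)) {
    records <- records[records$stage %in% stage, , drop = FALSE]
    if (nrow(records) == 0) stop("no records for stage ", stage)
  }
  records$variant[records$residual > residual_threshold]
}

#' The single best variant by residual activity
#'
#' @inheritParams screen_select
#' @return The variant label with the maximum residual activity. A tie at
#'   the maximum is an error (the rule cannot pick automatically).
#' @export
best_variant <- function(records, stage = NULL) {
  records <- check_screen_records(records)
  if (!is.null(stage) && "stage" %in% names(records)) {
    records <- records[records$stage %in% stage, , drop = FALSE]
    if (nrow(records) == 0) stop("no records for stage ", stage)
  }
  top <- max(records$residual)
  winners <- records$variant[records$residual == top]
  if (length(winners) > 1) {
    stop("tie at maximum residual activity (",
         paste(winners, collapse = ", "), "): choose manually")
  }
  winners
}
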