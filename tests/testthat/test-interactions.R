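# planted-geometry oracles: structures built with atoms at exact distances

two_val_structure <- function(d) {
  toy_structure(list(
    list("CA",  "VAL", 1, 0, 0, 0),
    list("CG1", "VAL", 1, 0, 0, 1),
    list("CA",  "VAL", 5, d, 10, 0),
    list("CG1", "VAL", 5, d, 0, 1)
  ))
}

test_that("hydrophobic pairs respect the distance cutoff and residue set", {
  hit <- hydrophobic_pairs(two_val_structure(4.0))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$min_distance, 4.0)
  expect_equal(c(hit$resno_a, hit$resno_b), c(1, 5))
  expect_equal(c(hit$atom_a, hit$atom_b), c("CG1", "CG1"))
  expect_equal(nrow(hydrophobic_pairs(two_val_structure(5.5))), 0)
  # Ser is not hydrophobic even at close range
  st <- toy_structure(list(
    list("CG1", "VAL", 1, 0, 0, 0),
    list("OG",  "SER", 5, 3, 0, 0)
  ))
  expect_equal(nrow(hydrophobic_pairs(st)), 0)
})

test_that("sequence-adjacent residues are excluded by min_seq_sep", {
  st <- toy_structure(list(
    list("CG1", "VAL", 4, 0, 0, 0),
    list("CG1", "VAL", 5, 3, 0, 0)
  ))
  expect_equal(nrow(hydrophobic_pairs(st)), 0)
  expect_equal(nrow(hydrophobic_pairs(st, min_seq_sep = 1)), 1)
})

test_that("salt bridges pair acidic oxygens with basic nitrogens only", {
  glu_arg <- function(d) toy_structure(list(
    list("OE1", "GLU", 84, 0, 0, 0),
    list("NH1", "ARG", 120, d, 0, 0)
  ))
  hit <- salt_bridges(glu_arg(3.5))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$kind, "salt_bridge")
  expect_equal(c(hit$resno_a, hit$resno_b), c(84, 120))
  expect_equal(nrow(salt_bridges(glu_arg(4.5))), 0)
  # like charges do not bridge
  st <- toy_structure(list(
    list("OE1", "GLU", 84, 0, 0, 0),
    list("OD1", "ASP", 120, 3, 0, 0)
  ))
  expect_equal(nrow(salt_bridges(st)), 0)
  # His participation is configurable
  his <- toy_structure(list(
    list("OE1", "GLU", 84, 0, 0, 0),
    list("ND1", "HIS", 120, 3, 0, 0)
  ))
  expect_equal(nrow(salt_bridges(his)), 1)
  expect_equal(nrow(salt_bridges(his, include_his = FALSE)), 0)
})

test_that("each residue pair is reported once with its minimum distance", {
  st <- toy_structure(list(
    list("CB",  "ILE", 1, 0, 0, 0),
    list("CG1", "ILE", 1, 0.8, 0, 0),
    list("CB",  "ILE", 4, 4.5, 0, 0),
    list("CG1", "ILE", 4, 3.9, 0.5, 0)
  ))
  hit <- hydrophobic_pairs(st)
  expect_equal(nrow(hit), 1)
  # the closest carbon-carbon pair realizes the distance
  d_expected <- sqrt((3.9 - 0.8)^2 + 0.25)
  expect_equal(hit$min_distance, d_expected, tolerance = 1e-12)
})

test_that("detection is invariant to rotation and atom-order permutation", {
  sp <- gen_structure_pair(seed = 41)
  st <- sp$variant
  base <- detect_interactions(st)
  R <- random_proper_rotation()
  rot <- st
  xyz <- coords_matrix(st) %*% R
  rot$atoms$x <- xyz[, 1]; rot$atoms$y <- xyz[, 2]; rot$atoms$z <- xyz[, 3]
  got <- detect_interactions(rot)
  expect_equal(got[, names(got) != "min_distance"],
               base[, names(base) != "min_distance"])
  expect_equal(got$min_distance, base$min_distance, tolerance = 1e-9)
  # permute atoms within residues
  set.seed(1)
  perm_atoms <- do.call(rbind, lapply(split(st$atoms, st$atoms$resno),
                                      function(d) d[sample(nrow(d)), ]))
  perm <- new_structure(perm_atoms, st$identifier)
  expect_equal(detect_interactions(perm), base)
})

test_that("shrinking the cutoff never adds interactions", {
  sp <- gen_structure_pair(seed = 42)
  n <- vapply(c(5.0, 4.5, 4.0, 3.5), function(cut) {
    nrow(hydrophobic_pairs(sp$variant, cutoff = cut))
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("interaction diffs recover planted gains and losses", {
  sp <- gen_structure_pair(seed = 43)
  d <- diff_interactions(sp$wild_type, sp$variant)
  expect_equal(nrow(d$lost), length(sp$truth$lost_hydrophobic))
  expect_equal(nrow(d$gained),
               length(sp$truth$gained_hydrophobic) +
                 length(sp$truth$gained_salt))
  expect_equal(sum(d$gained$kind == "salt_bridge"),
               length(sp$truth$gained_salt))
  got_lost <- Map(c, d$lost$resno_a, d$lost$resno_b)
  expect_setequal(lapply(got_lost, as.numeric), sp$truth$lost_hydrophobic)
  # self-diff is empty; lost/gained swap under argument exchange
  self <- diff_interactions(sp$variant, sp$variant)
  expect_equal(nrow(self$lost) + nrow(self$gained), 0)
  rev <- diff_interactions(sp$variant, sp$wild_type)
  expect_equal(rev$gained, d$lost)
  expect_equal(rev$lost, d$gained)
})

test_that("a single planted extra contact shows up as one gain", {
  a <- two_val_structure(6.5)          # no contact
  b <- two_val_structure(4.2)          # planted contact
  d <- diff_interactions(a, b)
  expect_equal(nrow(d$gained), 1)
  expect_equal(nrow(d$lost), 0)
})

test_that("hydrophobic clusters are the connected components of the graph", {
  mk <- function(pairs) {
    do.call(rbind, lapply(pairs, function(p) {
      data.frame(kind = "hydrophobic", chain_a = "A", resno_a = p[1],
                 resname_a = "ILE", chain_b = "A", resno_b = p[2],
                 resname_b = "ILE", min_distance = 4, atom_a = "CB",
                 atom_b = "CB", stringsAsFactors = FALSE)
    }))
  }
  # a chain linking 7 residues -> one cluster of size 7
  chain7 <- mk(list(c(34, 71), c(71, 72), c(72, 73), c(73, 74),
                    c(74, 87), c(87, 172)))
  cl <- hydrophobic_clusters(chain7)
  expect_equal(length(cl), 1)
  expect_equal(cl[[1]]$size, 7)
  expect_setequal(cl[[1]]$members,
                  paste0("A:", c(34, 71, 72, 73, 74, 87, 172)))
  # two disjoint pairs -> two clusters of size 2
  cl2 <- hydrophobic_clusters(mk(list(c(1, 5), c(10, 20))))
  expect_equal(vapply(cl2, `[[`, integer(1), "size"), c(2L, 2L))
  # mixed kinds are refused
  bad <- chain7
  bad$kind[1] <- "salt_bridge"
  expect_error(hydrophobic_clusters(bad), "hydrophobic")
})

test_that("cluster sizes agree with a brute-force union-find oracle", {
  set.seed(9)
  for (rep in 1:5) {
    # random edges over residues 1..30 with separation >= 2
    pairs <- unique(t(replicate(15, sort(sample(seq(1, 30, by = 2), 2)))))
    pairs <- pairs[pairs[, 2] - pairs[, 1] >= 2, , drop = FALSE]
    df <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      data.frame(kind = "hydrophobic", chain_a = "A",
                 resno_a = pairs[i, 1], resname_a = "ILE", chain_b = "A",
                 resno_b = pairs[i, 2], resname_b = "ILE",
                 min_distance = 4, atom_a = "CB", atom_b = "CB",
                 stringsAsFactors = FALSE)
    }))
    # union-find oracle
    parent <- stats::setNames(unique(c(pairs)), unique(c(pairs)))
    find <- function(x) {
      while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
      x
    }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[[as.character(ra)]] <- rb
    }
    roots <- vapply(as.numeric(names(parent)), find, numeric(1))
    oracle_sizes <- sort(as.integer(table(roots)), decreasing = TRUE)
    oracle_sizes <- oracle_sizes[oracle_sizes >= 2]
    got <- vapply(hydrophobic_clusters(df), `[[`, integer(1), "size")
    expect_equal(got, oracle_sizes)
  }
})
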