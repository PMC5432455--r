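test_that("a minimal one-residue PDB reads into a single-atom structure", {
  path <- write_lines_tmp(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"
  ))
  st <- read_structure(path)
  expect_s3_class(st, "xf_structure")
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$resno, 1L)
  expect_equal(unname(unlist(st$atoms[1, c("x", "y", "z")])), c(0, 0, 0))
})

test_that("write -> read round trip preserves identities and coordinates", {
  st <- toy_structure(list(
    list("N",  "ALA", 1, 1.234, -2.345, 3.456),
    list("CA", "ALA", 1, 4.001, 5.125, -6.790),
    list("CA", "GLY", 2, 0.001, 0.002, 0.003)
  ))
  # second chain to exercise the chain column
  st2 <- st
  st2$atoms$chain <- c("A", "A", "B")
  st2 <- new_structure(st2$atoms, "two-chain")
  path <- tempfile(fileext = ".pdb")
  write_structure(st2, path)
  back <- read_structure(path)
  for (col in c("name", "resname", "resno", "chain")) {
    expect_equal(back$atoms[[col]], st2$atoms[[col]])
  }
  # PDB stores 3 decimals
  for (col in c("x", "y", "z")) {
    expect_equal(back$atoms[[col]], st2$atoms[[col]], tolerance = 1e-8)
  }
})

test_that("malformed coordinate fields and empty files are parse errors", {
  bad <- write_lines_tmp(c(
    "ATOM      1  CA  ALA A   1       0.000   xx.00   0.000  1.00  0.00           C"
  ))
  expect_error(read_structure(bad), "line 1")
  empty <- write_lines_tmp(character(0))
  expect_error(read_structure(empty), "no ATOM")
})

test_that("insertion codes are rejected and altlocs keep the first conformer", {
  ins <- write_lines_tmp(c(
    "ATOM      1  CA  ALA A   1A      0.000   0.000   0.000  1.00  0.00           C"
  ))
  expect_error(read_structure(ins), "insertion code")
  alt <- write_lines_tmp(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  1.00  0.00           C"
  ))
  expect_warning(st <- read_structure(alt), "altloc")
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$x, 1.0)
})

test_that("multi-model PDB ensembles read frames in MODEL order", {
  lines <- unlist(lapply(1:3, function(k) c(
    sprintf("MODEL     %4d", k),
    sprintf("ATOM      1  CA  ALA A   1      %6.3f   0.000   0.000  1.00  0.00           C",
            as.numeric(k)),
    "ENDMDL"
  )))
  path <- write_lines_tmp(c(lines, "END"))
  ens <- read_ensemble(path)
  expect_equal(n_frames(ens), 3)
  expect_equal(ens$coords[1, 1, ], c(1, 2, 3))
})

test_that("a frame with a missing atom names the offending frame", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END"
  )
  expect_error(read_ensemble(write_lines_tmp(lines)), "frame 2 atom count")
})

test_that("XYZ blocks read as frames and round-trip through write_ensemble", {
  xyz <- c("5", "frame 1",
           sprintf("C %.4f 0.0 0.0", 1:5),
           "5", "frame 2",
           sprintf("C %.4f 0.5 0.0", 1:5))
  ens <- read_ensemble(write_lines_tmp(xyz, ext = ".xyz"))
  expect_equal(n_frames(ens), 2)
  expect_equal(dim(ens$coords)[1], 5)
  out <- tempfile(fileext = ".xyz")
  write_ensemble(ens, out, format = "xyz")
  back <- read_ensemble(out)
  expect_equal(back$coords, ens$coords, tolerance = 1e-6)
  # multi-model PDB round trip of the same ensemble
  out2 <- tempfile(fileext = ".pdb")
  write_ensemble(ens, out2, format = "pdb")
  back2 <- read_ensemble(out2)
  expect_equal(back2$coords, ens$coords, tolerance = 1e-8)
})

test_that("select_atoms honours keyword, residue-range and chain filters", {
  st <- three_residue_structure()
  expect_equal(nrow(select_atoms(st, "ca")$atoms), 3)
  expect_equal(nrow(select_atoms(st, resno = c(2, 3))$atoms), 5)
  # both ends inclusive
  got <- select_atoms(st, resno = c(1, 2))$atoms
  expect_setequal(unique(got$resno), c(1, 2))
  expect_error(select_atoms(st, chain = "Z"), "empty selection")
  # ensembles subset every frame identically
  ens <- toy_ensemble(st, list(coords_matrix(st), coords_matrix(st) + 1))
  sub <- select_atoms(ens, "ca")
  expect_equal(dim(sub$coords), c(3, 3, 2))
  expect_equal(sub$topology$atoms$name, rep("CA", 3))
})

test_that("selections compose: chained filters equal the conjunction", {
  st <- three_residue_structure()
  a_then_b <- select_atoms(select_atoms(st, "ca"), resno = c(2, 3))
  conj <- select_atoms(st, "ca", resno = c(2, 3))
  expect_equal(a_then_b$atoms, conj$atoms)
})

test_that("HETATM records are parsed but excluded by default", {
  path <- write_lines_tmp(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A   2       5.000   0.000   0.000  1.00  0.00           O"
  ))
  st <- suppressMessages(read_structure(path))
  expect_equal(sum(st$atoms$het), 1)
  expect_equal(nrow(select_atoms(st, "all")$atoms), 1)
  expect_equal(nrow(select_atoms(st, "all", keep_het = TRUE)$atoms), 2)
})
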