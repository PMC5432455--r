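# In-code fixtures shared across the suite: tiny hand-built structures
# and writers for minimal PDB text.

# a structure from a compact spec: list of (name, resname, resno, x, y, z)
toy_structure <- function(rows, chain = "A", id = "toy") {
  atoms <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], element = substr(r[[1]], 1, 1),
               resname = r[[2]], resno = as.integer(r[[3]]),
               chain = chain, het = FALSE,
               x = as.numeric(r[[4]]), y = as.numeric(r[[5]]),
               z = as.numeric(r[[6]]), stringsAsFactors = FALSE)
  }))
  new_structure(atoms, identifier = id)
}

# three-residue all-atom-ish chain used by selection tests
three_residue_structure <- function() {
  toy_structure(list(
    list("N",  "ALA", 1, 0.0, 0.0, 0.0),
    list("CA", "ALA", 1, 1.5, 0.0, 0.0),
    list("CB", "ALA", 1, 2.0, 1.0, 0.0),
    list("N",  "GLY", 2, 3.0, 0.0, 0.0),
    list("CA", "GLY", 2, 4.5, 0.0, 0.0),
    list("N",  "VAL", 3, 6.0, 0.0, 0.0),
    list("CA", "VAL", 3, 7.5, 0.0, 0.0),
    list("CG1", "VAL", 3, 8.0, 1.0, 0.0)
  ))
}

# ensemble built directly from a topology and a list of frames
toy_ensemble <- function(topology, frames) {
  new_ensemble(topology, frames)
}

# a single-CA-per-residue topology with n residues at given base coords
ca_chain <- function(base) {
  toy_structure(lapply(seq_len(nrow(base)), function(i) {
    list("CA", "ALA", i, base[i, 1], base[i, 2], base[i, 3])
  }))
}

random_proper_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

write_lines_tmp <- function(lines, ext = ".pdb") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
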