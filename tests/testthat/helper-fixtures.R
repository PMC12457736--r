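# Shared fixtures and memoized expensive results.
#
# All fixtures are fully deterministic (no seeds): the generator builds
# idealized internal-coordinate geometry and the SASA quadrature is a fixed
# Fibonacci lattice.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Polar-faced two-helix bundle at a loose contact distance: the designed
# positive of the detector smoke test.
fx_bundle <- function() cached("fx_bundle", function() {
  s <- polar_face_sequence(14)
  make_structure(fixture_spec(c(s, s), geometry = "two-helix-bundle",
                              contact_distance = 10.5))
})

# All-leucine bundle at a tight distance: the designed negative.
fx_control <- function() cached("fx_control", function() {
  s <- paste(rep("L", 14), collapse = "")
  make_structure(fixture_spec(c(s, s), geometry = "two-helix-bundle",
                              contact_distance = 9.5))
})

# Exact C2 homodimer of a 16-mer helix.
fx_dimer <- function() cached("fx_dimer", function() {
  make_structure(fixture_spec("LLSNLLSNLLSNLLLL", geometry = "symmetric-dimer",
                              contact_distance = 10.5))
})

# Isolated 20-residue helix (no tertiary contacts).
fx_helix20 <- function() cached("fx_helix20", function() {
  make_structure(fixture_spec(polar_face_sequence(20),
                              geometry = "ideal-helix"))
})

res_bundle <- function() cached("res_bundle", function() {
  suppressWarnings(find_lips(fx_bundle()$structure))
})

res_control <- function() cached("res_control", function() {
  suppressWarnings(find_lips(fx_control()$structure))
})

res_dimer <- function() cached("res_dimer", function() {
  suppressWarnings(find_lips(fx_dimer()$structure))
})

# Minimal hand-written PDB text: Ala-Gly dipeptide, 9 heavy atoms.
ala_gly_pdb <- function() c(
  "ATOM      1  N   ALA A   1      -0.525   1.362   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       1.520   0.000   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       2.197   0.998   0.000  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1      -0.507  -0.721  -1.245  1.00  0.00           C",
  "ATOM      6  N   GLY A   2       2.042  -1.206   0.122  1.00  0.00           N",
  "ATOM      7  CA  GLY A   2       3.475  -1.417   0.153  1.00  0.00           C",
  "ATOM      8  C   GLY A   2       4.072  -1.192   1.535  1.00  0.00           C",
  "ATOM      9  O   GLY A   2       3.373  -0.770   2.459  1.00  0.00           O")

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# Construct a synthetic lip_profile for rule-level detector tests.
synthetic_profile <- function(pr, rho, rho_mean = mean(rho, na.rm = TRUE),
                              rho_sd = stats::sd(rho[!is.na(rho)])) {
  n <- length(pr)
  pts <- data.frame(chain = "A", mode = "intra", partner = NA_character_,
                    key = paste0("A:", seq_len(n), ":"),
                    resno = seq_len(n), icode = "", resname = "ALA",
                    pr = pr, rho = rho,
                    n_interface_atoms = ifelse(is.na(pr), NA_integer_, 10L),
                    stringsAsFactors = FALSE)
  out <- list(points = pts, chain = "A", mode = "intra",
              partner = NA_character_, rho_mean = rho_mean, rho_sd = rho_sd,
              params = lip_params())
  class(out) <- "lip_profile"
  out
}
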