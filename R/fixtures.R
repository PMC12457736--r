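AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# place atom D from reference atoms A-B-C with bond |CD|, angle B-C-D and
# torsion A-B-C-D (NeRF construction; angles in degrees)
place_atom <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi),
          bond * sin(th) * sin(chi))
  C + bc * d2[1] + m * d2[2] + n * d2[3]
}

virtual_cb <- function(N, CA, C) {
  b <- CA - N; c <- C - CA
  a <- c(b[2] * c[3] - b[3] * c[2],
         b[3] * c[1] - b[1] * c[3],
         b[1] * c[2] - b[2] * c[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * c + CA
}

# gamma (and, for Asn/Asp, delta) side-chain stub definitions:
# list of atoms placed from (N, CA, CB) or (CA, CB, CG) frames
side_stub <- function(res) {
  g <- function(name, bond, chi1) {
    list(name = name, frame = "gamma", bond = bond, angle = 114.0,
         torsion = chi1)
  }
  d <- function(name, bond, chi2) {
    list(name = name, frame = "delta", bond = bond, angle = 120.0,
         torsion = chi2)
  }
  switch(res,
    GLY = list(cb = FALSE, extra = list()),
    ALA = list(cb = TRUE, extra = list()),
    SER = list(cb = TRUE, extra = list(g("OG", 1.417, -60))),
    CYS = list(cb = TRUE, extra = list(g("SG", 1.808, -60))),
    THR = list(cb = TRUE, extra = list(g("OG1", 1.433, -60),
                                       g("CG2", 1.521, 60))),
    VAL = list(cb = TRUE, extra = list(g("CG1", 1.521, 175),
                                       g("CG2", 1.521, -65))),
    ILE = list(cb = TRUE, extra = list(g("CG1", 1.530, -60),
                                       g("CG2", 1.521, 60))),
    ASN = list(cb = TRUE, extra = list(g("CG", 1.516, -65),
                                       d("OD1", 1.231, -58),
                                       d("ND2", 1.328, 122))),
    ASP = list(cb = TRUE, extra = list(g("CG", 1.516, -65),
                                       d("OD1", 1.249, -58),
                                       d("OD2", 1.249, 122))),
    # all remaining residue types: a single gamma carbon stub
    list(cb = TRUE, extra = list(g(if (res == "PRO") "CG" else "CG",
                                   1.530, -60))))
}

build_peptide <- function(seq3, phi, psi) {
  n <- length(seq3)
  if (length(phi) == 1) phi <- rep(phi, n)
  if (length(psi) == 1) psi <- rep(psi, n)
  rows <- list()
  Np <- CAp <- Cp <- NULL
  for (i in seq_len(n)) {
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      C <- place_atom(c(0, 1, 0), N, CA, 1.525, 111.2, 0)
    } else {
      N <- place_atom(Np, CAp, Cp, 1.329, 116.2, psi[i - 1])
      CA <- place_atom(CAp, Cp, N, 1.458, 121.7, 180)
      C <- place_atom(Cp, N, CA, 1.525, 111.2, phi[i])
    }
    O <- place_atom(N, CA, C, 1.231, 120.8, psi[i] + 180)
    res <- seq3[i]
    at <- list(N = N, CA = CA, C = C, O = O)
    stub <- side_stub(res)
    if (stub$cb) {
      CB <- virtual_cb(N, CA, C)
      at$CB <- CB
      for (ex in stub$extra) {
        if (ex$frame == "gamma") {
          at[[ex$name]] <- place_atom(N, CA, CB, ex$bond, ex$angle,
                                      ex$torsion)
        } else {
          CG <- at$CG
          at[[ex$name]] <- place_atom(CA, CB, CG, ex$bond, ex$angle,
                                      ex$torsion)
        }
      }
    }
    rows[[i]] <- data.frame(resi = i, resname = res,
                            name = names(at),
                            x = vapply(at, `[`, 0, 1),
                            y = vapply(at, `[`, 0, 2),
                            z = vapply(at, `[`, 0, 3),
                            stringsAsFactors = FALSE)
    Np <- N; CAp <- CA; Cp <- C
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# rotate/translate helper; R is 3x3, t length-3
transform_atoms <- function(at, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + t[1]
  at$y <- xyz[, 2] + t[2]
  at$z <- xyz[, 3] + t[3]
  at
}

# deterministic standardization: CA centroid to origin, principal axis of
# the CA trace to +z (pointing from first to last residue), first CA to +x
standardize_axis <- function(at) {
  ca <- as.matrix(at[at$name == "CA", c("x", "y", "z")])
  ctr <- colMeans(ca)
  sv <- svd(sweep(ca, 2, ctr))
  v <- sv$v[, 1]
  if (sum((ca[nrow(ca), ] - ca[1, ]) * v) < 0) v <- -v
  # orthonormal frame with v as z
  u <- c(1, 0, 0)
  if (abs(sum(u * v)) > 0.9) u <- c(0, 1, 0)
  u <- u - sum(u * v) * v; u <- u / sqrt(sum(u^2))
  w <- c(v[2] * u[3] - v[3] * u[2],
         v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  R <- rbind(u, w, v)  # maps v -> z
  at <- transform_atoms(at, R = R, t = -as.vector(R %*% ctr))
  # fix the rotation about z so the first CA points along +x
  ca1 <- unlist(at[at$name == "CA", c("x", "y")][1, ])
  ang <- atan2(ca1[2], ca1[1])
  Rz <- rbind(c(cos(-ang), -sin(-ang), 0), c(sin(-ang), cos(-ang), 0),
              c(0, 0, 1))
  transform_atoms(at, R = Rz)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
}

#' Specification of a synthetic test structure
#'
#' Describes a deterministic idealized structure: a single helix or
#' extended strand, a two-helix bundle within one chain (the two helices
#' separated by a numbering/structural gap), or a C2-symmetric two-chain
#' dimer.  Side chains are idealized stubs: backbone plus CB and the gamma
#' atom(s), extended to the delta heteroatoms for Asn/Asp so that
#' polar-face designs expose genuine polar side-chain surface.
#'
#' @param sequence one-letter sequence (one string; for the bundle either
#'   one string split in half or a vector of two).
#' @param geometry `"ideal-helix"`, `"extended"`, `"two-helix-bundle"` or
#'   `"symmetric-dimer"`.
#' @param contact_distance axis separation of the two helices (angstroms).
#' @param face_rot extra rotation (degrees) of each helix about its own
#'   axis, to aim a chosen face at the partner.
#' @param gap_size number of author positions skipped between the two
#'   helices of a bundle (a structural gap).
#' @param numbering_start author number of the first residue.
#' @param chain_ids chain identifier(s).
#' @param sites optional named list: site id -> vector of author residue
#'   numbers (on the first chain) to emit as SITE records.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(sequence,
                         geometry = c("ideal-helix", "extended",
                                      "two-helix-bundle", "symmetric-dimer"),
                         contact_distance = 10, face_rot = 0,
                         gap_size = 4, numbering_start = 1,
                         chain_ids = NULL, sites = list()) {
  geometry <- match.arg(geometry)
  seqs <- toupper(sequence)
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 names(AA1TO3))
  if (length(bad)) stop("non-canonical letter(s) in sequence: ",
                        paste(bad, collapse = ""))
  if (geometry == "two-helix-bundle" && length(seqs) == 1) {
    n <- nchar(seqs)
    seqs <- c(substr(seqs, 1, n %/% 2), substr(seqs, n %/% 2 + 1, n))
  }
  if (is.null(chain_ids)) {
    chain_ids <- if (geometry == "symmetric-dimer") c("A", "B") else "A"
  }
  structure(list(sequence = seqs, geometry = geometry,
                 contact_distance = contact_distance, face_rot = face_rot,
                 gap_size = gap_size, numbering_start = numbering_start,
                 chain_ids = chain_ids, sites = sites),
            class = "fixture_spec")
}

#' Build a helix sequence with a designed contact face
#'
#' Substitutes `polar` residues at roughly one helical face (period 3.6,
#' here positions congruent to 1 or 4/5 modulo 7 by default) of a `base`
#' background.
#'
#' @param n sequence length.
#' @param base background one-letter residue.
#' @param polar one-letter residue(s) for the face (recycled).
#' @param positions explicit positions (default: a heptad-like face).
#' @return one-letter sequence string.
#' @export
polar_face_sequence <- function(n, base = "L", polar = c("S", "N"),
                                positions = NULL) {
  if (is.null(positions)) {
    k <- seq_len(n) %% 7
    positions <- which(k == 1 | k == 4 | k == 5)
  }
  s <- rep(base, n)
  s[positions] <- rep(polar, length.out = length(positions))
  paste(s, collapse = "")
}

#' Generate a synthetic structure
#'
#' Builds the idealized coordinates described by a [fixture_spec()]
#' (helical phi/psi of -60/-47, which with the ideal bond geometry used
#' here reproduces the canonical 1.5 angstrom rise and 3.6-residue turn;
#' extended -139/+135), emits standard
#' PDB text, and parses it back through [read_pdb()] so the returned model
#' has passed the same code path as user input.  Output is bit-identical
#' for identical specs: there is no randomness anywhere.
#'
#' @param spec a `fixture_spec`.
#' @return list with `structure` (a `lip_structure`) and `pdb` (character
#'   vector of PDB lines).
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  hel <- c(phi = -60, psi = -47)
  ext <- c(phi = -139, psi = 135)
  seq3 <- lapply(spec$sequence,
                 function(s) unname(AA1TO3[strsplit(s, "")[[1]]]))
  d <- spec$contact_distance
  parts <- list()
  if (spec$geometry %in% c("ideal-helix", "extended")) {
    pp <- if (spec$geometry == "extended") ext else hel
    at <- standardize_axis(build_peptide(seq3[[1]], pp["phi"], pp["psi"]))
    at$chain <- spec$chain_ids[1]
    at$resno <- at$resi + spec$numbering_start - 1L
    parts[[1]] <- at
  } else if (spec$geometry == "two-helix-bundle") {
    h1 <- standardize_axis(build_peptide(seq3[[1]], hel["phi"], hel["psi"]))
    h2 <- standardize_axis(build_peptide(seq3[[2]], hel["phi"], hel["psi"]))
    h1 <- transform_atoms(h1, R = rot_z(spec$face_rot))
    h2 <- transform_atoms(h2, R = rot_z(-spec$face_rot))
    h2 <- transform_atoms(h2, R = rot_y(180))      # antiparallel
    h2 <- transform_atoms(h2, t = c(d, 0, 0))
    h1$chain <- h2$chain <- spec$chain_ids[1]
    n1 <- length(seq3[[1]])
    h1$resno <- h1$resi + spec$numbering_start - 1L
    h2$resno <- h2$resi + n1 + spec$gap_size + spec$numbering_start - 1L
    parts <- list(h1, h2)
  } else {  # symmetric-dimer: exact C2 about the z axis
    a <- standardize_axis(build_peptide(seq3[[1]], hel["phi"], hel["psi"]))
    a <- transform_atoms(a, R = rot_z(spec$face_rot))
    a <- transform_atoms(a, t = c(-d / 2, 0, 0))
    b <- transform_atoms(a, R = rot_z(180))
    a$chain <- spec$chain_ids[1]
    b$chain <- spec$chain_ids[2]
    a$resno <- b$resno <- a$resi + spec$numbering_start - 1L
    parts <- list(a, b)
  }
  atoms <- do.call(rbind, parts)
  lines <- character(0)
  serial <- 0L
  prev_chain <- NULL
  for (i in seq_len(nrow(atoms))) {
    if (!is.null(prev_chain) && atoms$chain[i] != prev_chain) {
      lines <- c(lines, "TER")
    }
    prev_chain <- atoms$chain[i]
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, atoms$name[i], atoms$resname[i], atoms$chain[i],
      atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i], 1.00, 0.00,
      substr(atoms$name[i], 1, 1)))
  }
  site_lines <- character(0)
  if (length(spec$sites)) {
    rt <- atoms[!duplicated(paste(atoms$chain, atoms$resno)), ]
    for (sid in names(spec$sites)) {
      resnos <- spec$sites[[sid]]
      recs <- split(resnos, (seq_along(resnos) - 1) %/% 4)
      for (k in seq_along(recs)) {
        chunk <- vapply(recs[[k]], function(rn) {
          row <- rt[rt$chain == spec$chain_ids[1] & rt$resno == rn, ]
          if (!nrow(row)) stop("SITE residue ", rn, " not in fixture")
          sprintf("%3s %s%4d  ", row$resname[1], row$chain[1], rn)
        }, "")
        site_lines <- c(site_lines, sprintf(
          "SITE   %3d %3s %2d %s", k, sid, length(resnos),
          paste(chunk, collapse = "")))
      }
    }
  }
  lines <- c(site_lines, lines, "TER", "END")
  list(structure = read_pdb(lines), pdb = lines)
}
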