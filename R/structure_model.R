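CANONICAL_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3")
# modified polymer residues mapped to their parent amino acid on read
MODRES_MAP <- c(MSE = "MET")

#' Residue keys
#'
#' Residues are identified throughout the package by the triple
#' (chain, author residue number, insertion code), encoded as the string
#' `"chain:resno:icode"`.
#'
#' @param chain,resno,icode vectors of chain identifiers, author residue
#'   numbers and insertion codes (empty string when absent).
#' @return character vector of keys.
#' @export
res_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste(chain, resno, icode, sep = ":")
}

source_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

derive_element <- function(elety, elesy) {
  e <- toupper(trimws(elesy))
  miss <- is.na(e) | !nzchar(e)
  if (any(miss)) {
    nm <- toupper(gsub("[^A-Z]", "", toupper(elety[miss])))
    guess <- substr(nm, 1, 1)
    guess[substr(nm, 1, 2) == "SE"] <- "SE"
    e[miss] <- guess
  }
  e
}

#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records (first model only) via \pkg{bio3d}, then
#' applies the conventions used by the LIP method: hydrogens and waters are
#' discarded; alternate locations are resolved by keeping the
#' highest-occupancy copy (ties broken by altloc letter); selenomethionine
#' (MSE) in the polymer is mapped to MET and flagged non-canonical; other
#' HETATM residues are excluded from the coordinate model but retained as
#' bookkeeping entries so SITE annotations naming them are not lost.  Every
#' retained atom is assigned a van der Waals radius and a polarity class.
#'
#' @param source path to a PDB file, or PDB text (a single string or a
#'   character vector of lines).
#' @param on_unknown_element `"error"` (default) to stop when an atom's
#'   element has no radius/polarity entry, `"skip"` to drop such atoms with
#'   a warning.
#' @param radii,polarity parameter tables (see [radii_table()],
#'   [polarity_table()]).
#' @return an object of class `lip_structure`: a list with elements
#'   `atoms` (data frame with one row per retained heavy atom: serial, name,
#'   element, polarity, radius, coordinates, occupancy, residue identity and
#'   key), `sites` (parsed SITE annotations), `het_residues` (non-water
#'   HETATM residues excluded from the model) and `provenance`.
#' @export
read_pdb <- function(source, on_unknown_element = c("error", "skip"),
                     radii = radii_table(), polarity = polarity_table()) {
  on_unknown_element <- match.arg(on_unknown_element)
  lines <- source_lines(source)
  prov <- if (length(source) == 1 && !grepl("\n", source) &&
              file.exists(source)) normalizePath(source) else "<text>"
  if (!any(grepl("^ATOM", lines))) {
    stop("no ATOM records found in PDB input")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1

  at$element <- derive_element(at$elety, at$elesy)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]

  is_water <- at$resid %in% WATER_NAMES
  het <- at$type == "HETATM" & !(at$resid %in% names(MODRES_MAP))
  het_res <- unique(at[het & !is_water,
                       c("chain", "resno", "insert", "resid"), drop = FALSE])
  names(het_res) <- c("chain", "resno", "icode", "resname")
  rownames(het_res) <- NULL

  at <- at[!is_water & !het, , drop = FALSE]
  if (nrow(at) == 0) stop("no polymer atoms retained from PDB input")

  # altloc resolution: highest occupancy, ties by altloc letter order
  akey <- paste(at$chain, at$resno, at$insert, at$elety)
  if (anyDuplicated(akey)) {
    ord <- order(akey, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
             drop = FALSE]
    at <- at[order(match(at$eleno, pdb$atom$eleno)), , drop = FALSE]
  }

  resname_orig <- at$resid
  mod <- at$resid %in% names(MODRES_MAP)
  at$resid[mod] <- MODRES_MAP[at$resid[mod]]

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = at$element,
    resname = at$resid,
    resname_orig = resname_orig,
    chain = at$chain,
    resno = at$resno,
    icode = at$insert,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    altloc = at$alt,
    canonical = at$resid %in% CANONICAL_AA & !mod,
    stringsAsFactors = FALSE)
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)

  r <- assign_radii(atoms$resname, atoms$name, atoms$element, table = radii,
                    on_unknown = on_unknown_element)
  if (anyNA(r)) {
    warning(sum(is.na(r)), " atom(s) with unknown element skipped")
    atoms <- atoms[!is.na(r), , drop = FALSE]
    r <- r[!is.na(r)]
  }
  atoms$radius <- r
  atoms$polarity <- atom_polarity(atoms$element, table = polarity)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in PDB input")
  }
  rownames(atoms) <- NULL

  str <- new_lip_structure(atoms, sites = list(), het_residues = het_res,
                           provenance = prov)
  str$sites <- parse_site_records(lines, structure = str)
  str
}

new_lip_structure <- function(atoms, sites = list(),
                              het_residues = NULL, provenance = "") {
  if (is.null(het_residues)) {
    het_residues <- data.frame(chain = character(0), resno = integer(0),
                               icode = character(0), resname = character(0),
                               stringsAsFactors = FALSE)
  }
  structure(list(atoms = atoms, sites = sites, het_residues = het_residues,
                 provenance = provenance),
            class = "lip_structure")
}

#' @export
print.lip_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("lip_structure:", nrow(x$atoms), "atoms,", nrow(rt), "residues,",
      length(unique(rt$chain)), "chain(s)",
      if (length(x$sites)) paste0(", ", length(x$sites), " SITE(s)") else "",
      "\n", sep = " ")
  invisible(x)
}

#' Residue-level view of a structure
#'
#' @param structure a `lip_structure`.
#' @param chain optional chain id to restrict to.
#' @return data frame with one row per residue in file order: chain, resno,
#'   icode, resname, key, canonical flag, atom count.
#' @export
residue_table <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  first <- !duplicated(a$key)
  rt <- a[first, c("chain", "resno", "icode", "resname", "key", "canonical"),
          drop = FALSE]
  rt$n_atoms <- as.vector(table(a$key)[rt$key])
  rownames(rt) <- NULL
  rt
}

#' Chains present in a structure
#' @param structure a `lip_structure`.
#' @return character vector of chain ids in file order.
#' @export
structure_chains <- function(structure) {
  unique(structure$atoms$chain)
}

#' Numbering gaps in author residue numbering
#'
#' Reports every place where the author residue number of consecutive
#' residues in a chain jumps by more than one (insertion-coded runs are not
#' treated as jumps).
#'
#' @param structure a `lip_structure`.
#' @return data frame with columns chain, before (key), after (key),
#'   missing (number of skipped author positions).
#' @export
sequence_gaps <- function(structure) {
  out <- list()
  for (ch in structure_chains(structure)) {
    rt <- residue_table(structure, chain = ch)
    if (nrow(rt) < 2) next
    d <- diff(rt$resno)
    idx <- which(d > 1)
    if (length(idx)) {
      out[[ch]] <- data.frame(chain = ch,
                              before = rt$key[idx], after = rt$key[idx + 1],
                              missing = d[idx] - 1L,
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chain = character(0), before = character(0),
                      after = character(0), missing = integer(0),
                      stringsAsFactors = FALSE))
  }
  rr <- do.call(rbind, out)
  rownames(rr) <- NULL
  rr
}

#' Contiguous solved segments of a chain
#'
#' Two consecutive residues belong to the same segment when they are joined
#' by a plausible peptide bond (C to next N distance below `max_peptide`);
#' when either backbone atom is missing, consecutive author numbering is
#' used as a fallback.  Numbering jumps across an intact peptide bond
#' (renumbering artifacts) do not split a segment, but unsolved residues do.
#'
#' @param structure a `lip_structure`.
#' @param chain chain id.
#' @param max_peptide maximum C-N distance for a peptide bond (angstroms).
#' @return list of character vectors of residue keys, one per segment, in
#'   file order.
#' @export
chain_segments <- function(structure, chain, max_peptide = 2.0) {
  rt <- residue_table(structure, chain = chain)
  if (nrow(rt) == 0) return(list())
  a <- structure$atoms
  cpos <- a[a$chain == chain & a$name == "C", c("key", "x", "y", "z")]
  npos <- a[a$chain == chain & a$name == "N", c("key", "x", "y", "z")]
  linked <- logical(nrow(rt) - 1)
  for (i in seq_len(max(nrow(rt) - 1, 0))) {
    ci <- match(rt$key[i], cpos$key)
    ni <- match(rt$key[i + 1], npos$key)
    if (!is.na(ci) && !is.na(ni)) {
      d <- sqrt((cpos$x[ci] - npos$x[ni])^2 + (cpos$y[ci] - npos$y[ni])^2 +
                (cpos$z[ci] - npos$z[ni])^2)
      linked[i] <- d <= max_peptide
    } else {
      linked[i] <- (rt$resno[i + 1] - rt$resno[i]) == 1
    }
  }
  seg_id <- cumsum(c(1L, as.integer(!linked)))
  unname(split(rt$key, seg_id))
}

#' Crop residues out of a structure
#'
#' Partitions a structure into the residues outside `span` (retained) and
#' the residues of `span` (removed); coordinates are untouched, so merging
#' the two parts reproduces the original atom set.
#'
#' @param structure a `lip_structure`.
#' @param span character vector of residue keys to crop out.
#' @return list with elements `retained` and `removed`, both `lip_structure`.
#' @export
crop <- function(structure, span) {
  if (length(span) == 0) stop("empty crop span")
  all_keys <- unique(structure$atoms$key)
  if (!all(span %in% all_keys)) {
    stop("crop span contains residues absent from the structure: ",
         paste(setdiff(span, all_keys), collapse = ", "))
  }
  inside <- structure$atoms$key %in% span
  list(
    retained = new_lip_structure(structure$atoms[!inside, , drop = FALSE],
                                 sites = structure$sites,
                                 het_residues = structure$het_residues,
                                 provenance = structure$provenance),
    removed = new_lip_structure(structure$atoms[inside, , drop = FALSE],
                                sites = structure$sites,
                                het_residues = structure$het_residues,
                                provenance = structure$provenance))
}

#' Keep only selected chains
#' @param structure a `lip_structure`.
#' @param chains chain ids to keep.
#' @return a `lip_structure`.
#' @export
select_chains <- function(structure, chains) {
  keep <- structure$atoms$chain %in% chains
  if (!any(keep)) stop("no atoms in chain(s) ", paste(chains, collapse = ","))
  new_lip_structure(structure$atoms[keep, , drop = FALSE],
                    sites = structure$sites,
                    het_residues = structure$het_residues,
                    provenance = structure$provenance)
}

#' Merge two structures (inverse of crop)
#' @param a,b `lip_structure` objects with disjoint atoms.
#' @return a `lip_structure` with atoms ordered by serial number.
#' @export
merge_structures <- function(a, b) {
  atoms <- rbind(a$atoms, b$atoms)
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  new_lip_structure(atoms, sites = a$sites, het_residues = a$het_residues,
                    provenance = a$provenance)
}

#' Parse SITE records from PDB text
#'
#' SITE records spanning several continuation lines are combined by site
#' identifier.  When a structure is supplied, each member is flagged with
#' whether it resolves to a polymer residue of the model (`is_protein`) or
#' to a HETATM bookkeeping entry; unresolvable members are kept and flagged.
#'
#' @param source path to a PDB file or PDB text.
#' @param structure optional `lip_structure` to resolve members against.
#' @return list of site annotations, each a list with `site_id` and a
#'   `members` data frame (chain, resno, icode, resname, is_protein,
#'   in_structure).
#' @export
parse_site_records <- function(source, structure = NULL) {
  lines <- source_lines(source)
  site_lines <- lines[startsWith(lines, "SITE")]
  if (!length(site_lines)) return(list())
  members <- list()
  for (ln in site_lines) {
    ln <- sprintf("%-61s", ln)
    site_id <- trimws(substr(ln, 12, 14))
    if (!nzchar(site_id)) {
      warning("malformed SITE record skipped: ", trimws(ln))
      next
    }
    for (k in 0:3) {
      off <- 11 * k
      resname <- trimws(substr(ln, 19 + off, 21 + off))
      chain <- trimws(substr(ln, 23 + off, 23 + off))
      resno <- trimws(substr(ln, 24 + off, 27 + off))
      icode <- trimws(substr(ln, 28 + off, 28 + off))
      if (!nzchar(resname) && !nzchar(resno)) next
      resno_i <- suppressWarnings(as.integer(resno))
      if (is.na(resno_i)) {
        warning("malformed SITE member skipped in site ", site_id)
        next
      }
      members[[length(members) + 1]] <-
        data.frame(site_id = site_id, chain = chain, resno = resno_i,
                   icode = icode, resname = resname, stringsAsFactors = FALSE)
    }
  }
  if (!length(members)) return(list())
  mm <- do.call(rbind, members)
  out <- lapply(split(mm, mm$site_id), function(df) {
    df <- df[!duplicated(df[c("chain", "resno", "icode")]), , drop = FALSE]
    df$key <- res_key(df$chain, df$resno, df$icode)
    if (!is.null(structure)) {
      poly <- unique(structure$atoms$key)
      hetk <- res_key(structure$het_residues$chain,
                      structure$het_residues$resno,
                      structure$het_residues$icode)
      df$is_protein <- df$key %in% poly
      df$in_structure <- df$is_protein | df$key %in% hetk
    } else {
      df$is_protein <- NA
      df$in_structure <- NA
    }
    rownames(df) <- NULL
    list(site_id = df$site_id[1],
         members = df[, setdiff(names(df), "site_id"), drop = FALSE])
  })
  names(out) <- NULL
  out[order(vapply(out, function(s) s$site_id, ""))]
}

#' Write a structure back to PDB format
#'
#' Minimal writer (ATOM records only) used for debugging crops and for
#' round-trip tests.
#'
#' @param structure a `lip_structure`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(structure, file) {
  a <- structure$atoms
  suppressWarnings(bio3d::write.pdb(
    file = file,
    eleno = a$serial, elety = a$name, resid = a$resname, chain = a$chain,
    resno = a$resno, insert = ifelse(nzchar(a$icode), a$icode, ""),
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element))
  invisible(file)
}
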