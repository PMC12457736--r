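#' Parameter tables
#'
#' The package ships its numeric parameter tables as editable plain-text
#' TSV files under `inst/extdata`: van der Waals radii (Chothia-style, the
#' set used by classic SASA programs), element polarity classes, per-residue
#' theoretical maximum SASA values (Tien et al. 2013), and standard Voronoi
#' atomic volumes (Tsai/Gerstein-style mean volumes per protein heavy-atom
#' type, expanded to residue/atom pairs).  Each loader accepts a `path`
#' argument so a user can substitute their own table.
#'
#' @param path optional path to a replacement TSV file.
#' @return a data frame with the table contents.
#' @name parameter_tables
NULL

table_path <- function(name) {
  p <- system.file("extdata", name, package = "lipscan")
  if (!nzchar(p)) stop("parameter table not found: ", name)
  p
}

#' @rdname parameter_tables
#' @export
radii_table <- function(path = NULL) {
  read.table(path %||% table_path("radii.tsv"), header = TRUE,
             sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname parameter_tables
#' @export
polarity_table <- function(path = NULL) {
  read.table(path %||% table_path("polarity.tsv"), header = TRUE,
             sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname parameter_tables
#' @export
max_sasa_table <- function(path = NULL) {
  read.table(path %||% table_path("max_sasa.tsv"), header = TRUE,
             sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname parameter_tables
#' @export
standard_volume_table <- function(path = NULL) {
  read.table(path %||% table_path("standard_volumes.tsv"), header = TRUE,
             sep = "\t", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign van der Waals radii to atoms
#'
#' Radii come from the (residue, atom) overrides of the radii table when one
#' matches, otherwise from the element default.  Trigonal carbons (backbone
#' carbonyl, aromatic rings, carboxyl/amide/guanidinium centres) carry the
#' smaller sp2 radius, all other carbons the tetrahedral one.
#'
#' @param resname,atomname,element character vectors of equal length.
#' @param table a radii table as returned by [radii_table()].
#' @param on_unknown `"error"` to stop on an element absent from the table,
#'   `"skip"` to return `NA` for it (callers then drop the atom with a
#'   warning).
#' @return numeric vector of radii in angstroms (`NA` for skipped atoms).
#' @export
assign_radii <- function(resname, atomname, element,
                         table = radii_table(),
                         on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  r <- rep(NA_real_, length(element))
  elem_rows <- table$resname == "*" & table$atomname == "*"
  edef <- setNames(table$radius[elem_rows], table$element[elem_rows])
  r[] <- edef[element]
  ov <- table[!elem_rows, , drop = FALSE]
  if (nrow(ov)) {
    key <- paste(resname, atomname)
    okey1 <- paste(ov$resname, ov$atomname)
    m <- match(key, okey1)
    hit <- !is.na(m)
    r[hit] <- ov$radius[m[hit]]
    # wildcard-residue overrides (e.g. the backbone carbonyl carbon "C")
    wc <- ov$resname == "*"
    if (any(wc)) {
      m2 <- match(atomname, ov$atomname[wc])
      hit2 <- !is.na(m2) & is.na(m)
      r[hit2] <- ov$radius[wc][m2[hit2]]
    }
  }
  if (anyNA(r) && on_unknown == "error") {
    bad <- which(is.na(r))[1]
    stop("no radius for atom ", atomname[bad], " (element ", element[bad],
         ") of ", resname[bad])
  }
  r
}

#' Classify atom polarity from element
#'
#' Nitrogen and oxygen atoms are polar; carbon, sulfur and selenium atoms
#' apolar.  This is the element-based partition used by NACCESS-style
#' polar/non-polar surface decompositions; it is supplied as an editable
#' table so sulfur can be reclassified if desired.
#'
#' @param element character vector of element symbols.
#' @param table a polarity table as returned by [polarity_table()].
#' @return character vector, each entry `"polar"` or `"apolar"`.
#' @export
atom_polarity <- function(element, table = polarity_table()) {
  cls <- setNames(table$polarity, table$element)[element]
  if (anyNA(cls)) {
    bad <- element[is.na(cls)][1]
    stop("cannot classify polarity of element '", bad, "'")
  }
  unname(cls)
}
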