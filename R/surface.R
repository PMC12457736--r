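#' Deterministic quadrature points on the unit sphere
#'
#' Golden-spiral (Fibonacci) lattice: quasi-uniform, fully deterministic for
#' a given `n`, so SASA values are exactly reproducible without seeds.
#'
#' @param n number of points.
#' @return an `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe (default 1.4 angstrom, a water molecule) over the
#' heavy atoms and integrates the accessible fraction of each atom's
#' expanded sphere over a fixed quasi-uniform point set.
#'
#' @param structure a `lip_structure`, or a data frame of atoms with columns
#'   x, y, z, radius (and key/polarity for the per-residue summaries).
#' @param probe probe radius in angstroms.
#' @param n_points number of quadrature points per atom (>= 32).
#' @return an object of class `sasa_result`: list with `per_atom` (numeric,
#'   one value per atom row, angstrom^2), `per_residue` (named by residue
#'   key), `per_residue_polar`/`per_residue_apolar` (polarity split),
#'   `atoms` (the atom table used), `probe`, `n_points`.
#' @export
atom_sasa <- function(structure, probe = 1.4, n_points = 960) {
  atoms <- if (inherits(structure, "lip_structure")) structure$atoms
           else structure
  stopifnot(nrow(atoms) >= 1, n_points >= 32)
  pts <- sphere_points(n_points)
  area <- sasa_cpp(as.matrix(atoms[, c("x", "y", "z")]), atoms$radius,
                   probe, pts)
  res <- list(per_atom = area, atoms = atoms, probe = probe,
              n_points = n_points)
  if (!is.null(atoms$key)) {
    keys <- unique(atoms$key)
    res$per_residue <- vapply(split(area, factor(atoms$key, levels = keys)),
                              sum, 0)
    if (!is.null(atoms$polarity)) {
      pol <- atoms$polarity == "polar"
      agg <- function(sel) {
        v <- setNames(rep(0, length(keys)), keys)
        if (any(sel)) {
          s <- vapply(split(area[sel],
                            factor(atoms$key[sel], levels = keys)), sum, 0)
          v[names(s)] <- s
        }
        v
      }
      res$per_residue_polar <- agg(pol)
      res$per_residue_apolar <- agg(!pol)
    }
  }
  class(res) <- "sasa_result"
  res
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("sasa_result:", length(x$per_atom), "atoms, total",
      round(sum(x$per_atom), 1), "A^2 (probe", x$probe, "A,",
      x$n_points, "points)\n")
  invisible(x)
}

#' Per-residue SASA change on cropping
#'
#' For every residue still present after a segment has been cropped out,
#' reports the solvent accessibility it gains: `delta = sasa_cropped -
#' sasa_full`.  Residues that packed against the removed segment gain
#' exposure (positive delta); a positive threshold on delta therefore
#' selects the segment's contact residues.
#'
#' @param full a `sasa_result` for the complete structure.
#' @param cropped a `sasa_result` for the structure with a span removed.
#' @return data frame with columns key, chain, resno, icode, resname,
#'   sasa_full, sasa_cropped, delta (angstrom^2), one row per residue of the
#'   cropped structure.
#' @export
delta_sasa <- function(full, cropped) {
  kc <- names(cropped$per_residue)
  kf <- names(full$per_residue)
  if (!all(kc %in% kf)) {
    stop("cropped structure contains residues absent from the full one")
  }
  at <- cropped$atoms[!duplicated(cropped$atoms$key),
                      c("key", "chain", "resno", "icode", "resname")]
  at <- at[match(kc, at$key), , drop = FALSE]
  out <- data.frame(at,
                    sasa_full = unname(full$per_residue[kc]),
                    sasa_cropped = unname(cropped$per_residue[kc]),
                    stringsAsFactors = FALSE)
  out$delta <- out$sasa_cropped - out$sasa_full
  rownames(out) <- NULL
  out
}

#' Relative solvent exposure
#'
#' SASA of a residue divided by the theoretical maximum for its residue
#' type.  Values above 1 can occur for distorted geometry and are returned
#' unclamped; non-canonical residues have no tabulated maximum and yield
#' `NA` (they are excluded from exposure tallies).
#'
#' @param resname 3-letter residue name vector.
#' @param sasa per-residue SASA values (angstrom^2).
#' @param table maximum-SASA table (see [max_sasa_table()]).
#' @return numeric vector of fractions (`NA` where undefined).
#' @export
relative_exposure <- function(resname, sasa, table = max_sasa_table()) {
  mx <- setNames(table$max_sasa, table$resname)[resname]
  unname(sasa / mx)
}

#' Exposure class from relative exposure
#'
#' Buried below 10%, intermediate from 10% to 40% (both ends inclusive),
#' exposed above 40%.
#'
#' @param rel relative exposure fractions.
#' @return character vector (`NA` where rel is `NA`).
#' @export
exposure_class <- function(rel) {
  out <- rep(NA_character_, length(rel))
  out[!is.na(rel) & rel < 0.10] <- "buried"
  out[!is.na(rel) & rel >= 0.10 & rel <= 0.40] <- "intermediate"
  out[!is.na(rel) & rel > 0.40] <- "exposed"
  out
}

#' Per-residue SASA summary table
#'
#' @param structure a `lip_structure`.
#' @param sasa optional precomputed `sasa_result` for it.
#' @param ... passed to [atom_sasa()].
#' @return data frame with chain, resno, icode, resname, sasa_total,
#'   sasa_polar, sasa_apolar, rel_exposure, class.
#' @export
residue_sasa_table <- function(structure, sasa = NULL, ...) {
  if (is.null(sasa)) sasa <- atom_sasa(structure, ...)
  rt <- residue_table(structure)
  out <- data.frame(rt[, c("chain", "resno", "icode", "resname", "key")],
                    sasa_total = unname(sasa$per_residue[rt$key]),
                    sasa_polar = unname(sasa$per_residue_polar[rt$key]),
                    sasa_apolar = unname(sasa$per_residue_apolar[rt$key]),
                    stringsAsFactors = FALSE)
  rel <- relative_exposure(out$resname, out$sasa_total)
  rel[!rt$canonical] <- NA
  out$rel_exposure <- rel
  out$class <- exposure_class(rel)
  out
}
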