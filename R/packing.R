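#' Voronoi atomic volumes
#'
#' Plain (unweighted, bisector-plane) Voronoi tessellation of the atom
#' centres.  Interior atoms receive the volume of their convex cell; cells
#' that reach the bounding region (surface atoms) are flagged unbounded and
#' carry no volume.
#'
#' @param structure a `lip_structure` or a data frame/matrix of coordinates
#'   (columns x, y, z).
#' @param box half-width of the clipping cube around each atom (angstroms);
#'   any genuine cell of a packed structure is far smaller, so a cell
#'   touching the cube extends to infinity in the true tessellation.
#' @param max_neighbors number of nearest atoms contributing candidate
#'   bisector planes.
#' @return data frame of class `voronoi_cells` with columns `volume`
#'   (angstrom^3, `NA` when unbounded) and `bounded`, one row per atom.
#' @export
voronoi_cells <- function(structure, box = 12.0, max_neighbors = 48) {
  xyz <- if (inherits(structure, "lip_structure")) {
    as.matrix(structure$atoms[, c("x", "y", "z")])
  } else {
    m <- as.matrix(as.data.frame(structure))
    if (all(c("x", "y", "z") %in% colnames(m))) m[, c("x", "y", "z")]
    else if (ncol(m) == 3) m
    else stop("coordinates must have columns x, y, z")
  }
  storage.mode(xyz) <- "double"
  if (nrow(xyz) < 5) stop("Voronoi tessellation needs at least 5 atoms")
  ctr <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-6 * max(sv[1], 1)) {
    stop("degenerate geometry: atoms are collinear or coplanar")
  }
  res <- voronoi_cpp(xyz, box = box, max_neighbors = max_neighbors)
  out <- data.frame(volume = res$volume, bounded = res$bounded)
  class(out) <- c("voronoi_cells", class(out))
  out
}

#' Look up standard atomic volumes
#'
#' Matches each atom against the (residue, atom) standard-volume table;
#' atoms without an exact match fall back to the element-level median with
#' a warning, and atoms matching neither raise an error.
#'
#' @param resname,atomname,element character vectors of equal length.
#' @param table standard-volume table (see [standard_volume_table()]).
#' @return numeric vector of reference volumes (angstrom^3).
#' @export
standard_volumes <- function(resname, atomname, element,
                             table = standard_volume_table()) {
  exact <- match(paste(resname, atomname),
                 paste(table$resname, table$atomname))
  v <- table$volume[exact]
  miss <- is.na(v)
  if (any(miss)) {
    fb <- match(paste("*", paste0("element:", element[miss])),
                paste(table$resname, table$atomname))
    v[miss] <- table$volume[fb]
    if (any(!is.na(fb))) {
      warning(sum(!is.na(fb)), " atom(s) without a tabulated standard ",
              "volume; element-level fallback used")
    }
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("no standard volume for atom ", atomname[bad], " of ",
           resname[bad], " (element ", element[bad], ")")
    }
  }
  v
}

#' Packing density of a set of interface atoms
#'
#' The ratio of summed standard atomic volumes to summed actual Voronoi
#' volumes over the interface atoms: values near 1 indicate packing as
#' tight as reference protein interiors, values below 1 looser packing.
#' Atoms whose Voronoi cell is unbounded contribute to neither sum (an atom
#' enters the numerator only if it enters the denominator).
#'
#' @param interface_idx integer indices (into the cell/volume vectors) of
#'   the interface atoms.
#' @param cells a `voronoi_cells` data frame for the same atom ordering.
#' @param std_vols standard volumes for the same atom ordering
#'   (see [standard_volumes()]).
#' @return a single number, or `NA` when no interface atom has a bounded
#'   cell.
#' @export
packing_density <- function(interface_idx, cells, std_vols) {
  if (length(interface_idx) == 0) stop("empty interface atom set")
  ok <- interface_idx[cells$bounded[interface_idx]]
  if (!length(ok)) return(NA_real_)
  sum(std_vols[ok]) / sum(cells$volume[ok])
}
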