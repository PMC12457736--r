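#' Default detection parameters
#'
#' Bundles the tunable thresholds of the LIP method with their standard
#' values: an 8-residue sliding probe, PR peak cut-off 0.8 with baseline
#' 0.5, packing test rho below the profile mean minus one standard
#' deviation, cLIP membership at delta-SASA above 1.0 angstrom^2, a 1.4
#' angstrom solvent probe with 960 quadrature points, and a 0.1 angstrom^2
#' per-atom buried-area cut-off for interface membership.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `lip_params`.
#' @export
lip_params <- function(...) {
  p <- list(window = 8L, pr_peak = 0.8, pr_base = 0.5, rho_k = 1.0,
            dsasa = 1.0, probe = 1.4, n_points = 960L,
            interface_cutoff = 0.1, pr_cap = 1e6, voronoi_box = 12.0)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  class(p) <- "lip_params"
  p
}

#' Buried-surface interface between a probe segment and its environment
#'
#' The probe and the environment are each evaluated in isolation and then
#' together; every atom's buried area is the SASA it loses on complexation,
#' `b = SASA(own component isolated) - SASA(complex)`.  Atoms burying more
#' than the interface cut-off form the interface; their buried areas are
#' summed by polarity class into the numerator (polar) and denominator
#' (apolar) of the polarity ratio.
#'
#' @param structure a `lip_structure` containing both components.
#' @param probe_keys residue keys of the probe segment.
#' @param env_keys residue keys of the environment (disjoint from the probe).
#' @param params a [lip_params()] object.
#' @param sasa_complex,sasa_probe,sasa_env optional precomputed
#'   `sasa_result` objects (the complex result may cover a superset of the
#'   two components; isolated results must cover the exact component).
#' @return an object of class `interface_patch`: list with `interface`
#'   (data frame: serial, key, name, polarity, side, b), `buried_polar`,
#'   `buried_apolar`, `probe_keys`, `env_keys`.
#' @export
interface_patch <- function(structure, probe_keys, env_keys,
                            params = lip_params(),
                            sasa_complex = NULL, sasa_probe = NULL,
                            sasa_env = NULL) {
  if (length(probe_keys) < params$window) {
    stop("probe has fewer than ", params$window,
         " residues; window positions at segment termini are undefined")
  }
  if (length(intersect(probe_keys, env_keys))) {
    stop("probe and environment residue sets overlap")
  }
  a <- structure$atoms
  pi_ <- which(a$key %in% probe_keys)
  ei <- which(a$key %in% env_keys)
  if (!length(pi_) || !length(ei)) stop("empty probe or environment")

  if (is.null(sasa_probe)) {
    sasa_probe <- atom_sasa(a[pi_, , drop = FALSE], probe = params$probe,
                            n_points = params$n_points)
  }
  if (is.null(sasa_env)) {
    sasa_env <- atom_sasa(a[ei, , drop = FALSE], probe = params$probe,
                          n_points = params$n_points)
  }
  ci <- c(pi_, ei)
  if (is.null(sasa_complex)) {
    sasa_complex <- atom_sasa(a[ci, , drop = FALSE], probe = params$probe,
                              n_points = params$n_points)
    complex_area <- setNames(sasa_complex$per_atom, a$serial[ci])
  } else {
    complex_area <- setNames(sasa_complex$per_atom,
                             sasa_complex$atoms$serial)
  }
  iso <- c(setNames(sasa_probe$per_atom, a$serial[pi_]),
           setNames(sasa_env$per_atom, a$serial[ei]))
  serials <- a$serial[ci]
  b <- iso[as.character(serials)] - complex_area[as.character(serials)]
  sel <- which(b > params$interface_cutoff)
  idx <- ci[sel]
  interface <- data.frame(serial = a$serial[idx], key = a$key[idx],
                          name = a$name[idx], polarity = a$polarity[idx],
                          side = ifelse(a$key[idx] %in% probe_keys,
                                        "probe", "env"),
                          b = unname(b[sel]), stringsAsFactors = FALSE)
  out <- list(interface = interface,
              buried_polar = sum(interface$b[interface$polarity == "polar"]),
              buried_apolar = sum(interface$b[interface$polarity == "apolar"]),
              probe_keys = probe_keys, env_keys = env_keys)
  class(out) <- "interface_patch"
  out
}

#' Polarity ratio of an interface
#'
#' Buried polar surface divided by buried apolar surface.  An all-apolar
#' interface gives 0; a purely polar one gives `Inf` (treated as above any
#' peak threshold); an empty interface is undefined (`NA`).
#'
#' @param patch an `interface_patch`.
#' @return a single number (possibly `Inf` or `NA`).
#' @export
polarity_ratio <- function(patch) {
  if (nrow(patch$interface) == 0) return(NA_real_)
  if (patch$buried_apolar == 0) {
    return(if (patch$buried_polar > 0) Inf else NA_real_)
  }
  patch$buried_polar / patch$buried_apolar
}

#' Sliding-window PR/rho profile of a chain
#'
#' Slides an `window`-residue probe along each contiguous solved segment of
#' the chain and assigns each window's polarity ratio (PR) and packing
#' density (rho) to the window's 4th residue.  In `intra` mode the
#' environment is the rest of the same chain once the probe is cropped out;
#' in `inter` mode it is the entire partner chain.  Windows never span
#' structural gaps, so profiles are discontinuous (undefined points) at
#' unsolved residues and at the first 3 / last `window - 4` positions of
#' each segment.  rho is evaluated over the window's interface atoms using
#' Voronoi cells of the full analysis structure (the chain itself for
#' `intra`, both chains for `inter`); its profile mean and standard
#' deviation are computed across this profile only.
#'
#' @param structure a `lip_structure`.
#' @param chain chain id to scan.
#' @param mode `"intra"` or `"inter"`.
#' @param partner partner chain id (required for `inter`).
#' @param params a [lip_params()] object.
#' @return an object of class `lip_profile`: list with `points` (data frame:
#'   chain, mode, partner, key, resno, icode, resname, pr, rho,
#'   n_interface_atoms), `rho_mean`, `rho_sd`, `chain`, `mode`, `partner`,
#'   `params`.
#' @export
scan_profile <- function(structure, chain, mode = c("intra", "inter"),
                         partner = NULL, params = lip_params()) {
  mode <- match.arg(mode)
  if (mode == "inter") {
    if (is.null(partner)) stop("inter mode requires a partner chain")
    if (identical(partner, chain)) stop("partner must differ from the chain")
    analysis <- select_chains(structure, c(chain, partner))
  } else {
    partner <- NA_character_
    analysis <- select_chains(structure, chain)
  }
  rt <- residue_table(analysis, chain = chain)
  w <- params$window
  points <- data.frame(chain = chain, mode = mode, partner = partner,
                       key = rt$key, resno = rt$resno, icode = rt$icode,
                       resname = rt$resname,
                       pr = NA_real_, rho = NA_real_,
                       n_interface_atoms = NA_integer_,
                       stringsAsFactors = FALSE)
  segs <- chain_segments(analysis, chain)
  empty <- !length(segs) || max(lengths(segs)) < w
  if (empty) {
    warning("chain ", chain, " has no contiguous segment of ", w,
            " solved residues; profile is empty")
  }

  a <- analysis$atoms
  cells <- voronoi_cells(analysis, box = params$voronoi_box)
  stdv <- standard_volumes(a$resname, a$name, a$element)

  chain_keys <- rt$key
  if (mode == "intra") {
    sasa_complex <- atom_sasa(analysis, probe = params$probe,
                              n_points = params$n_points)
    sasa_env_fixed <- NULL
  } else {
    env_keys_all <- residue_table(analysis, chain = partner)$key
    env_idx <- which(a$key %in% env_keys_all)
    sasa_env_fixed <- atom_sasa(a[env_idx, , drop = FALSE],
                                probe = params$probe,
                                n_points = params$n_points)
  }

  if (!empty) for (seg in segs) {
    if (length(seg) < w) next
    for (i in seq_len(length(seg) - w + 1)) {
      probe_keys <- seg[i:(i + w - 1)]
      center <- probe_keys[4]
      if (mode == "intra") {
        env_keys <- setdiff(chain_keys, probe_keys)
        if (!length(env_keys)) next
        patch <- interface_patch(analysis, probe_keys, env_keys,
                                 params = params,
                                 sasa_complex = sasa_complex)
      } else {
        patch <- interface_patch(analysis, probe_keys, env_keys_all,
                                 params = params,
                                 sasa_env = sasa_env_fixed)
      }
      pr <- polarity_ratio(patch)
      if (is.infinite(pr)) pr <- params$pr_cap
      row <- match(center, points$key)
      points$pr[row] <- pr
      points$n_interface_atoms[row] <- nrow(patch$interface)
      if (nrow(patch$interface)) {
        idx <- match(patch$interface$serial, a$serial)
        points$rho[row] <- packing_density(idx, cells, stdv)
      }
    }
  }
  rho_def <- points$rho[!is.na(points$rho)]
  out <- list(points = points, chain = chain, mode = mode, partner = partner,
              rho_mean = if (length(rho_def)) mean(rho_def) else NA_real_,
              rho_sd = if (length(rho_def) > 1) sd(rho_def) else NA_real_,
              params = params)
  class(out) <- "lip_profile"
  out
}

#' @export
print.lip_profile <- function(x, ...) {
  nd <- sum(!is.na(x$points$pr))
  cat("lip_profile: chain ", x$chain, ", mode ", x$mode,
      if (x$mode == "inter") paste0(" (partner ", x$partner, ")"), ", ",
      nd, " defined points of ", nrow(x$points),
      ", rho mean ", signif(x$rho_mean, 4), " sd ", signif(x$rho_sd, 4),
      "\n", sep = "")
  invisible(x)
}

#' Detect mLIPs on a profile
#'
#' Finds local PR maxima above the peak threshold, extends each over
#' adjacent defined points while PR stays above the baseline, merges
#' candidate regions that share residues, and keeps a region only when at
#' least one of its residues has a rho value below the profile mean minus
#' `rho_k` standard deviations.
#'
#' @param profile a `lip_profile`.
#' @param params a [lip_params()] object (peak/baseline/rho thresholds).
#' @return list of `mlip` objects, each with chain, mode, partner, span
#'   (residue keys), resno_from/resno_to, peak_pr, residues (profile rows).
#' @export
detect_mlips <- function(profile, params = profile$params %||% lip_params()) {
  p <- profile$points
  if (!any(!is.na(p$pr))) return(list())
  rho_cut <- profile$rho_mean - params$rho_k * profile$rho_sd
  runs <- split(seq_len(nrow(p)),
                cumsum(is.na(p$pr)))  # defined runs share a cumsum level
  regions <- list()
  for (run in runs) {
    run <- run[!is.na(p$pr[run])]
    if (!length(run)) next
    pr <- p$pr[run]
    n <- length(pr)
    is_peak <- pr > params$pr_peak &
      pr >= c(-Inf, pr[-n]) & pr >= c(pr[-1], -Inf)
    for (k in which(is_peak)) {
      lo <- k
      while (lo > 1 && pr[lo - 1] > params$pr_base) lo <- lo - 1
      hi <- k
      while (hi < n && pr[hi + 1] > params$pr_base) hi <- hi + 1
      regions[[length(regions) + 1]] <- run[lo]:run[hi]
    }
  }
  if (!length(regions)) return(list())
  # merge regions sharing any residue
  regions <- regions[order(vapply(regions, min, 0L))]
  merged <- list(regions[[1]])
  for (r in regions[-1]) {
    last <- merged[[length(merged)]]
    if (min(r) <= max(last)) {
      merged[[length(merged)]] <- union(last, r)
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  out <- list()
  for (r in merged) {
    rho <- p$rho[r]
    if (is.na(rho_cut) || !any(!is.na(rho) & rho < rho_cut)) next
    ml <- list(chain = profile$chain, mode = profile$mode,
               partner = profile$partner,
               span = p$key[r],
               resno_from = p$resno[min(r)], resno_to = p$resno[max(r)],
               peak_pr = max(p$pr[r]),
               residues = p[r, , drop = FALSE])
    class(ml) <- "mlip"
    out[[length(out) + 1]] <- ml
  }
  out
}

#' @export
print.mlip <- function(x, ...) {
  cat("mLIP [", x$mode, "] chain ", x$chain,
      if (x$mode == "inter") paste0(" vs ", x$partner),
      ": residues ", x$resno_from, "-", x$resno_to,
      " (", length(x$span), " aa), peak PR ", signif(x$peak_pr, 4), "\n",
      sep = "")
  invisible(x)
}

#' cLIP of an mLIP
#'
#' Crops the mLIP span out of the analysis structure (the mLIP's chain for
#' intra mode; that chain plus its partner for inter mode) and recomputes
#' SASA; every remaining residue gaining more than the delta-SASA threshold
#' of exposure is a cLIP member.  Members need not be contiguous in
#' sequence and, by construction, exclude the mLIP span itself.
#'
#' @param structure a `lip_structure`.
#' @param mlip an `mlip` object.
#' @param params a [lip_params()] object.
#' @return an object of class `clip`: list with `mlip` and `members`
#'   (data frame: key, chain, resno, icode, resname, sasa_full,
#'   sasa_cropped, delta).
#' @export
compute_clip <- function(structure, mlip, params = lip_params()) {
  chains <- if (mlip$mode == "inter") c(mlip$chain, mlip$partner)
            else mlip$chain
  analysis <- select_chains(structure, chains)
  full <- atom_sasa(analysis, probe = params$probe,
                    n_points = params$n_points)
  cr <- crop(analysis, mlip$span)
  cropped <- atom_sasa(cr$retained, probe = params$probe,
                       n_points = params$n_points)
  ds <- delta_sasa(full, cropped)
  members <- ds[ds$delta > params$dsasa, , drop = FALSE]
  rownames(members) <- NULL
  out <- list(mlip = mlip, members = members)
  class(out) <- "clip"
  out
}

#' @export
print.clip <- function(x, ...) {
  cat("cLIP of ", x$mlip$chain, ":", x$mlip$resno_from, "-",
      x$mlip$resno_to, " [", x$mlip$mode, "]: ", nrow(x$members),
      " residue(s)\n", sep = "")
  invisible(x)
}

#' Residue keys of a full LIP (mLIP plus cLIP, each residue once)
#' @param lip a `lip` object.
#' @return character vector of residue keys.
#' @export
lip_residues <- function(lip) {
  union(lip$mlip$span, lip$clip$members$key)
}

#' Find all LIPs of a structure
#'
#' Orchestrates the full method.  For each selected chain an intra-chain
#' profile is scanned; with two chains and `mode` `"inter"` or `"both"`,
#' both ordered chain pairs are scanned (the probe slides along the first
#' chain against the entirety of the second).  For oligomers with more than
#' two chains the pair to analyse must be named via `chains`.  Every
#' detected mLIP is paired with its cLIP.
#'
#' @param structure a `lip_structure`.
#' @param mode `"both"`, `"intra"` or `"inter"`.
#' @param chains chain ids to analyse (default: all, at most two for inter).
#' @param params a [lip_params()] object.
#' @return an object of class `lip_result`: list with `profiles` (named
#'   list of `lip_profile`), `lips` (list of `lip` objects, each mLIP +
#'   cLIP), `structure`, `params`.
#' @export
find_lips <- function(structure, mode = c("both", "intra", "inter"),
                      chains = NULL, params = lip_params()) {
  mode <- match.arg(mode)
  all_chains <- structure_chains(structure)
  if (is.null(chains)) chains <- all_chains
  if (!all(chains %in% all_chains)) {
    stop("chain(s) not in structure: ",
         paste(setdiff(chains, all_chains), collapse = ", "))
  }
  want_inter <- mode %in% c("both", "inter")
  if (want_inter && length(chains) < 2) {
    if (mode == "inter") stop("inter mode requires at least two chains")
    want_inter <- FALSE
  }
  if (want_inter && length(chains) > 2) {
    stop("more than two chains: specify the chain pair to analyse ",
         "via `chains`")
  }
  profiles <- list()
  if (mode %in% c("both", "intra")) {
    for (ch in chains) {
      profiles[[paste0("intra-", ch)]] <-
        scan_profile(structure, ch, "intra", params = params)
    }
  }
  if (want_inter) {
    prs <- list(chains, rev(chains))
    for (pair in prs) {
      profiles[[paste0("inter-", pair[1], ":", pair[2])]] <-
        scan_profile(structure, pair[1], "inter", partner = pair[2],
                     params = params)
    }
  }
  lips <- list()
  for (prof in profiles) {
    for (ml in detect_mlips(prof, params)) {
      cl <- compute_clip(structure, ml, params)
      lip <- list(mlip = ml, clip = cl)
      class(lip) <- "lip"
      lips[[length(lips) + 1]] <- lip
    }
  }
  out <- list(profiles = profiles, lips = lips, structure = structure,
              params = params)
  class(out) <- "lip_result"
  out
}

#' @export
print.lip_result <- function(x, ...) {
  cat("lip_result:", length(x$profiles), "profile(s),", length(x$lips),
      "LIP(s)\n")
  for (lip in x$lips) {
    print(lip$mlip)
    print(lip$clip)
  }
  invisible(x)
}
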