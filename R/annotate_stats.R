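#' Amino-acid polarity groups
#'
#' The four groups partition the 20 proteinogenic amino acids: non-polar
#' (A, G, V, L, I, P, M, C, F, W), polar uncharged (Y, S, T, N, Q),
#' negatively charged (D, E) and positively charged (K, R, H).
#'
#' @return named list of character vectors of one-letter codes.
#' @export
aa_groups <- function() {
  list(`non-polar` = c("A", "G", "V", "L", "I", "P", "M", "C", "F", "W"),
       `polar-uncharged` = c("Y", "S", "T", "N", "Q"),
       negative = c("D", "E"),
       positive = c("K", "R", "H"))
}

AA_ALPHABET <- sort(unname(unlist(aa_groups())))

#' Amino-acid enrichment factors
#'
#' For each amino acid (and each polarity group) computes the relative
#' frequency inside a region of interest and outside it, and their ratio,
#' the enrichment factor EF.  Standard errors follow binomial propagation
#' of the two frequencies.  An amino acid absent outside the region has an
#' undefined EF (`NA`), not an infinite one.
#'
#' @param in_counts,out_counts named integer vectors (one-letter codes) of
#'   residue counts inside and outside the region; missing letters count 0.
#' @return data frame of class `enrichment_table` with one row per amino
#'   acid and per group: name, level (`"aa"`/`"group"`), count_in,
#'   count_out, nu_in, nu_out, ef, se.
#' @export
enrichment_factor <- function(in_counts, out_counts) {
  fill <- function(x) {
    v <- setNames(rep(0, length(AA_ALPHABET)), AA_ALPHABET)
    x <- x[names(x) %in% AA_ALPHABET]
    v[names(x)] <- x
    v
  }
  ci <- fill(in_counts); co <- fill(out_counts)
  ni <- sum(ci); no <- sum(co)
  if (ni == 0 || no == 0) stop("zero total count in a region")
  nu_i <- ci / ni; nu_o <- co / no
  se_nu <- function(nu, n) sqrt(nu * (1 - nu) / n)
  ef_row <- function(name, level, k_in, k_out) {
    vi <- k_in / ni; vo <- k_out / no
    ef <- if (vo > 0) vi / vo else NA_real_
    se <- if (vo > 0 && vi > 0) {
      ef * sqrt((se_nu(vi, ni) / vi)^2 + (se_nu(vo, no) / vo)^2)
    } else NA_real_
    data.frame(name = name, level = level, count_in = k_in,
               count_out = k_out, nu_in = vi, nu_out = vo, ef = ef,
               se = se, stringsAsFactors = FALSE)
  }
  rows <- lapply(AA_ALPHABET, function(a) ef_row(a, "aa", ci[[a]], co[[a]]))
  grp <- aa_groups()
  rows <- c(rows, lapply(names(grp), function(g) {
    ef_row(g, "group", sum(ci[grp[[g]]]), sum(co[grp[[g]]]))
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Two-proportion Z-test
#'
#' Pooled two-sample test for a difference of proportions with a two-tailed
#' normal p-value.
#'
#' @param k1,n1 successes and trials in the first sample.
#' @param k2,n2 successes and trials in the second sample.
#' @return list with `z` and `p`.
#' @export
proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must satisfy 0 <= k <= n")
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Read a per-residue score table
#'
#' Plain TSV with header columns `chain`, `resno`, `icode`, `score`
#' (conservation, stability or any other per-residue metric).
#'
#' @param path file path.
#' @return data frame with those columns plus `key`.
#' @export
read_score_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(chain = "character", icode = "character"))
  df$icode[is.na(df$icode)] <- ""
  df$key <- res_key(df$chain, df$resno, df$icode)
  if (anyDuplicated(df$key)) stop("duplicate residues in score table")
  df
}

#' Inside/outside mean-difference analysis
#'
#' Compares the mean score of residues inside a structure element to the
#' mean of all scored residues outside it: reports the mean difference
#' (inside minus outside), a two-tailed two-sample t-test (pooled-variance
#' Student by default), the point-biserial correlation (algebraically tied
#' to t) and Cohen's d on the pooled standard deviation.
#'
#' @param scores a score table (see [read_score_table()], or any data frame
#'   with `key` and `score`).
#' @param element_mask residue keys of the structure element.
#' @param element name for the report.
#' @param flavor `"student"` (pooled variance) or `"welch"`.
#' @return one-row data frame of class `mean_difference_report`: element,
#'   n_in, n_out, mean_in, mean_out, difference, t, df, p, r, d.
#' @export
mean_difference <- function(scores, element_mask, element = "element",
                            flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  inside <- scores$score[scores$key %in% element_mask]
  outside <- scores$score[!(scores$key %in% element_mask)]
  if (!length(inside) || !length(outside)) {
    stop("both sides of the comparison must be non-empty")
  }
  n1 <- length(inside); n2 <- length(outside)
  v1 <- if (n1 > 1) stats::var(inside) else 0
  v2 <- if (n2 > 1) stats::var(outside) else 0
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  if (sp > 0) {
    tt <- stats::t.test(inside, outside, var.equal = (flavor == "student"))
    t <- unname(tt$statistic); dfree <- unname(tt$parameter)
    pval <- tt$p.value
  } else {
    # degenerate: no variance anywhere, so no evidence of a difference
    t <- 0; dfree <- n1 + n2 - 2; pval <- 1
  }
  out <- data.frame(element = element, n_in = n1, n_out = n2,
                    mean_in = mean(inside), mean_out = mean(outside),
                    difference = mean(inside) - mean(outside),
                    t = t, df = dfree, p = pval,
                    r = t / sqrt(t^2 + dfree),
                    d = if (sp > 0) (mean(inside) - mean(outside)) / sp
                        else 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("mean_difference_report", class(out))
  out
}

#' Parse secondary structure from a DSSP output file
#'
#' Reads the per-residue block of a standard DSSP file and maps the
#' summary letter to coarse classes: alpha is `H` only; beta is `B` or `E`;
#' coil is a blank summary; 3-10/pi helices, turns and bends are kept as
#' `other` and excluded from the three classes.
#'
#' @param path DSSP file path.
#' @return data frame: chain, resno, icode, aa, ss, class, key.
#' @export
parse_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP file: per-residue header not found")
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  body <- body[substr(body, 14, 14) != "!"]
  resno <- as.integer(trimws(substr(body, 6, 10)))
  icode <- trimws(substr(body, 11, 11))
  chain <- substr(body, 12, 12)
  ss <- substr(body, 17, 17)
  cls <- rep("other", length(ss))
  cls[ss == "H"] <- "alpha"
  cls[ss %in% c("B", "E")] <- "beta"
  cls[ss == " "] <- "coil"
  out <- data.frame(chain = chain, resno = resno, icode = icode,
                    aa = substr(body, 14, 14), ss = ss, class = cls,
                    stringsAsFactors = FALSE)
  out$key <- res_key(out$chain, out$resno, out$icode)
  out
}

lip_component_sets <- function(lips) {
  mset <- unique(unlist(lapply(lips, function(l) l$mlip$span)))
  cset <- unique(unlist(lapply(lips, function(l) l$clip$members$key)))
  list(mlip = mset %||% character(0), clip = cset %||% character(0),
       full = union(mset %||% character(0), cset %||% character(0)))
}

#' SITE-versus-domain LIP occupancy report
#'
#' Counts residues falling in mLIPs, cLIPs, full LIPs (each residue counted
#' once even when in both components) and outside LIPs, separately for
#' SITE-annotated residues and for all residues of the structure, and
#' attaches a two-proportion Z-test per row.
#'
#' @param lips list of `lip` objects (or a `lip_result`).
#' @param sites list of site annotations (see [parse_site_records()]).
#' @param structure the `lip_structure` the LIPs were computed on.
#' @return data frame of class `site_lip_report`: element, n_site,
#'   pct_site, n_domain, pct_domain, z, p.  SITE columns are `NA` when no
#'   resolvable SITE residues exist.
#' @export
site_lip_report <- function(lips, sites, structure) {
  if (inherits(lips, "lip_result")) lips <- lips$lips
  all_keys <- unique(structure$atoms$key)
  site_keys <- character(0)
  for (s in sites) {
    m <- s$members
    ok <- m$key %in% all_keys
    if (any(!ok & isTRUE(any(m$is_protein)))) {
      warning("SITE ", s$site_id, " references residues absent from the ",
              "structure; skipped")
    }
    site_keys <- union(site_keys, m$key[ok])
  }
  sets <- lip_component_sets(lips)
  comp <- list(mLIPs = sets$mlip, cLIPs = sets$clip,
               `Full LIPs` = sets$full,
               `NO LIPs` = setdiff(all_keys, sets$full))
  n_all <- length(all_keys); n_site <- length(site_keys)
  rows <- lapply(names(comp), function(nm) {
    kd <- sum(all_keys %in% comp[[nm]])
    ks <- sum(site_keys %in% comp[[nm]])
    zt <- if (n_site > 0) proportion_ztest(ks, n_site, kd, n_all)
          else list(z = NA_real_, p = NA_real_)
    data.frame(element = nm,
               n_site = if (n_site > 0) ks else NA_integer_,
               pct_site = if (n_site > 0) 100 * ks / n_site else NA_real_,
               n_domain = kd, pct_domain = 100 * kd / n_all,
               z = zt$z, p = zt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("site_lip_report", class(out))
  out
}

#' Exposure profile of residue sets
#'
#' Cross-tabulates named residue masks against exposure classes.
#' Percentages are taken over the full mask size, so residues with
#' undefined exposure (non-canonical) make the three classes sum to less
#' than 100%; their count is reported separately.
#'
#' @param masks named list of residue-key vectors.
#' @param exposures data frame with columns `key` and `class`
#'   (`"buried"`/`"intermediate"`/`"exposed"`, `NA` undefined), e.g. from
#'   [residue_sasa_table()].
#' @return data frame of class `exposure_profile`: element, n_buried,
#'   pct_buried, n_intermediate, pct_intermediate, n_exposed, pct_exposed,
#'   n_undefined, total.
#' @export
exposure_profile <- function(masks, exposures) {
  cls <- setNames(exposures$class, exposures$key)
  rows <- lapply(names(masks), function(nm) {
    keys <- masks[[nm]]
    k <- cls[keys]
    tot <- length(keys)
    cnt <- function(what) sum(!is.na(k) & k == what)
    data.frame(element = nm,
               n_buried = cnt("buried"),
               pct_buried = 100 * cnt("buried") / tot,
               n_intermediate = cnt("intermediate"),
               pct_intermediate = 100 * cnt("intermediate") / tot,
               n_exposed = cnt("exposed"),
               pct_exposed = 100 * cnt("exposed") / tot,
               n_undefined = sum(is.na(k)),
               total = tot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exposure_profile", class(out))
  out
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Amino-acid enrichment of LIP components
#'
#' Builds the enrichment table for the residues of a LIP component versus
#' the NO-LIP region (residues in no mLIP and no cLIP) of the same
#' structure(s).
#'
#' @param result a `lip_result`, or a list of them (multi-structure
#'   analyses pool counts across structures).
#' @param component `"full"`, `"mlip"` or `"clip"`.
#' @return an `enrichment_table` (see [enrichment_factor()]).
#' @export
lip_enrichment <- function(result, component = c("full", "mlip", "clip")) {
  component <- match.arg(component)
  results <- if (inherits(result, "lip_result")) list(result) else result
  count <- function(keys, structure) {
    rt <- residue_table(structure)
    aa <- AA3TO1[rt$resname[rt$key %in% keys]]
    table(factor(aa[!is.na(aa)], levels = AA_ALPHABET))
  }
  ci <- co <- setNames(rep(0, length(AA_ALPHABET)), AA_ALPHABET)
  for (res in results) {
    sets <- lip_component_sets(res$lips)
    inside <- switch(component, full = sets$full, mlip = sets$mlip,
                     clip = sets$clip)
    outside <- setdiff(unique(res$structure$atoms$key), sets$full)
    ci <- ci + count(inside, res$structure)
    co <- co + count(outside, res$structure)
  }
  enrichment_factor(ci, co)
}

#' Residue-type composition of a residue set
#'
#' Percentage of residues per polarity group (non-polar, polar uncharged,
#' negatively charged, positively charged).
#'
#' @param keys residue keys.
#' @param structure the `lip_structure` they belong to.
#' @return named numeric vector of percentages over the four groups.
#' @export
group_composition <- function(keys, structure) {
  rt <- residue_table(structure)
  aa <- AA3TO1[rt$resname[rt$key %in% keys]]
  aa <- aa[!is.na(aa)]
  grp <- aa_groups()
  v <- vapply(grp, function(g) sum(aa %in% g), 0)
  100 * v / max(length(aa), 1)
}
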