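#' Profile table in TSV-ready form
#'
#' @param result a `lip_result`.
#' @return data frame with columns chain, mode, partner, resnum, icode,
#'   resname, PR, rho, in_mlip across all profiles of the run.
#' @export
profile_table <- function(result) {
  sets <- lapply(result$lips, function(l) l$mlip)
  rows <- lapply(result$profiles, function(prof) {
    p <- prof$points
    in_ml <- rep(0L, nrow(p))
    for (ml in sets) {
      if (ml$chain == prof$chain && ml$mode == prof$mode &&
          identical(ml$partner, prof$partner)) {
        in_ml[p$key %in% ml$span] <- 1L
      }
    }
    data.frame(chain = p$chain, mode = p$mode, partner = p$partner,
               resnum = p$resno, icode = p$icode, resname = p$resname,
               PR = p$pr, rho = p$rho, in_mlip = in_ml,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structured LIP report
#'
#' @param result a `lip_result`.
#' @return a list (JSON-serializable) describing each LIP: mode, chain,
#'   partner, mLIP span and peak PR, and cLIP members with their
#'   delta-SASA values.
#' @export
lip_report <- function(result) {
  lapply(result$lips, function(l) {
    list(mode = l$mlip$mode,
         chain = l$mlip$chain,
         partner = if (l$mlip$mode == "inter") l$mlip$partner else NULL,
         mlip = list(from = l$mlip$resno_from, to = l$mlip$resno_to,
                     residues = l$mlip$span,
                     peak_pr = l$mlip$peak_pr),
         clip = list(n = nrow(l$clip$members),
                     members = l$clip$members[, c("key", "resname",
                                                  "delta")]),
         full_lip_n = length(lip_residues(l)))
  })
}

#' Plain-text run summary
#'
#' Mirrors a downloadable analysis report: detected mLIP spans per mode,
#' cLIP members, numbering and structural gaps, SITE annotations, and the
#' effective parameter set.
#'
#' @param result a `lip_result`.
#' @return character vector of lines.
#' @export
summary_text <- function(result) {
  s <- result$structure
  out <- c("LIP analysis summary",
           paste0("input: ", s$provenance),
           paste0("chains: ", paste(structure_chains(s), collapse = ", ")),
           "")
  pm <- result$params
  out <- c(out, "parameters:",
           sprintf("  window=%d pr_peak=%g pr_base=%g rho_rule=mean-%g*sd",
                   pm$window, pm$pr_peak, pm$pr_base, pm$rho_k),
           sprintf("  dsasa=%g probe=%g n_points=%d interface_cutoff=%g",
                   pm$dsasa, pm$probe, pm$n_points, pm$interface_cutoff),
           "")
  if (!length(result$lips)) {
    out <- c(out, "no LIPs detected", "")
  } else {
    for (i in seq_along(result$lips)) {
      l <- result$lips[[i]]
      hdr <- sprintf("LIP %d [%s] chain %s%s: mLIP %d-%d (%d aa, peak PR %.3g)",
                     i, l$mlip$mode, l$mlip$chain,
                     if (l$mlip$mode == "inter")
                       paste0(" vs ", l$mlip$partner) else "",
                     l$mlip$resno_from, l$mlip$resno_to,
                     length(l$mlip$span), l$mlip$peak_pr)
      mem <- if (nrow(l$clip$members)) {
        paste(sprintf("%s(%0.1f)", l$clip$members$key,
                      l$clip$members$delta), collapse = " ")
      } else "none"
      out <- c(out, hdr, paste0("  cLIP: ", mem))
    }
    out <- c(out, "")
  }
  gaps <- sequence_gaps(s)
  out <- c(out, if (nrow(gaps)) {
    c("numbering gaps:",
      sprintf("  chain %s: %s -> %s (%d positions)", gaps$chain,
              gaps$before, gaps$after, gaps$missing))
  } else "numbering gaps: none")
  segs <- unlist(lapply(structure_chains(s), function(ch) {
    length(chain_segments(s, ch))
  }))
  out <- c(out, paste0("structural segments per chain: ",
                       paste(segs, collapse = ", ")))
  if (length(s$sites)) {
    out <- c(out, "SITE annotations:")
    for (st in s$sites) {
      out <- c(out, sprintf("  %s: %s", st$site_id,
                            paste(st$members$key, collapse = " ")))
    }
  } else {
    out <- c(out, "SITE annotations: none")
  }
  out
}

#' Dual PR/rho profile plot
#'
#' PR on top with the peak and baseline thresholds dashed, rho at the
#' bottom with the mean minus one standard deviation dashed; mLIP spans
#' shaded.  Undefined points (segment edges, structural gaps) break the
#' lines.
#'
#' @param profile a `lip_profile`.
#' @param mlips optional list of `mlip` objects detected on this profile.
#' @param params a [lip_params()] object for the threshold lines.
#' @return a ggplot object.
#' @export
plot_profile <- function(profile, mlips = NULL,
                         params = profile$params %||% lip_params()) {
  p <- profile$points
  idx <- seq_len(nrow(p))
  long <- rbind(
    data.frame(i = idx, resno = p$resno, value = pmin(p$pr, 5),
               panel = "PR", stringsAsFactors = FALSE),
    data.frame(i = idx, resno = p$resno, value = p$rho, panel = "rho",
               stringsAsFactors = FALSE))
  thr <- rbind(
    data.frame(panel = "PR", y = c(params$pr_peak, params$pr_base)),
    data.frame(panel = "rho",
               y = profile$rho_mean - params$rho_k * profile$rho_sd))
  g <- ggplot2::ggplot(long, ggplot2::aes(x = i, y = value)) +
    ggplot2::geom_line(na.rm = TRUE, linewidth = 0.7,
                       colour = "firebrick") +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = y),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "residue position",
                  y = NULL,
                  title = sprintf("chain %s, %s%s", profile$chain,
                                  profile$mode,
                                  if (profile$mode == "inter")
                                    paste0(" vs ", profile$partner) else ""))
  if (!is.null(mlips) && length(mlips)) {
    shade <- do.call(rbind, lapply(mlips, function(ml) {
      r <- range(match(ml$span, p$key))
      data.frame(xmin = r[1] - 0.5, xmax = r[2] + 0.5)
    }))
    g <- g + ggplot2::geom_rect(data = shade, inherit.aes = FALSE,
                                ggplot2::aes(xmin = xmin, xmax = xmax, ymin = -Inf, ymax = Inf),
                                alpha = 0.2, fill = "grey40")
  }
  g
}

#' Read a key=value configuration file
#'
#' Lines of the form `name=value`; `#` starts a comment.  Values are
#' converted to numeric where possible.  Returned entries can be passed to
#' [lip_params()].
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full analysis pipeline
#'
#' Reads a PDB file, finds LIPs, and writes the artifact bundle: the
#' per-chain profile TSV, a JSON LIP report, a plain-text summary, the
#' per-residue SASA/exposure TSV, and (optionally) the dual-profile plots
#' as PNG.
#'
#' @param pdb path to a PDB file.
#' @param out_dir output directory (created if missing).
#' @param mode `"both"`, `"intra"` or `"inter"`.
#' @param chains optional chain selection.
#' @param params a [lip_params()] object.
#' @param plots write PNG profile plots.
#' @return the `lip_result`, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(pdb, out_dir, mode = "both", chains = NULL,
                         params = lip_params(), plots = TRUE) {
  structure <- read_pdb(pdb)
  if (mode %in% c("both", "inter") &&
      length(structure_chains(structure)) < 2) {
    if (mode == "inter") stop("inter mode requires an oligomer")
    mode <- "intra"
  }
  result <- find_lips(structure, mode = mode, chains = chains,
                      params = params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) format(x, digits = 10, trim = TRUE)
  pt <- profile_table(result)
  pt$PR <- num(pt$PR); pt$rho <- num(pt$rho)
  write.table(pt, file.path(out_dir, "profiles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lip_report(result),
                       file.path(out_dir, "lips.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(summary_text(result), file.path(out_dir, "summary.txt"))
  rs <- residue_sasa_table(structure, probe = params$probe,
                           n_points = params$n_points)
  rs$sasa_total <- num(rs$sasa_total)
  rs$sasa_polar <- num(rs$sasa_polar)
  rs$sasa_apolar <- num(rs$sasa_apolar)
  rs$rel_exposure <- num(rs$rel_exposure)
  write.table(rs, file.path(out_dir, "sasa.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (plots) {
    for (nm in names(result$profiles)) {
      prof <- result$profiles[[nm]]
      mls <- Filter(function(ml) {
        ml$chain == prof$chain && ml$mode == prof$mode &&
          identical(ml$partner, prof$partner)
      }, lapply(result$lips, function(l) l$mlip))
      fn <- file.path(out_dir, paste0("profile-", gsub(":", "_", nm),
                                      ".png"))
      grDevices::png(fn, width = 900, height = 600)
      print(plot_profile(prof, mls, params))
      grDevices::dev.off()
    }
  }
  invisible(result)
}

utils::globalVariables(c("i", "value", "y", "xmin", "xmax"))
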