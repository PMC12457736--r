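# Detector oracles: definition-level PR recomputation, rule-level mLIP
# walk-throughs on synthetic profiles, and symmetry/monotonicity properties.

test_that("parameter object validates names and applies overrides", {
  p <- lip_params()
  expect_equal(p$window, 8L)
  expect_equal(p$pr_peak, 0.8)
  expect_equal(p$pr_base, 0.5)
  expect_equal(p$dsasa, 1.0)
  p2 <- lip_params(pr_peak = 1.2)
  expect_equal(p2$pr_peak, 1.2)
  expect_error(lip_params(bogus = 1), "unknown parameter")
})

test_that("interface buried areas follow the SASA definition exactly", {
  st <- fx_bundle()$structure
  rt <- residue_table(st)
  probe_keys <- rt$key[4:11]
  env_keys <- setdiff(rt$key, probe_keys)
  patch <- interface_patch(st, probe_keys, env_keys)
  # recompute b = SASA(component isolated) - SASA(complex) from scratch
  a <- st$atoms
  sp <- atom_sasa(a[a$key %in% probe_keys, ])
  se <- atom_sasa(a[a$key %in% env_keys, ])
  sc <- atom_sasa(a)
  iso <- setNames(c(sp$per_atom, se$per_atom),
                  c(a$serial[a$key %in% probe_keys],
                    a$serial[a$key %in% env_keys]))
  cx <- setNames(sc$per_atom, a$serial)
  for (j in seq_len(nrow(patch$interface))) {
    s <- as.character(patch$interface$serial[j])
    expect_equal(patch$interface$b[j], unname(iso[s] - cx[s]),
                 tolerance = 1e-9)
  }
  expect_true(all(patch$interface$b > lip_params()$interface_cutoff))
  expect_equal(patch$buried_polar,
               sum(patch$interface$b[patch$interface$polarity == "polar"]))
  expect_equal(patch$buried_apolar,
               sum(patch$interface$b[patch$interface$polarity == "apolar"]))
})

test_that("interface is empty when the components cannot touch", {
  s <- paste(rep("L", 14), collapse = "")
  far <- make_structure(fixture_spec(c(s, s), geometry = "two-helix-bundle",
                                     contact_distance = 40))$structure
  rt <- residue_table(far)
  patch <- interface_patch(far, rt$key[1:14], rt$key[15:28])
  expect_equal(nrow(patch$interface), 0)
  expect_true(is.na(polarity_ratio(patch)))
})

test_that("probe/environment preconditions are enforced", {
  st <- fx_bundle()$structure
  rt <- residue_table(st)
  expect_error(interface_patch(st, rt$key[1:5], rt$key[15:28]),
               "fewer than")
  expect_error(interface_patch(st, rt$key[1:8], rt$key[8:20]),
               "overlap")
})

test_that("polarity ratio handles the degenerate interfaces", {
  mk <- function(pol, b) {
    patch <- list(interface = data.frame(polarity = pol, b = b),
                  buried_polar = sum(b[pol == "polar"]),
                  buried_apolar = sum(b[pol == "apolar"]))
    class(patch) <- "interface_patch"
    patch
  }
  expect_equal(polarity_ratio(mk(c("apolar", "apolar"), c(2, 3))), 0)
  expect_equal(polarity_ratio(mk(c("polar", "polar"), c(2, 3))), Inf)
  expect_equal(polarity_ratio(mk(c("polar", "apolar"), c(4, 5))), 0.8)
  expect_true(is.na(polarity_ratio(mk(character(0), numeric(0)))))
})

test_that("profile window arithmetic: values sit on the 4th residue", {
  st <- make_structure(fixture_spec(polar_face_sequence(30),
                                    geometry = "ideal-helix"))$structure
  prof <- scan_profile(st, "A", "intra")
  def <- which(!is.na(prof$points$pr))
  # 30 - 8 + 1 = 23 windows; first window centres on residue 4,
  # last on residue 26
  expect_equal(def, 4:26)
  expect_equal(nrow(prof$points), 30)
})

test_that("windows never span structural gaps", {
  st <- fx_bundle()$structure       # two 14-residue segments in one chain
  prof <- suppressWarnings(scan_profile(st, "A", "intra"))
  def <- which(!is.na(prof$points$pr))
  # each segment contributes positions 4..(14-4): 7 windows each
  expect_equal(def, c(4:10, 14 + (4:10)))
})

test_that("a chain with no segment of window length warns and is empty", {
  st <- read_pdb(ala_gly_pdb())
  expect_warning(prof <- scan_profile(st, "A", "intra"), "no contiguous")
  expect_true(all(is.na(prof$points$pr)))
  expect_equal(detect_mlips(prof), list())
})

test_that("profile rho statistics are computed over defined points only", {
  prof <- suppressWarnings(scan_profile(fx_bundle()$structure, "A", "intra"))
  rho <- prof$points$rho[!is.na(prof$points$rho)]
  expect_equal(prof$rho_mean, mean(rho))
  expect_equal(prof$rho_sd, sd(rho))
})

test_that("mLIP rule: flat sub-threshold profile yields nothing", {
  prof <- synthetic_profile(pr = rep(0.6, 20), rho = rep(0.8, 20))
  expect_equal(detect_mlips(prof), list())
})

test_that("mLIP rule: peak is extended to the baseline and rho-gated", {
  pr <- c(0.2, 0.3, 0.55, 0.7, 0.95, 0.7, 0.55, 0.3, 0.2, 0.2)
  rho_lo <- c(rep(0.80, 4), 0.60, rep(0.80, 5))     # dip under mean - sd
  prof <- synthetic_profile(pr, rho_lo, rho_mean = 0.78, rho_sd = 0.06)
  mls <- detect_mlips(prof)
  expect_length(mls, 1)
  # extension: indices 3..7 all have PR > 0.5; 2 and 8 do not
  expect_equal(mls[[1]]$span, paste0("A:", 3:7, ":"))
  expect_equal(mls[[1]]$peak_pr, 0.95)
  # same shape but well-packed everywhere -> rejected by the rho test
  prof2 <- synthetic_profile(pr, rep(0.80, 10), rho_mean = 0.78,
                             rho_sd = 0.06)
  expect_equal(detect_mlips(prof2), list())
})

test_that("mLIP rule: overlapping candidate regions merge", {
  pr <- c(0.2, 0.9, 0.6, 0.85, 0.2, 0.2)
  rho <- c(0.9, 0.5, 0.9, 0.5, 0.9, 0.9)
  prof <- synthetic_profile(pr, rho, rho_mean = 0.8, rho_sd = 0.1)
  mls <- detect_mlips(prof)
  expect_length(mls, 1)
  expect_equal(mls[[1]]$span, paste0("A:", 2:4, ":"))
})

test_that("mLIP rule: undefined points split runs and block extension", {
  pr <- c(0.7, 0.9, 0.7, NA, 0.9, 0.7, 0.2, 0.2)
  rho <- c(0.5, 0.5, 0.5, NA, 0.5, 0.5, 0.9, 0.9)
  prof <- synthetic_profile(pr, rho, rho_mean = 0.8, rho_sd = 0.1)
  mls <- detect_mlips(prof)
  expect_length(mls, 2)
  expect_equal(mls[[1]]$span, paste0("A:", 1:3, ":"))
  expect_equal(mls[[2]]$span, paste0("A:", 5:6, ":"))
})

test_that("mLIP rule: a plateau at the peak counts as one maximum", {
  pr <- c(0.2, 0.9, 0.9, 0.9, 0.2)
  rho <- c(0.9, 0.5, 0.5, 0.5, 0.9)
  prof <- synthetic_profile(pr, rho, rho_mean = 0.8, rho_sd = 0.1)
  mls <- detect_mlips(prof)
  expect_length(mls, 1)
  expect_equal(mls[[1]]$span, paste0("A:", 2:4, ":"))
})

test_that("rho gate is strict and undefined-cutoff profiles detect nothing", {
  pr <- c(0.2, 0.95, 0.2)
  # rho exactly at the cut-off (mean - sd = 0.75 - 0.25 = 0.5, all values
  # exactly representable): not below it -> rejected
  prof <- synthetic_profile(pr, c(0.9, 0.5, 0.9), rho_mean = 0.75,
                            rho_sd = 0.25)
  expect_equal(detect_mlips(prof), list())
  # single defined point -> sd undefined -> no detection
  prof2 <- synthetic_profile(c(NA, 0.95, NA), c(NA, 0.5, NA))
  expect_equal(detect_mlips(prof2), list())
})

test_that("designed smoke pair: polar-faced bundle detects, control does not", {
  pos <- res_bundle()
  neg <- res_control()
  expect_gt(length(pos$lips), 0)
  expect_equal(length(neg$lips), 0)
  # the detected mLIP overlaps the designed polar interface region
  spans <- unlist(lapply(pos$lips, function(l) l$mlip$span))
  expect_gt(length(intersect(spans,
                             residue_table(pos$structure)$key)), 0)
})

test_that("cLIP members are the strict-threshold contact residues", {
  res <- res_bundle()
  expect_gt(length(res$lips), 0)
  for (l in res$lips) {
    ml <- l$mlip
    # recompute from scratch: crop the span, all-atom SASA both ways
    analysis <- select_chains(res$structure, ml$chain)
    full <- atom_sasa(analysis)
    cropped <- atom_sasa(crop(analysis, ml$span)$retained)
    ds <- delta_sasa(full, cropped)
    want <- ds$key[ds$delta > lip_params()$dsasa]
    expect_setequal(l$clip$members$key, want)
    # membership is strict: every member is strictly above the threshold
    expect_true(all(l$clip$members$delta > lip_params()$dsasa))
    # the mLIP span itself is excluded by construction
    expect_length(intersect(l$clip$members$key, ml$span), 0)
  }
})

test_that("full LIP is the union of mLIP and cLIP without duplicates", {
  res <- res_bundle()
  for (l in res$lips) {
    keys <- lip_residues(l)
    expect_setequal(keys, union(l$mlip$span, l$clip$members$key))
    expect_false(any(duplicated(keys)))
  }
})

test_that("find_lips produces the four calculations for a dimer", {
  res <- res_dimer()
  expect_named(res$profiles,
               c("intra-A", "intra-B", "inter-A:B", "inter-B:A"))
  expect_equal(res$profiles[["inter-A:B"]]$chain, "A")
  expect_equal(res$profiles[["inter-A:B"]]$partner, "B")
  expect_equal(res$profiles[["inter-B:A"]]$chain, "B")
})

test_that("an exact C2 homodimer gives near-identical chain profiles", {
  # The dimer is an exact two-fold symmetry copy; profiles agree up to
  # quadrature orientation dependence of the fixed sphere lattice.
  res <- res_dimer()
  pa <- res$profiles[["intra-A"]]$points
  pb <- res$profiles[["intra-B"]]$points
  expect_equal(which(!is.na(pa$pr)), which(!is.na(pb$pr)))
  expect_equal(pa$pr, pb$pr, tolerance = 0.05)
  ia <- res$profiles[["inter-A:B"]]$points
  ib <- res$profiles[["inter-B:A"]]$points
  expect_equal(ia$pr, ib$pr, tolerance = 0.05)
  expect_equal(ia$rho, ib$rho, tolerance = 0.05)
  # detected spans map onto each other under the chain swap
  spans_a <- lapply(Filter(function(l) l$mlip$chain == "A", res$lips),
                    function(l) sub("^A", "B", l$mlip$span))
  spans_b <- lapply(Filter(function(l) l$mlip$chain == "B", res$lips),
                    function(l) l$mlip$span)
  expect_setequal(vapply(spans_a, paste, "", collapse = ","),
                  vapply(spans_b, paste, "", collapse = ","))
})

test_that("mode and chain validation in find_lips", {
  mono <- fx_helix20()$structure
  expect_error(find_lips(mono, mode = "inter"), "two chains")
  # mode 'both' degrades to intra-only on a monomer
  res <- find_lips(mono, mode = "both")
  expect_named(res$profiles, "intra-A")
  expect_error(find_lips(mono, chains = "Z"), "not in structure")
  tri <- fx_dimer()$structure
  a3 <- tri$atoms[tri$atoms$chain == "A", ]
  a3$chain <- "C"
  a3$x <- a3$x + 60
  a3$serial <- a3$serial + 1000L
  a3$key <- res_key(a3$chain, a3$resno, a3$icode)
  tri3 <- merge_structures(tri, new_lip_structure(a3))
  expect_error(find_lips(tri3, mode = "inter"), "chain pair")
  res3 <- find_lips(tri3, mode = "inter", chains = c("A", "B"))
  expect_named(res3$profiles, c("inter-A:B", "inter-B:A"))
})

test_that("detection responds monotonically to its thresholds", {
  st <- fx_bundle()$structure
  base <- res_bundle()
  # an unattainable peak threshold removes every detection
  hi <- suppressWarnings(find_lips(st, params = lip_params(pr_peak = 1e5,
                                                           pr_cap = 1e4)))
  expect_equal(length(hi$lips), 0)
  # a permissive delta-SASA threshold can only grow each cLIP
  lo <- suppressWarnings(find_lips(st, params = lip_params(dsasa = 0.2)))
  expect_gte(length(lo$lips), length(base$lips))
  key0 <- unlist(lapply(base$lips, function(l) l$clip$members$key))
  key1 <- unlist(lapply(lo$lips, function(l) l$clip$members$key))
  expect_true(all(key0 %in% key1))
})

test_that("the whole detection pass is deterministic", {
  r1 <- suppressWarnings(find_lips(fx_bundle()$structure))
  r2 <- res_bundle()
  expect_identical(profile_table(r1), profile_table(r2))
})
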