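# Statistics oracles: arithmetic identities, literature reference values
# for the two-proportion test, and a planted-effect simulation.

test_that("polarity groups partition the twenty amino acids", {
  g <- aa_groups()
  all20 <- sort(unname(unlist(g)))
  expect_equal(all20, sort(unique(all20)))
  expect_length(all20, 20)
  expect_setequal(all20, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_setequal(g$negative, c("D", "E"))
  expect_setequal(g$positive, c("K", "R", "H"))
})

test_that("identical compositions have unit enrichment everywhere", {
  counts <- setNames(rep(3L, 20), sort(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                "")[[1]]))
  et <- enrichment_factor(counts, counts * 5L)
  expect_equal(et$ef, rep(1, nrow(et)))
})

test_that("enrichment follows the frequency-ratio definition", {
  ci <- c(A = 6L, L = 2L, S = 2L)   # 10 inside
  co <- c(A = 10L, L = 20L, S = 10L, D = 10L)  # 50 outside
  et <- enrichment_factor(ci, co)
  row <- function(n) et[et$name == n & et$level == "aa", ]
  expect_equal(row("A")$ef, (6 / 10) / (10 / 50))     # 3.0
  expect_equal(row("L")$ef, (2 / 10) / (20 / 50))     # 0.5
  # absent outside -> undefined, not infinite
  ci2 <- c(A = 5L, W = 5L); co2 <- c(A = 10L)
  et2 <- enrichment_factor(ci2, co2)
  expect_true(is.na(row2 <- et2[et2$name == "W" & et2$level == "aa", ]$ef))
  # group rows aggregate their member counts
  grp <- et[et$name == "non-polar" & et$level == "group", ]
  expect_equal(grp$count_in, 8)  # A + L
  expect_equal(grp$ef, (8 / 10) / (30 / 50))
  # empty regions are rejected
  expect_error(enrichment_factor(c(A = 0L), co), "zero total")
})

test_that("enrichment standard errors follow binomial propagation", {
  ci <- c(A = 6L, L = 4L); co <- c(A = 10L, L = 40L)
  et <- enrichment_factor(ci, co)
  a <- et[et$name == "A" & et$level == "aa", ]
  vi <- 0.6; vo <- 0.2; ni <- 10; no <- 50
  se <- (vi / vo) * sqrt((sqrt(vi * (1 - vi) / ni) / vi)^2 +
                         (sqrt(vo * (1 - vo) / no) / vo)^2)
  expect_equal(a$se, se)
})

test_that("two-proportion Z-test reproduces published reference values", {
  # catalytic-site occupancy contrasts from the LIP literature:
  # 196/301 vs 3983/7668 -> p ~ 7e-6; 83/196 vs 30/104 -> p ~ 0.022
  t1 <- proportion_ztest(196, 301, 3983, 7668)
  expect_lt(abs(t1$p - 7e-6), 3e-6)
  t2 <- proportion_ztest(83, 196, 30, 104)
  expect_equal(t2$p, 0.022, tolerance = 0.05)
  # equal proportions give z = 0, p = 1
  t0 <- proportion_ztest(10, 100, 20, 200)
  expect_equal(t0$z, 0)
  expect_equal(t0$p, 1)
  expect_error(proportion_ztest(5, 0, 1, 10), "positive")
  expect_error(proportion_ztest(11, 10, 1, 10), "0 <= k <= n")
})

test_that("Z-test p-value agrees with a null-model simulation", {
  k1 <- 60; n1 <- 200; k2 <- 40; n2 <- 200
  obs <- proportion_ztest(k1, n1, k2, n2)
  set.seed(123)
  pp <- (k1 + k2) / (n1 + n2)
  reps <- 40000
  s1 <- rbinom(reps, n1, pp) / n1
  s2 <- rbinom(reps, n2, pp) / n2
  p_sim <- mean(abs(s1 - s2) >= abs(k1 / n1 - k2 / n2) - 1e-12)
  expect_equal(obs$p, p_sim, tolerance = 0.2)
  expect_lt(abs(obs$p - p_sim), 0.01)
})

test_that("mean difference report is internally consistent", {
  set.seed(5)
  keys <- paste0("A:", 1:100, ":")
  scores <- data.frame(key = keys, score = rnorm(100))
  mask <- keys[1:30]
  rep1 <- mean_difference(scores, mask)
  expect_equal(rep1$difference, rep1$mean_in - rep1$mean_out)
  # point-biserial correlation is algebraically tied to t
  expect_equal(rep1$r^2, rep1$t^2 / (rep1$t^2 + rep1$df))
  # swapping the mask negates the difference and t
  rep2 <- mean_difference(scores, setdiff(keys, mask))
  expect_equal(rep2$difference, -rep1$difference)
  expect_equal(rep2$t, -rep1$t)
  expect_equal(rep2$p, rep1$p)
  # Welch flavour alters df but not the means
  rep3 <- mean_difference(scores, mask, flavor = "welch")
  expect_equal(rep3$difference, rep1$difference)
  expect_lt(rep3$df, rep1$df + 1e-9)
})

test_that("mean difference handles degenerate inputs", {
  keys <- paste0("A:", 1:10, ":")
  scores <- data.frame(key = keys, score = rep(2.5, 10))
  rep0 <- mean_difference(scores, keys[1:4])
  expect_equal(rep0$difference, 0)
  expect_equal(rep0$d, 0)
  expect_equal(rep0$p, 1)
  expect_error(mean_difference(scores, keys), "non-empty")
  expect_error(mean_difference(scores, "Z:9:"), "non-empty")
})

test_that("a planted effect is recovered at the right size", {
  set.seed(77)
  keys <- paste0("A:", 1:1000, ":")
  inside <- keys[1:200]
  score <- c(rnorm(200, mean = 1), rnorm(800, mean = 0))
  scores <- data.frame(key = keys, score = score)
  rep1 <- mean_difference(scores, inside)
  expect_equal(rep1$difference, 1, tolerance = 0.25)
  expect_equal(rep1$d, 1, tolerance = 0.15)
  expect_lt(rep1$p, 1e-10)
})

test_that("site_lip_report counts match a brute-force tally", {
  res <- res_bundle()
  st <- res$structure
  rt <- residue_table(st)
  # annotate three residues as a synthetic SITE (two inside helix 2)
  sites <- list(list(site_id = "AC1",
                     members = data.frame(chain = "A",
                                          resno = c(2L, 16L, 19L),
                                          icode = "",
                                          resname = rt$resname[c(2, 16, 19)],
                                          key = rt$key[c(2, 16, 19)],
                                          is_protein = TRUE,
                                          in_structure = TRUE,
                                          stringsAsFactors = FALSE)))
  rep1 <- site_lip_report(res, sites, st)
  expect_equal(rep1$element, c("mLIPs", "cLIPs", "Full LIPs", "NO LIPs"))
  sets <- list(unique(unlist(lapply(res$lips, function(l) l$mlip$span))),
               unique(unlist(lapply(res$lips,
                                    function(l) l$clip$members$key))))
  sets[[3]] <- union(sets[[1]], sets[[2]])
  sets[[4]] <- setdiff(rt$key, sets[[3]])
  site_keys <- rt$key[c(2, 16, 19)]
  for (i in 1:4) {
    expect_equal(rep1$n_domain[i], length(intersect(rt$key, sets[[i]])))
    expect_equal(rep1$pct_domain[i],
                 100 * length(intersect(rt$key, sets[[i]])) / nrow(rt))
    expect_equal(rep1$n_site[i], length(intersect(site_keys, sets[[i]])))
    zt <- proportion_ztest(rep1$n_site[i], 3, rep1$n_domain[i], nrow(rt))
    expect_equal(rep1$p[i], zt$p)
  }
  # full LIPs + NO LIPs partition the domain
  expect_equal(rep1$n_domain[3] + rep1$n_domain[4], nrow(rt))
  # without sites the site columns are NA but the domain side is kept
  rep0 <- site_lip_report(res, list(), st)
  expect_true(all(is.na(rep0$n_site)))
  expect_true(all(is.na(rep0$p)))
  expect_equal(rep0$n_domain, rep1$n_domain)
})

test_that("exposure_profile tallies classes over the full mask size", {
  exposures <- data.frame(
    key = paste0("A:", 1:10, ":"),
    class = c("buried", "buried", "exposed", "intermediate", NA,
              "exposed", "buried", "exposed", "intermediate", "exposed"),
    stringsAsFactors = FALSE)
  masks <- list(all = exposures$key, some = exposures$key[c(1, 3, 5)])
  ep <- exposure_profile(masks, exposures)
  expect_equal(ep$n_buried, c(3L, 1L))
  expect_equal(ep$n_exposed, c(4L, 1L))
  expect_equal(ep$n_undefined, c(1L, 1L))
  # percentages use the total including undefined
  expect_equal(ep$pct_buried, 100 * c(3 / 10, 1 / 3))
  expect_equal(ep$pct_buried + ep$pct_intermediate + ep$pct_exposed +
               100 * ep$n_undefined / ep$total, c(100, 100))
})

test_that("lip_enrichment pools detections against the NO-LIP region", {
  # pool the designed positive (LIPs everywhere) with the designed
  # negative (no LIPs): both regions are then populated
  et <- lip_enrichment(list(res_bundle(), res_control()))
  expect_s3_class(et, "enrichment_table")
  leu <- et[et$name == "L" & et$level == "aa", ]
  # the no-LIP side is the all-leucine control, so leucine is depleted
  expect_lt(leu$ef, 1)
  expect_gt(leu$count_out, 0)
  # serine/asparagine exist only inside LIPs -> undefined EF (absent outside)
  ser <- et[et$name == "S" & et$level == "aa", ]
  expect_true(is.na(ser$ef))
})

test_that("group_composition percentages sum to 100 on canonical input", {
  st <- fx_bundle()$structure
  keys <- residue_table(st)$key
  gc <- group_composition(keys, st)
  expect_equal(sum(gc), 100)
  expect_named(gc, c("non-polar", "polar-uncharged", "negative", "positive"))
  # the polar-faced sequence is L with S/N at face positions
  s <- polar_face_sequence(14)
  n_polar <- sum(strsplit(paste0(s, s), "")[[1]] %in% c("S", "N"))
  expect_equal(unname(gc["polar-uncharged"]), 100 * n_polar / 28)
})

test_that("score tables round trip and reject duplicates", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(chain = "A", resno = 1:5, icode = "",
                   score = c(0.1, 0.5, 0.9, 0.2, 0.7))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_score_table(f)
  expect_equal(back$score, df$score)
  expect_equal(back$key, paste0("A:", 1:5, ":"))
  write.table(rbind(df, df[1, ]), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_score_table(f), "duplicate")
})

test_that("DSSP parsing maps summary letters to coarse classes", {
  dssp <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M              0   0  200",
    "    2    2 A K  H  >  S+     0   0  100",
    "    3    3 A E  E     -A    8   0   55",
    "    4    4 A V  B     -B    9   0   40",
    "    5    5 A G  T  <  S+     0   0   30",
    "    6        !*             0   0    0",
    "    7    6 B A  G  <  S+     0   0   10")
  f <- tempfile(fileext = ".dssp")
  writeLines(dssp, f)
  ss <- parse_dssp(f)
  expect_equal(nrow(ss), 6)      # chain-break record dropped
  expect_equal(ss$class, c("coil", "alpha", "beta", "beta", "other",
                           "other"))
  expect_equal(ss$key[1], "A:1:")
  expect_equal(ss$chain[6], "B")
  writeLines("not dssp", f)
  expect_error(parse_dssp(f), "not a DSSP")
})
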