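## TMT screen: rollup, baseline band, Method 1 filter, Method 2 clustering.

test_that("rollup normalizes to time zero and takes the PSM median", {
  # all channels equal -> all log ratios zero
  flat <- rbind(psm_row("P1", "pep1", rep(1, 6)),
                psm_row("P1", "pep2", rep(3, 6)))
  r <- rollup_proteins(flat)
  expect_equal(unname(r$log10_abundance["P1", ]), rep(0, 6))
  expect_equal(unname(r$log10_abundance[, "0"]), 0)

  # single PSM with ratios (1, 2, 2, 2, 2, 2); a second flat peptide keeps
  # the protein above the two-unique-peptide support rule
  one <- rbind(psm_row("P1", "pep1", c(1, 2, 2, 2, 2, 2)),
               psm_row("P1", "pep2", c(1, 2, 2, 2, 2, 2), base = 5e5))
  r <- rollup_proteins(one)
  expect_equal(unname(r$log10_abundance["P1", "8"]), log10(2))

  # two PSMs with ratios 1.0 and 3.0 -> median 2.0 -> log10 2 ~ 0.301
  two <- rbind(psm_row("P1", "pep1", c(1, 1, 1, 1, 1, 1)),
               psm_row("P1", "pep2", c(1, 3, 3, 3, 3, 3)))
  r <- rollup_proteins(two)
  expect_equal(unname(r$log10_abundance["P1", "8"]), log10(2))
  expect_equal(round(log10(2), 3), 0.301)
})

test_that("rollup is scale-invariant and enforces unique-peptide support", {
  psms <- rbind(psm_row("P1", "pep1", c(1, 2, 4, 8, 8, 8)),
                psm_row("P1", "pep2", c(1, 1.5, 2, 4, 4, 4)),
                psm_row("P1", "pep3", c(1, 1.5, 2, 4, 4, 4)),
                psm_row("P2", "pep1", c(1, 1, 1, 1, 1, 1)))  # one peptide only
  r <- rollup_proteins(psms)
  expect_false("P2" %in% rownames(r$log10_abundance))

  scaled <- psms
  icol <- grep("^t", names(scaled))
  scaled[1, icol] <- scaled[1, icol] * 17.3
  expect_equal(rollup_proteins(scaled)$log10_abundance, r$log10_abundance)

  # zero reference intensity -> PSM dropped with a warning
  bad <- psms
  bad$t0[1] <- 0
  expect_warning(rb <- rollup_proteins(bad), "non-positive reference")
  expect_equal(unname(rb$log10_abundance["P1", "24"]), log10(4))
})

test_that("baseline band is the control envelope at the anchor time", {
  # max 8-h fold change of 1.35 reproduces the +0.13 log10 threshold
  ctrl <- abund(c(0, log10(1.35), 0.02, 0.01, 0, 0.01),
                c(0, -0.04, 0.01, 0.03, 0.02, 0),
                c(0, 0.05, -0.02, 0.01, 0.04, 0.03))
  band <- derive_baseline_band(ctrl, anchor_time = 8)
  expect_equal(band$upper, log10(1.35))
  expect_equal(round(band$upper, 2), 0.13)
  expect_equal(band$lower, -0.04)

  # direct min/max example
  ctrl2 <- abund(c(0, -0.05, 0, 0, 0, 0), c(0, 0.02, 0, 0, 0, 0),
                 c(0, 0.10, 0, 0, 0, 0))
  band2 <- derive_baseline_band(ctrl2)
  expect_equal(c(band2$lower, band2$upper), c(-0.05, 0.10))

  # degenerate control: band collapses to (0, 0)
  band0 <- derive_baseline_band(abund(rep(0, 6), rep(0, 6)))
  expect_equal(c(band0$lower, band0$upper), c(0, 0))

  bandov <- derive_baseline_band(ctrl2, upper_override = 0.13)
  expect_equal(bandov$upper, 0.13)
  expect_error(derive_baseline_band(ctrl2[0, , drop = FALSE]), "empty")
  expect_error(derive_baseline_band(ctrl2, anchor_time = 9), "anchor_time")
})

test_that("the baseline-band filter implements rise, sustain and fall", {
  band <- structure(list(upper = 0.13, lower = -0.13), class = "baseline_band")
  up <- c(0, 0.2, 0.25, 0.3, 0.3, 0.3)
  down <- -up
  flat <- rep(0, 6)
  late <- c(0, 0, 0, 0, 0.3, 0.3)       # rises after the early window
  transient <- c(0, 0.3, 0.3, 0.1, 0.1, 0.1)  # not sustained
  ifng <- abund(up, flat, up, up, late, transient)
  il4 <- abund(down, flat, up, down, down, down)
  rownames(ifng) <- rownames(il4) <- paste0("P", 1:6)
  got <- filter_candidates(ifng, il4, band)
  expect_identical(got$protein, c("P1", "P4"))

  # explicit control containment removes proteins drifting out of band
  ctrl <- abund(flat, flat, flat, c(0, 0.5, 0, 0, 0, 0), flat, flat)
  rownames(ctrl) <- paste0("P", 1:6)
  got2 <- filter_candidates(ifng, il4, band, control = ctrl)
  expect_identical(got2$protein, c("P1"))
})

test_that("raising the band's upper edge can only shrink the candidate set", {
  sim <- simulate_tmt_experiment(tmt_sim_config(rng_seed = 31))
  roll <- lapply(sim$psms, rollup_proteins)
  prev <- Inf
  for (up in c(0.05, 0.13, 0.2, 0.31)) {
    band <- structure(list(upper = up, lower = -0.13), class = "baseline_band")
    n <- nrow(filter_candidates(roll[["M(IFNg)"]], roll[["M(IL-4)"]], band))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("zero-noise simulation is recovered exactly by the filter", {
  cfg <- tmt_sim_config(psm_noise_sd = 0, control_drift_sd = 0,
                        candidate_effect = 0.3, rng_seed = 13)
  sim <- simulate_tmt_experiment(cfg)
  roll <- lapply(sim$psms, rollup_proteins)
  band <- derive_baseline_band(roll[["M(-)"]])
  got <- filter_candidates(roll[["M(IFNg)"]], roll[["M(IL-4)"]], band,
                           control = roll[["M(-)"]])
  planted <- names(sim$truth$labels)[sim$truth$labels == "candidate"]
  expect_setequal(got$protein, planted)
})

test_that("sum normalization scales profiles to unit mass", {
  m <- abund(rep(1, 6), c(2, 0, 0, 0, 0, 0))
  s <- sum_normalize(m)
  expect_equal(unname(s[1, ]), rep(1 / 6, 6))
  expect_equal(unname(s[2, ]), c(1, 0, 0, 0, 0, 0))

  r <- matrix(runif(60), 10)
  expect_equal(rowSums(sum_normalize(r)), rep(1, 10), tolerance = 1e-12)
  expect_warning(sz <- sum_normalize(rbind(r, 0)), "all-zero")
  expect_equal(nrow(sz), 10)
  expect_error(sum_normalize(matrix(c(-1, 1), 1)), "nonnegative")
})

test_that("mixture clustering selects K by BIC and recovers planted groups", {
  # no structure: identical profiles collapse to a single cluster
  same <- matrix(rep(c(0.1, 0.2, 0.3, 0.2, 0.1, 0.1), each = 12), 12)
  expect_equal(cluster_profiles(same)$K, 1L)

  # two well-separated planted groups
  set.seed(42)
  g1 <- matrix(rnorm(25 * 6, 0, 0.05), 25, 6) +
    matrix(rep(c(1, 1, 1, 1, 1, 1), each = 25), 25)
  g2 <- matrix(rnorm(25 * 6, 0, 0.05), 25, 6) +
    matrix(rep(c(1, 2, 3, 4, 4, 4), each = 25), 25)
  prof <- rbind(g1, g2)
  rownames(prof) <- paste0("P", 1:50)
  colnames(prof) <- c(0, 8, 12, 24, 48, 72)
  model <- cluster_profiles(prof, K_range = 1:5)
  expect_equal(model$K, 2L)
  truth <- rep(1:2, each = 25)
  expect_equal(mclust::adjustedRandIndex(model$assignment, truth), 1)
  # the chosen K maximizes BIC among fitted K
  expect_equal(unname(which.max(model$bic)), model$K)
  expect_error(cluster_profiles(prof[1, , drop = FALSE]), "at least 2")
})

test_that("cluster selection composes the three per-condition trends", {
  band <- structure(list(upper = 0.13, lower = -0.13), class = "baseline_band")
  up <- c(0, 0.2, 0.3, 0.3, 0.3, 0.3); flat <- rep(0, 6)
  mk <- function(n_up, n_flat, seed) {
    set.seed(seed)
    m <- rbind(matrix(rep(up, each = n_up), n_up, 6) + rnorm(n_up * 6, 0, 0.01),
               matrix(rep(flat, each = n_flat), n_flat, 6) + rnorm(n_flat * 6, 0, 0.01))
    m[, 1] <- 0
    rownames(m) <- paste0("P", seq_len(nrow(m)))
    colnames(m) <- c(0, 8, 12, 24, 48, 72)
    m
  }
  ifng <- mk(10, 30, 1)
  il4 <- -mk(10, 30, 2)
  ctrl <- mk(0, 40, 3)
  models <- list(ifng = cluster_profiles(sum_normalize(10^ifng)),
                 il4 = cluster_profiles(sum_normalize(10^il4)),
                 control = cluster_profiles(sum_normalize(10^ctrl)))
  sel <- select_clusters(models, ifng, il4, ctrl, band, tol = 0.02)
  expect_setequal(sel$protein, paste0("P", 1:10))
  expect_true(all(sel$protein %in% rownames(ifng)))

  # a protein rising in both stimulated arms must be excluded
  il4_up <- mk(10, 30, 4)  # same first-10 block now increases in IL-4
  models$il4 <- cluster_profiles(sum_normalize(10^il4_up))
  sel2 <- select_clusters(models, ifng, il4_up, ctrl, band, tol = 0.02)
  expect_length(sel2$protein, 0)
})

test_that("zero-noise planted candidates are found by both screening methods", {
  cfg <- tmt_sim_config(psm_noise_sd = 0, control_drift_sd = 0, rng_seed = 17)
  sim <- simulate_tmt_experiment(cfg)
  roll <- lapply(sim$psms, rollup_proteins)
  band <- derive_baseline_band(roll[["M(-)"]])
  planted <- names(sim$truth$labels)[sim$truth$labels == "candidate"]

  m1 <- filter_candidates(roll[["M(IFNg)"]], roll[["M(IL-4)"]], band)
  expect_setequal(m1$protein, planted)

  prof <- lapply(roll, function(r) sum_normalize(10^r$log10_abundance))
  # zero-noise profiles are degenerate for EM at most K; skipped-K warnings
  # are expected here
  models <- suppressWarnings(
    list(ifng = cluster_profiles(prof[["M(IFNg)"]]),
         il4 = cluster_profiles(prof[["M(IL-4)"]]),
         control = cluster_profiles(prof[["M(-)"]])))
  m2 <- select_clusters(models, roll[["M(IFNg)"]], roll[["M(IL-4)"]],
                        roll[["M(-)"]], band)
  expect_true(all(planted %in% m2$protein))
  expect_true(all(m2$protein %in% rownames(roll[["M(IFNg)"]]$log10_abundance)))
})

test_that("cross-species intersection matches by uppercased symbol", {
  a <- candidate_list(c("Parp14", "Parp9", "Aldh2"), "filter")
  b <- candidate_list(c("PARP14", "STAT1"), "cluster")
  got <- intersect_species(a, b)
  expect_identical(got$protein, "PARP14")
  expect_identical(got$species, "both")

  expect_equal(nrow(intersect_species(c("A", "B"), c("C"))), 0)
  expect_lte(nrow(intersect_species(a, b)), min(nrow(a), nrow(b)))

  map <- data.frame(from = c("PARP14", "XDH"), to = c("PARP14", "XDH"))
  expect_message(got2 <- intersect_species(a, b, id_map = map), "excluded")
  expect_identical(got2$protein, "PARP14")
})

test_that("heat-map rows are z-scored and ordered by average-linkage leaves", {
  m <- abund(c(1, 2, 3, 4, 5, 6), timepoints = c(0, 8, 12, 24, 48, 72))
  m3 <- rbind(m, m + 10, -m)
  hm <- suppressWarnings(heatmap_matrix(m3))
  expect_equal(unname(rowMeans(hm$z)), rep(0, 3))
  expect_equal(unname(apply(hm$z, 1, sd)), rep(1, 3))
  z123 <- (c(1, 2, 3) - 2) / sd(c(1, 2, 3))
  expect_equal(unname(heatmap_matrix(rbind(cbind(1, 2, 3), cbind(3, 1, 2)))$z[1, ]),
               z123)

  expect_warning(hmc <- heatmap_matrix(abund(rep(0.5, 6), c(0, 1, 2, 3, 4, 5))),
                 "constant")
  expect_equal(unname(hmc$z[1, ]), rep(0, 6))

  # merge order on 4 rows equals the brute-force average-linkage oracle
  set.seed(9)
  r4 <- matrix(rnorm(24), 4)
  hm4 <- heatmap_matrix(r4)
  expect_identical(hclust_merge_sets(hm4$hclust), greedy_average_linkage(hm4$z))
})
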