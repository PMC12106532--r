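# Synthetic-cohort generator: panel, scenario defaults, compositions,
# events, clinical records and on-disk cohorts.

test_that("marker panel names are unique and cover the subset-label markers", {
  p <- default_marker_panel()
  expect_false(anyDuplicated(p$markers) > 0)
  required <- c("CD45", "CD45RA", "CD3", "CD4", "CD8", "CD14", "CD15",
                "CD19", "CD25", "CD56", "FoxP3", "CTLA4", "PD1", "TIGIT",
                "CX3CR1", "CXCR3", "CCR4", "CD160", "CD244", "HLADR",
                "TCRgd", "Tbet", "GATA3", "Ki67", "IL17A", "IL4", "IL8",
                "TNFa", "IFNg", "GranzymeB")
  expect_true(all(required %in% p$markers))
  expect_setequal(unique(p$lineage_map),
                  c("lineage", "functional", "checkpoint", "proliferation"))
})

test_that("default scenario matches the study design", {
  sc <- default_scenario()
  expect_equal(sc$n_sepsis, 39L)
  expect_equal(sc$n_healthy, 19L)
  expect_length(sc$archetypes, 20L)
  expect_equal(sum(sc$group_shift > 0), 4L)
  expect_equal(sum(sc$group_shift < 0), 7L)
  cp <- sc$clinical_couplings
  expect_equal(cp$r[cp$subset == "CD15+CD14+ monocyte" &
                      cp$variable == "procalcitonin"], 0.68)
  expect_equal(cp$r[cp$subset == "CD45RA-IL17A+CD4+ T" &
                      cp$variable == "lactate"], 0.57)
  val <- build_default_scenario("validation")
  expect_equal(val$n_sepsis, 20L)
  expect_equal(val$n_healthy, 15L)
})

test_that("scenario validation rejects broken inputs", {
  sc <- default_scenario()
  bad <- sc
  bad$covariance_healthy[1, 2] <- 5   # asymmetric
  expect_error(validate_scenario(bad), "symmetric")
  bad2 <- sc
  bad2$covariance_sepsis <- -diag(length(sc$subsets))
  expect_error(validate_scenario(bad2), "positive semi-definite")
  bad3 <- sc
  bad3$clinical_couplings$r[1] <- 1.2
  expect_error(validate_scenario(bad3), "< 1")
})

test_that("compositions close to 1 and degenerate noise returns the baseline", {
  sc <- default_scenario()
  comp <- simulate_compositions(sc, "sepsis", n = 50, seed = 1)
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))
  expect_true(all(comp >= 0))
  # deterministic given seed
  expect_identical(comp, simulate_compositions(sc, "sepsis", n = 50, seed = 1))
  # zero covariance and zero shift: every subject sits at the closed baseline
  dg <- degenerate_scenario()
  base <- exp(dg$base_logratio_mean) / sum(exp(dg$base_logratio_mean))
  comp0 <- simulate_compositions(dg, "sepsis", n = 7, seed = 2)
  for (i in 1:7) expect_equal(unname(comp0[i, ]), unname(base), tolerance = 1e-10)
  # non-PSD covariance is rejected
  bad <- dg
  bad$covariance_sepsis <- -diag(length(dg$subsets))
  expect_error(simulate_compositions(bad, "sepsis", n = 3, seed = 1),
               "positive semi-definite")
})

test_that("planted negative covariance survives the closure", {
  sc <- default_scenario()
  k <- length(sc$subsets)
  r <- diag(k)
  r[1, 2] <- r[2, 1] <- -0.7
  dimnames(r) <- dimnames(sc$covariance_healthy)
  sc$covariance_healthy <- 0.35^2 * r
  comp <- simulate_compositions(sc, "healthy", n = 1000, seed = 3)
  expect_lt(cor(comp[, 1], comp[, 2]), 0)
})

test_that("planted group means order enriched and depleted subsets", {
  sc <- default_scenario()
  fs <- colMeans(simulate_compositions(sc, "sepsis", n = 3000, seed = 4))
  fh <- colMeans(simulate_compositions(sc, "healthy", n = 3000, seed = 5))
  up <- sc$subsets[sc$group_shift > 0]
  dn <- sc$subsets[sc$group_shift < 0]
  expect_true(all(fs[up] > fh[up]))
  expect_true(all(fs[dn] < fh[dn]))
})

test_that("event simulation respects composition, count and labels", {
  arch <- three_archetypes()
  one <- c(1, 0, 0)
  em <- simulate_events(one, arch, 500, seed = 1)
  expect_true(all(em$labels == 1L))
  expect_equal(nrow(em$exprs), 500L)
  expect_identical(em$scale, "raw")
  expect_true(all(em$exprs >= 0))
  expect_error(simulate_events(numeric(0), list(), 10), "empty archetype")
  # a nearest-centroid oracle on asinh5 intensities recovers true labels
  sc <- default_scenario()
  em2 <- simulate_events(rep(1 / 20, 20), sc$archetypes, 6000, seed = 6)
  x <- asinh_transform(em2$exprs)
  cent <- vapply(sc$archetypes, archetype_centroid,
                 numeric(length(sc$panel$markers)))
  d <- -2 * x %*% cent
  d <- sweep(d, 2L, colSums(cent^2), `+`)
  pred <- max.col(-d, ties.method = "first")
  expect_gte(mean(pred == em2$labels), 0.95)
})

test_that("clinical couplings are calibrated and sepsis definitions hold", {
  sc <- default_scenario()
  comp <- simulate_compositions(sc, "sepsis", n = 1000, seed = 7)
  clin <- simulate_clinical(comp, "sepsis", sc, seed = 8)
  r_pct <- cor(100 * comp[, "CD15+CD14+ monocyte"], clin$procalcitonin)
  r_lac <- cor(100 * comp[, "CD45RA-IL17A+CD4+ T"], clin$lactate)
  expect_lt(abs(r_pct - 0.68), 0.06)
  expect_lt(abs(r_lac - 0.57), 0.06)
  expect_true(all(clin$psofa >= 2))
  # null coupling: lab independent of frequency
  sc0 <- sc
  sc0$clinical_couplings$r <- c(0, 0)
  clin0 <- simulate_clinical(simulate_compositions(sc0, "sepsis", n = 2000,
                                                   seed = 9),
                             "sepsis", sc0, seed = 10)
  comp0 <- simulate_compositions(sc0, "sepsis", n = 2000, seed = 9)
  expect_lt(abs(cor(100 * comp0[, "CD15+CD14+ monocyte"],
                    clin0$procalcitonin)), 0.1)
  # invalid coupling target
  scbad <- sc
  scbad$clinical_couplings$r[1] <- 1
  expect_error(simulate_clinical(comp, "sepsis", scbad, seed = 1), "< 1")
  # healthy records carry no severity or laboratory fields
  ch <- simulate_clinical(simulate_compositions(sc, "healthy", n = 20,
                                                seed = 11),
                          "healthy", sc, seed = 12)
  expect_true(all(is.na(ch$psofa)) && all(is.na(ch$procalcitonin)))
  expect_false(any(ch$picu_mortality))
})

test_that("outcome prevalences sit near their calibration targets", {
  sc <- default_scenario()
  comp <- simulate_compositions(sc, "sepsis", n = 4000, seed = 13)
  clin <- simulate_clinical(comp, "sepsis", sc, seed = 14)
  expect_lt(abs(mean(clin$severe_sepsis) - 0.746), 0.05)
  expect_lt(abs(mean(clin$septic_shock) - 0.729), 0.05)
  expect_lt(abs(mean(clin$multiorgan_dysfunction) - 0.695), 0.05)
  expect_lt(abs(mean(clin$picu_mortality) - 0.136), 0.04)
  expect_lt(abs(mean(clin$age_years > 1) - 0.744), 0.05)
})

test_that("generate_cohort writes a reproducible cohort", {
  sc <- build_default_scenario(events_per_subject = 60, seed = 21)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  g1 <- generate_cohort(sc, d1)
  g2 <- generate_cohort(sc, d2)
  expect_length(g1$event_files, 58L)
  # same seed twice: byte-identical truth sidecars
  expect_identical(readBin(g1$truth_file, "raw", file.size(g1$truth_file)),
                   readBin(g2$truth_file, "raw", file.size(g2$truth_file)))
  # event counts equal events_per_subject exactly
  em <- read_event_tsv(g1$event_files[1])
  expect_equal(nrow(em$exprs), 60L)
  expect_false(is.null(em$labels))
  # validation scenario: 35 event files
  val <- build_default_scenario("validation", events_per_subject = 40,
                                seed = 22)
  gv <- generate_cohort(val, file.path(tempdir(), "cohort_v"))
  expect_length(gv$event_files, 35L)
  # round trip preserves the clinical table
  back <- read_cohort(d1)
  expect_equal(nrow(back$clinical), 58L)
  expect_equal(back$truth$seed, 21L)
})
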