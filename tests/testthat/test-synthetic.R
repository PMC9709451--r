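test_that("the same seed reproduces the compendium exactly", {
  arch <- new_architecture(list(`1` = c(30, 110)), c(`1` = 160))
  sc <- new_scenario(n_studies = 10, detection_prob = 0.6, seed = 77)
  a <- simulate_compendium(arch, sc)
  b <- simulate_compendium(arch, sc)
  expect_identical(a$qtls, b$qtls)
  expect_identical(a$maps, b$maps)
  expect_identical(a$truth$qtls, b$truth$qtls)
})

test_that("generated CIs satisfy the formula inverse-proportionality exactly", {
  arch <- new_architecture(list(`1` = c(30, 110), `2` = c(60)),
                           c(`1` = 160, `2` = 120))
  sim <- simulate_compendium(arch, new_scenario(n_studies = 15,
                                                detection_prob = 0.8,
                                                missing_pve_prob = 0,
                                                seed = 9))
  withci <- attach_ci(sim$qtls, sim$studies)
  consts <- c(BC = 530, F2 = 530, DH = 287, RIL = 163)
  lhs <- withci$ci95_cm * withci$pop_size * withci$r2
  expect_true(all(abs(lhs - consts[withci$pop_type]) /
                    consts[withci$pop_type] < 1e-9))
  # and the generation-time sigma agrees with the formula sigma
  expect_equal(withci$sigma_cm, sim$truth$qtls$sigma_cm, tolerance = 1e-9)
})

test_that("near-noiseless simulations recover every true position closely", {
  arch <- new_architecture(list(`1` = c(40, 120)), c(`1` = 160),
                           expected_r2 = 0.5)
  # huge N * r2 forces CI (and sigma) to the floor
  sc <- new_scenario(n_studies = 8, detection_prob = 1,
                     n_range = c(10000L, 10000L),
                     r2_meanlog = log(0.5), r2_sdlog = 0,
                     r2_clip = c(0.5, 0.5), jitter_range = c(1, 1),
                     missing_pve_prob = 0, missing_lod_prob = 0, seed = 3)
  sim <- simulate_compendium(arch, sc)
  expect_true(all(abs(sim$truth$qtls$peak_cons_cm -
                        sim$truth$qtls$true_position_cm) < 0.3))
  res <- run_pipeline(sim$qtls, sim$studies, sim$scaffold, sim$maps,
                      seed = 2, k_max = 4)
  rec <- recovery_metrics(sim$truth, res$meta$mqtls)
  expect_equal(rec$k_accuracy, 1.0)
  expect_lt(rec$rmse_cm, 1.0)
})

test_that("a panel-scale scenario stays inside its stated bounds", {
  arch <- default_architecture()
  expect_equal(sum(arch$lengths), 2945.67, tolerance = 1e-9)
  expect_equal(sum(lengths(arch$positions)), 62)
  for (seed in 1:3) {
    sim <- simulate_compendium(arch, new_scenario(seed = seed))
    s <- summarize_compendium(sim$qtls, sim$studies)
    expect_equal(s$n_studies, 47)
    expect_gte(s$pop_size_range[1], 24)
    expect_lte(s$pop_size_range[2], 472)
    pve <- sim$qtls$pve_pct[!is.na(sim$qtls$pve_pct)]
    expect_true(all(pve >= 1 & pve <= 52))
    expect_true(all(sim$qtls$chr %in% 1:12))
  }
})

test_that("recovery metrics handle perfect and split outputs", {
  truth <- list(architecture = new_architecture(list(`1` = c(20, 80)),
                                                c(`1` = 100)))
  perfect <- data.frame(chr = 1L, position_cm = c(20, 80), ci95_cm = 4)
  rec <- recovery_metrics(truth, perfect)
  expect_equal(rec$k_accuracy, 1.0)
  expect_equal(rec$rmse_cm, 0)
  expect_equal(rec$coverage, 1.0)
  split <- data.frame(chr = 1L, position_cm = c(19, 21, 80), ci95_cm = 4)
  rec2 <- recovery_metrics(truth, split)
  expect_equal(rec2$k_accuracy, 0.0)
  expect_equal(rec2$n_matched, 2)   # greedy matching still defined
})

test_that("zero-detection scenarios fail with advice rather than silently", {
  arch <- new_architecture(list(`1` = c(50)), c(`1` = 100))
  sc <- new_scenario(n_studies = 1, detection_prob = 1e-6, seed = 1)
  expect_error(simulate_compendium(arch, sc), "no QTLs generated")
})
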