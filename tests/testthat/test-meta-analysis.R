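test_that("K=1 EM equals the closed-form precision-weighted mean", {
  f <- em_fit(c(0, 10), c(1, 1), K = 1)
  expect_equal(f$mu, 5.0, tolerance = 1e-10)
  # unequal precisions: (0*1 + 10/9) / (1 + 1/9) = 1
  f2 <- em_fit(c(0, 10), c(1, 3), K = 1)
  expect_equal(f2$mu, 1.0, tolerance = 1e-10)
  # generic closed form against an independent one-liner
  set.seed(5)
  x <- rnorm(12, 50, 10); s <- runif(12, 0.5, 4)
  f3 <- em_fit(x, s, K = 1)
  expect_equal(f3$mu, sum(x / s^2) / sum(1 / s^2), tolerance = 1e-10)
  expect_equal(f3$loglik,
               oracle_mixture_loglik(x, pmax(s, 0.1), f3$mu, 1),
               tolerance = 1e-9)
})

test_that("two separated clusters are recovered within 1 cM", {
  set.seed(7)
  x <- c(rnorm(10, 20, 2), rnorm(10, 80, 2))
  s <- rep(2, 20)
  f <- em_fit(x, s, K = 2, seed = 7)
  # oracle: the sample means of each generated half
  expect_lt(abs(f$mu[1] - mean(x[1:10])), 1)
  expect_lt(abs(f$mu[2] - mean(x[11:20])), 1)
  expect_equal(sum(f$pi), 1, tolerance = 1e-9)
  expect_true(all(diff(f$mu) > 0))
  expect_equal(f$nu, 3L)
})

test_that("EM reaches the brute-force partition optimum for n <= 6, K <= 2", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(2:6, 1)
    x <- runif(n, 0, 100)
    s <- runif(n, 0.5, 8)
    for (K in 1:min(2, n)) {
      f <- em_fit(x, s, K = K, seed = rep)
      oracle <- oracle_best_partition_loglik(x, pmax(s, 0.1), K)
      expect_gte(f$loglik, oracle - 1e-6)
    }
  }
})

test_that("information criteria follow their formulas, with the AICc guard", {
  fit <- structure(list(K = 1L, nu = 1L, n = 10L, loglik = -10,
                        loglik_classified = -10), class = "mixture_fit")
  sc <- score_models(fit)
  expect_equal(sc$aic, 22.0)
  expect_equal(sc$aic3, 23.0)
  expect_equal(sc$bic, 20 + log(10), tolerance = 1e-10)
  expect_equal(sc$aicc, 22 + 2 * 1 * 2 / 8)
  expect_equal(sc$awe, 20 + 2 * (1.5 + log(10)), tolerance = 1e-10)
  expect_gte(sc$aicc, sc$aic)
  # K=5, n=10: nu=9, n-nu-1=0 -> AICc sentinel
  fit5 <- structure(list(K = 5L, nu = 9L, n = 10L, loglik = -10,
                         loglik_classified = -12), class = "mixture_fit")
  expect_equal(score_models(fit5)$aicc, Inf)
})

test_that("model selection branches on n and breaks ties toward smaller K", {
  sc <- data.frame(K = 1:3,
                   aic = c(10, 5, 8), aic3 = c(10, 9, 2),
                   aicc = c(10, 9, 2), bic = c(1, 9, 8),
                   awe = c(10, 9, 2))
  # branch A: AIC alone decides
  selA <- select_model(sc, n = 8)
  expect_equal(selA$K, 2)
  expect_equal(selA$branch, "aic")
  # branch B: votes are aic3->3, aic->2, bic->1, awe->3, aicc->3
  selB <- select_model(sc, n = 15)
  expect_equal(selB$K, 3)
  expect_equal(selB$branch, "vote")
  # 2/2/1 split -> smaller K wins
  sc2 <- data.frame(K = 1:3, aic = c(9, 1, 5), aic3 = c(9, 1, 5),
                    aicc = c(9, 5, 1), bic = c(9, 5, 1),
                    awe = c(1, 5, 9))
  expect_equal(select_model(sc2, n = 15)$K, 2)
  expect_error(select_model(sc[0, ], 15), "empty")
})

test_that("MQTL construction applies precision addition, naming and traits", {
  proj <- data.frame(qtl_id = c("a", "b"), chr = 1L,
                     peak_cons_cm = c(10, 12), ci95_cons_cm = 3.92 * 2,
                     sigma_cm = 2, trait = c("SF", "TGW"),
                     pve_pct = c(10, 14), stringsAsFactors = FALSE)
  f <- em_fit(proj$peak_cons_cm, proj$sigma_cm, K = 1)
  built <- build_mqtls(f, proj)
  m <- built$mqtls
  expect_equal(m$position_cm, 11.0, tolerance = 1e-10)
  expect_equal(m$ci95_cm, 3.92 * sqrt(1 / (0.25 + 0.25)), tolerance = 1e-9)
  expect_equal(m$name, "MQTL1.1")
  expect_equal(m$traits, "SF,TGW")
  expect_equal(m$avg_pve, 12)
  # single member: MQTL CI equals the member CI
  f1 <- em_fit(10, 2, K = 1)
  one <- build_mqtls(f1, proj[1, ])
  expect_equal(one$mqtls$ci95_cm, 7.84, tolerance = 1e-12)
})

test_that("MQTLs are named by ascending position per chromosome", {
  proj <- data.frame(qtl_id = sprintf("q%d", 1:8), chr = 1L,
                     peak_cons_cm = c(rnorm(4, 62.9, .5), rnorm(4, 46.5, .5)),
                     sigma_cm = 1, ci95_cons_cm = 3.92,
                     trait = "SF", pve_pct = 10, stringsAsFactors = FALSE)
  f <- em_fit(proj$peak_cons_cm, proj$sigma_cm, K = 2, seed = 2)
  built <- build_mqtls(f, proj)
  expect_equal(built$mqtls$name, c("MQTL1.1", "MQTL1.2"))
  expect_true(diff(built$mqtls$position_cm) > 0)
})

test_that("chromosome run handles a single QTL and conserves membership", {
  one <- data.frame(qtl_id = "q", chr = 3L, peak_cons_cm = 40,
                    ci95_cons_cm = 7.84, sigma_cm = 2, trait = "PN",
                    pve_pct = 9, stringsAsFactors = FALSE)
  res <- run_chromosome(one, seed = 1)
  expect_equal(nrow(res$mqtls), 1)
  expect_equal(res$mqtls$ci95_cm, 7.84, tolerance = 1e-12)
  expect_equal(res$mqtls$position_cm, 40)
  # conservation on a larger run; each peak drawn with its own sigma
  set.seed(21)
  sig <- runif(24, 1, 3)
  mu <- rep(c(30, 90), each = 12)
  proj <- data.frame(qtl_id = sprintf("q%d", 1:24), chr = 5L,
                     peak_cons_cm = rnorm(24, mu, sig),
                     sigma_cm = sig, trait = "SF",
                     pve_pct = 10, stringsAsFactors = FALSE)
  proj$ci95_cons_cm <- proj$sigma_cm * 3.92
  res2 <- run_chromosome(proj, seed = 4, k_max = 6)
  expect_equal(sum(res2$mqtls$n_qtls), 24)
  expect_equal(res2$selection$K, 2)
})

test_that("tight two-group simulations select K = 2 under the vote", {
  set.seed(99)
  hits <- 0L
  for (i in 1:10) {
    x <- c(rnorm(6, 40, 2), rnorm(6, 100, 2))
    proj <- data.frame(qtl_id = sprintf("q%d", 1:12), chr = 1L,
                       peak_cons_cm = x, sigma_cm = 2,
                       ci95_cons_cm = 2 * 3.92, trait = "SF",
                       pve_pct = 10, stringsAsFactors = FALSE)
    res <- run_chromosome(proj, seed = i, k_max = 5)
    if (res$selection$K == 2) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("diffuse QTLs are not over-fragmented", {
  set.seed(555)
  ks <- integer(20)
  for (i in 1:20) {
    x <- runif(12, 0, 150)
    proj <- data.frame(qtl_id = sprintf("q%d", 1:12), chr = 1L,
                       peak_cons_cm = x, sigma_cm = 15,
                       ci95_cons_cm = 15 * 3.92, trait = "SF",
                       pve_pct = 10, stringsAsFactors = FALSE)
    ks[i] <- run_chromosome(proj, seed = i, k_max = 6)$selection$K
  }
  expect_gte(mean(ks <= 3), 0.9)
})

test_that("EM errors on K > n and refits on an empty component", {
  expect_error(em_fit(c(1, 2), c(1, 1), K = 3), "exceed")
  # all mass at one location: a 2-component fit collapses to 1
  f <- em_fit(rep(10, 5), rep(1, 5), K = 2, seed = 1)
  expect_true(f$K < 2 || f$empty_cluster_refit ||
                length(unique(f$assignment)) == f$K)
})
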