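test_that("Langmuir closed forms match independent evaluation", {
  expect_equal(langmuir_association(0, 1e-9, 1e7, 1e-4, 100), 0)
  # t -> Inf at C = K_D approaches r_max / 2
  kd <- 1e-4 / 1e7
  expect_equal(langmuir_association(1e9, kd, 1e7, 1e-4, 100), 50,
               tolerance = 1e-9)
  # kink-turn-range rates: independent evaluation of the closed form
  expect_equal(langmuir_association(100, 1e-9, 1.41e7, 2.77e-4, 100),
               74.7835166759, tolerance = 1e-9)
  # C >> K_D limit: R -> r_max (1 - exp(-C k_on t))
  C <- 1e-6; kon <- 1e7; koff <- 1e-4
  t <- seq(0, 50, by = 5)
  expect_equal(langmuir_association(t, C, kon, koff, 100),
               100 * (1 - exp(-C * kon * t)), tolerance = 1e-3)
  expect_equal(langmuir_dissociation(7, 42, 3e-4, t0 = 7), 42)
  expect_equal(langmuir_dissociation(log(2) / 3e-4, 42, 3e-4), 21)
  # 420 s window at the Table-1-range k_off decays by exp(-0.11634)
  expect_equal(langmuir_dissociation(420, 1, 2.77e-4) / 1,
               exp(-0.11634), tolerance = 1e-12)
})

test_that("sensorgram simulation is exact when noiseless and seeded otherwise", {
  sg <- simulate_sensorgrams(1e7, 1e-3, 80, concs = c(1e-10, 1e-9),
                             noise_sd = 0, drift_slope = 0)
  a <- sg[sg$phase == "association" & sg$conc == 1e-9, ]
  expect_equal(a$response,
               langmuir_association(a$time, 1e-9, 1e7, 1e-3, 80))
  d <- sg[sg$phase == "dissociation" & sg$conc == 1e-9, ]
  r0 <- langmuir_association(100, 1e-9, 1e7, 1e-3, 80)
  expect_equal(d$response, langmuir_dissociation(d$time, r0, 1e-3, 100))
  expect_true(all(sg$response[sg$phase == "baseline"] == 0))
  s1 <- simulate_sensorgrams(1e7, 1e-3, 80, 1e-9, noise_sd = 1, seed = 4L)
  s2 <- simulate_sensorgrams(1e7, 1e-3, 80, 1e-9, noise_sd = 1, seed = 4L)
  expect_identical(s1, s2)
})

test_that("double referencing is linear, grid-checked, and invariant to common offsets", {
  sg <- simulate_sensorgrams(1e7, 1e-3, 80, c(1e-9, 1e-8))
  zero <- sg; zero$response <- 0
  # all four identical -> zero everywhere
  expect_true(all(double_reference(sg, sg, sg, sg)$response == 0))
  # zero blank pair -> simple reference subtraction
  ref <- sg; ref$response <- 5
  corr <- double_reference(sg, ref, zero, zero)
  expect_equal(corr$response, sg$response - 5)
  # adding a constant to both sample and reference leaves R_corr unchanged
  sgc <- sg; sgc$response <- sg$response + 11
  refc <- ref; refc$response <- ref$response + 11
  expect_equal(double_reference(sgc, refc, zero, zero)$response,
               corr$response)
  bad <- sg[-1L, ]
  expect_error(double_reference(sg, bad, zero, zero), "grids")
})

test_that("kd_from_rates is an exact quotient and matches printed values", {
  # CS1-LS4 printed mean rates reproduce the printed K_D within 1%
  expect_lt(abs(kd_from_rates(2.00e7, 1.36e-4) / 6.82e-12 - 1), 0.01)
  expect_equal(kd_from_rates(1e7, 1e-4), 1e-11)
  expect_equal(kd_from_rates(3.3, 3.3), 1)
  expect_error(kd_from_rates(-1, 1e-4), "positive")
  expect_error(kd_from_rates(1e7, 0), "positive")
})

test_that("noiseless global fits recover generating parameters to 0.1%", {
  # spot checks here; the full 4x4 grid runs in the acceptance suite
  for (truth in list(c(kon = 2.00e7, koff = 1.36e-4),
                     c(kon = 1e5, koff = 1e-2))) {
    kd <- truth[["koff"]] / truth[["kon"]]
    sg <- simulate_sensorgrams(truth[["kon"]], truth[["koff"]], 100,
                               concs = kd * c(0.1, 0.3, 1, 3, 10))
    fit <- fit_kinetics(sg)
    expect_true(fit$converged)
    expect_false(fit$no_binding)
    expect_lt(abs(fit$k_on / truth[["kon"]] - 1), 1e-3)
    expect_lt(abs(fit$k_off / truth[["koff"]] - 1), 1e-3)
    # reported K_D is k_off/k_on of the same fit, bit for bit
    expect_identical(fit$k_d, fit$k_off / fit$k_on)
  }
})

test_that("flat zero signal raises the no-binding flag", {
  sg <- simulate_sensorgrams(1e7, 1e-4, 100, concs = c(1e-9, 1e-8, 1e-7),
                             noise_sd = 0.2, seed = 6L)
  sg$response <- sg$response * 0 + stats::rnorm(nrow(sg), 0, 0.2)
  fit <- fit_kinetics(sg)
  expect_true(fit$no_binding)
})

test_that("replicate aggregation is mean-of-ratios, with guards", {
  mkfit <- function(kon, koff) {
    structure(list(k_on = kon, k_off = koff, r_max = 100,
                   k_d = koff / kon, se = NULL, rss = 0, converged = TRUE,
                   no_binding = FALSE, noise_sd = 0, message = ""),
              class = "kinetic_fit")
  }
  same <- aggregate_replicates(list(mkfit(1e7, 1e-4), mkfit(1e7, 1e-4)))
  expect_equal(same$sd, rep(0, 4))
  two <- aggregate_replicates(list(mkfit(1e7, 2e-4), mkfit(1e7, 2.3e-4)))
  expect_equal(two$mean[two$parameter == "k_d"], 2.15e-11)
  # the replicates implied by printed means +/- SD (n = 2): K_D mean-of-ratios
  # is 2.14e-11 while the ratio of the mean rates is 1.96e-11
  kon <- 1.41e7 + c(-1, 1) * 1.11e7 / sqrt(2)
  koff <- 2.77e-4 + c(-1, 1) * 1.75e-4 / sqrt(2)
  agg <- aggregate_replicates(list(mkfit(kon[1L], koff[1L]),
                                   mkfit(kon[2L], koff[2L])))
  kd_mean <- agg$mean[agg$parameter == "k_d"]
  ratio_of_means <- agg$mean[agg$parameter == "k_off"] /
    agg$mean[agg$parameter == "k_on"]
  expect_equal(kd_mean, 2.13873401115e-11, tolerance = 1e-9)
  expect_equal(ratio_of_means, 1.96453900709e-11, tolerance = 1e-9)
  expect_gt(abs(kd_mean - ratio_of_means) / kd_mean, 0.05)
  nb <- mkfit(1e7, 1e-4); nb$no_binding <- TRUE
  expect_error(aggregate_replicates(list(mkfit(1e7, 1e-4), nb)), "N\\.B\\.")
  expect_error(aggregate_replicates(list(mkfit(1e7, 1e-4))), "length")
})

test_that("selectivity folds reproduce the printed values at 3 significant figures", {
  expect_equal(selectivity(2.75e-8, 6.82e-12), 4030)
  expect_equal(selectivity(1.49e-9, 6.82e-12), 218)
  expect_equal(selectivity(1.14e-7, 5.71e-12), 20000)
  expect_equal(selectivity(3e-9, 3e-9), 1)
})

test_that("orthogonality matrix orients ratios and proposes pairs", {
  kd <- matrix(c(1e-11, 1e-7,
                 1e-7, 1e-11), nrow = 2, byrow = TRUE,
               dimnames = list(c("rnaA", "rnaB"), c("pA", "pB")))
  out <- orthogonality_matrix(kd, cognate = c(rnaA = "pA", rnaB = "pB"),
                              selectivity_min = 4000)
  expect_equal(unname(diag(out$selectivity)), c(1, 1))
  expect_true(all(out$selectivity >= 1))
  expect_true(out$pairs$orthogonal)
  expect_equal(out$pairs$cross_selectivity_a, 1e4)
  # a CS2-like RNA that cannot discriminate two proteins is not orthogonal
  kd2 <- matrix(c(6.82e-12, 2.75e-8, 1.49e-9,
                  1.14e-7, 7.24e-12, 5.71e-12),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("CS1", "CS2"), c("LS4", "LS12", "L7Ae")))
  out2 <- orthogonality_matrix(kd2, cognate = c(CS1 = "LS4", CS2 = "L7Ae"),
                               selectivity_min = 4000)
  expect_equal(out2$selectivity["CS2", "LS12"], 7.24e-12 / 5.71e-12,
               tolerance = 5e-3)
  expect_false(out2$pairs$orthogonal)  # CS2 barely prefers L7Ae over LS12
  # the (CS1, LS4) x (CS2, LS12) pairing is orthogonal above 4000-fold
  out3 <- orthogonality_matrix(kd2, cognate = c(CS1 = "LS4", CS2 = "LS12"),
                               selectivity_min = 4000)
  expect_true(out3$pairs$orthogonal)
  expect_equal(min(out3$pairs$cross_selectivity_a,
                   out3$pairs$cross_selectivity_b), 4030)
  # N.B. entries are floored at the concentration-limit bound and flagged
  kdnb <- kd; kdnb["rnaA", "pB"] <- NA
  outnb <- orthogonality_matrix(kdnb, cognate = c(rnaA = "pA", rnaB = "pB"),
                                kd_nb_floor = 1e-6)
  expect_equal(outnb$selectivity["rnaA", "pB"], 1e5)
  expect_true(outnb$pairs$censored)
})

test_that("a 1% noise fit stays within a few percent of truth", {
  # slow dissociation needs the extended 200 s / 1500 s protocol (the same
  # reason dissociation was monitored for 25 min for the tightest binder)
  kd <- 1.36e-4 / 2e7
  sg <- simulate_sensorgrams(2e7, 1.36e-4, 100, concs = kd * c(0.1, 0.3, 1, 3, 10),
                             t_assoc = 200, t_dissoc = 1500,
                             noise_sd = 1, seed = 11L)
  fit <- fit_kinetics(sg)
  expect_true(fit$converged)
  expect_lt(abs(fit$k_on / 2e7 - 1), 0.05)
  expect_lt(abs(fit$k_off / 1.36e-4 - 1), 0.05)
})
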