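test_that("equilibrium bound fraction and avidity adjustment behave", {
  kd <- 3e-9
  expect_equal(equilibrium_bound_fraction(kd, kd), 0.5)
  expect_equal(equilibrium_bound_fraction(kd, 0), 0)
  expect_equal(equilibrium_bound_fraction(1e-11, 1e-8), 1e-8 / (1e-8 + 1e-11))
  expect_equal(equilibrium_bound_fraction(Inf, 1e-9), 0)
  # vector kd against scalar conc must broadcast element-wise
  expect_equal(equilibrium_bound_fraction(c(1e-9, 1e-6), 1e-9),
               c(0.5, 1e-9 / (1e-9 + 1e-6)))
  expect_equal(avidity_adjusted_kd(kd, copies = 1, urea = FALSE), kd)
  expect_equal(avidity_adjusted_kd(kd, copies = 10, avidity_exponent = 1),
               kd / 10)
  expect_equal(avidity_adjusted_kd(kd, urea = TRUE, urea_penalty = 5) /
                 avidity_adjusted_kd(kd, urea = FALSE), 5)
})

test_that("capture probability follows the mixture model", {
  cfg <- round_config(n_washes = 0L, avidity_copies = 1L,
                      capture_eff_step1 = 0.5, background_step1 = 1e-4,
                      effective_protein_conc = 1e-9)
  phage <- protein_pool("ARNDCEQG", 1, ids = "P1", seed = 2L)
  ls <- kd_landscape("R1", "P1", k_on = 1e7, k_off = 1e-4)  # K_D 1e-11
  # planted case: 0.5 * C/(C + K_D) + background
  expect_equal(unname(capture_probability("R1", phage, ls, cfg)),
               0.5 * (1e-9 / (1e-9 + 1e-11)) + 1e-4)
  # nonbinder with zero background -> 0
  cfg0 <- round_config(n_washes = 0L, background_step1 = 0)
  expect_equal(unname(capture_probability("Rx", phage, ls, cfg0)), 0)
  # saturation limit: kd << conc, eff 1, bg 0 -> ~1
  cfg1 <- round_config(n_washes = 0L, avidity_copies = 1L,
                       capture_eff_step1 = 1, background_step1 = 0,
                       effective_protein_conc = 1e-6)
  lsat <- kd_landscape("R1", "P1", k_on = 1e8, k_off = 1e-6)  # 1e-14 M
  expect_equal(unname(capture_probability("R1", phage, lsat, cfg1)), 1,
               tolerance = 1e-7)
  # washes erode the background term only
  cfgw <- round_config(n_washes = 3L, wash_loss = 0.5,
                       background_step1 = 1e-2, capture_eff_step1 = 0)
  expect_equal(unname(capture_probability("Rx", phage, ls, cfgw)),
               1e-2 * 0.5^3)
  expect_error(capture_probability(NA_character_, phage, ls, cfg), "unknown")
})

test_that("expectation-mode mixture enrichment matches the closed form exactly", {
  mix <- tiny_mixture(binder_frac = 0.01)
  cfg <- round_config(n_washes = 0L, avidity_copies = 1L,
                      capture_eff_step1 = 0.5, background_step1 = 1e-3,
                      bottleneck_rna = Inf, bottleneck_phage = Inf)
  p <- capture_probability(c("bind", "nonbind"), mix$phage, mix$landscape, cfg)
  res <- simulate_round(mix$rna, mix$phage, mix$landscape, cfg,
                        mode = "expectation")
  f0 <- 0.01
  f1 <- res$rna$count[1L] / sum(res$rna$count)
  f1_formula <- f0 * p[["bind"]] / (f0 * p[["bind"]] + (1 - f0) * p[["nonbind"]])
  expect_equal(f1, f1_formula, tolerance = 1e-15)
  expect_gt(f1 / f0, 1)
  # the closed form itself at p_bind = 0.5, p_nonbind = 0.001 gives 83.47x
  f <- 0.01
  expect_equal(f * 0.5 / (f * 0.5 + (1 - f) * 0.001) / f, 83.4724540902,
               tolerance = 1e-10)
})

test_that("expectation mode equals the stochastic mean within 3 SE", {
  mix <- tiny_mixture(binder_frac = 0.2, total = 2e4)
  cfg <- round_config(n_washes = 2L, capture_eff_step1 = 0.5,
                      background_step1 = 1e-2, background_step2 = 1e-2,
                      bottleneck_rna = Inf, bottleneck_phage = Inf)
  exp_res <- simulate_round(mix$rna, mix$phage, mix$landscape, cfg,
                            mode = "expectation")
  n_rep <- 120L
  draws <- vapply(seq_len(n_rep), function(s)
    simulate_round(mix$rna, mix$phage, mix$landscape, cfg, seed = s)$rna$count,
    numeric(2L))
  m <- rowMeans(draws)
  se <- apply(draws, 1L, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(m - exp_res$rna$count) <= 3 * se + 1e-9))
  # captured counts never exceed inputs
  expect_true(all(exp_res$rna$count <= mix$rna$count))
  expect_true(all(draws <= mix$rna$count))
})

test_that("simulate_round is deterministic, reports crashes, applies negative selection", {
  mix <- tiny_mixture()
  cfg <- round_config(seed = 5L)
  r1 <- simulate_round(mix$rna, mix$phage, mix$landscape, cfg)
  r2 <- simulate_round(mix$rna, mix$phage, mix$landscape, cfg)
  expect_identical(r1$rna, r2$rna)
  expect_identical(r1$phage, r2$phage)
  # all efficiencies and backgrounds zero -> crash flagged, not an error
  cfg0 <- round_config(capture_eff_step1 = 0, capture_eff_step2 = 0,
                       background_step1 = 0, background_step2 = 0)
  crash <- simulate_round(mix$rna, mix$phage, mix$landscape, cfg0,
                          mode = "expectation")
  expect_true(crash$crashed)
  expect_setequal(crash$crashed_pool, c("RNA", "phage"))
  # negative selection depletes flagged bead binders
  rna_fl <- rna_pool(c(strrep("A", 20), strrep("G", 20)), c(1e4, 1e4),
                     ids = c("ok", "sticky"), bead_binder = c(FALSE, TRUE))
  cfg_neg <- round_config(negative_selection = TRUE,
                          neg_selection_depletion = 0.99,
                          background_step1 = 1e-2, bottleneck_rna = Inf)
  out <- simulate_round(rna_fl, mix$phage, mix$landscape, cfg_neg,
                        mode = "expectation")
  ratio <- out$rna$count[out$rna$species_id == "sticky"] /
    out$rna$count[out$rna$species_id == "ok"]
  expect_equal(ratio, 0.01, tolerance = 1e-12)
})

test_that("raising stringency never decreases cognate expected enrichment", {
  mix <- tiny_mixture(binder_frac = 0.01)
  ef_of <- function(cfg) {
    res <- simulate_round(mix$rna, mix$phage, mix$landscape, cfg,
                          mode = "expectation")
    (res$rna$count[1L] / sum(res$rna$count)) / 0.01
  }
  base <- round_config(n_washes = 2L, background_step1 = 1e-3,
                       bottleneck_rna = Inf, bottleneck_phage = Inf)
  more_washes <- round_config(n_washes = 6L, background_step1 = 1e-3,
                              bottleneck_rna = Inf, bottleneck_phage = Inf)
  with_urea <- round_config(n_washes = 2L, background_step1 = 1e-3,
                            urea = TRUE, bottleneck_rna = Inf,
                            bottleneck_phage = Inf)
  lower_bg <- round_config(n_washes = 2L, background_step1 = 1e-4,
                           bottleneck_rna = Inf, bottleneck_phage = Inf)
  expect_gte(ef_of(more_washes), ef_of(base))
  expect_gte(ef_of(with_urea), ef_of(base))
  expect_gte(ef_of(lower_bg), ef_of(base))
})

test_that("amplification preserves abundances and scales exactly without noise", {
  pool <- rna_pool(c(strrep("A", 20), strrep("C", 20), strrep("G", 20)),
                   c(100, 250, 650))
  out <- amplify(pool, target_total = 10000, amplification_noise_sd = 0)
  expect_identical(out$count, c(1000, 2500, 6500))
  # single species keeps abundance 1
  single <- rna_pool(strrep("U", 20), 7)
  amp1 <- amplify(single, 1e4, amplification_noise_sd = 0.3, seed = 2L)
  expect_equal(amp1$count / sum(amp1$count), 1)
  # relative abundances preserved in expectation under noise (200 seeds, 3 SE)
  fracs <- vapply(seq_len(200L), function(s) {
    a <- amplify(pool, 1e6, amplification_noise_sd = 0.2, seed = s)
    a$count[1L] / sum(a$count)
  }, numeric(1L))
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.1), 3 * se)
})

test_that("read generation is seeded, honors the error model and abundances", {
  pool <- rna_pool(strrep("A", 20), 100)
  r0 <- generate_reads(pool, 50L, per_base_error_rate = 0, seed = 1L)
  expect_identical(unique(r0$sequence), pool$read_template)
  expect_identical(nrow(generate_reads(pool, 0L)), 0L)
  r1 <- generate_reads(pool, 200L, per_base_error_rate = 0.01,
                       barcode = "ACGTAC", seed = 9L)
  r2 <- generate_reads(pool, 200L, per_base_error_rate = 0.01,
                       barcode = "ACGTAC", seed = 9L)
  expect_identical(r1, r2)
  expect_true(all(startsWith(r1$sequence, "ACGTAC")))
  expect_identical(nchar(r1$sequence), nchar(r1$quality))
  # 50/50 two-species pool: read counts within 3 sigma of binomial
  two <- rna_pool(c(strrep("A", 20), strrep("C", 20)), c(5e4, 5e4))
  n <- 1e5L
  rr <- generate_reads(two, n, seed = 3L)
  k <- sum(rr$sequence == two$read_template[1L])
  expect_lt(abs(k - n / 2), 3 * sqrt(n * 0.25))
})

test_that("campaigns compose rounds, stay seeded, and flag crashes with the round index", {
  mix <- tiny_mixture(binder_frac = 0.01, total = 1e6)
  sched <- default_campaign_schedule(2L, background_step1 = 1e-3,
                                     background_step2 = 1e-3)
  camp <- campaign_config(mix$rna, mix$phage, mix$landscape, sched,
                          n_reads = 500L, seed = 77L)
  sim1 <- simulate_campaign(camp)
  sim2 <- simulate_campaign(camp)
  expect_identical(sim1$pools, sim2$pools)
  expect_identical(sim1$reads, sim2$reads)
  expect_true(is.na(sim1$crashed_round))
  # 1-round expectation campaign equals simulate_round + amplify
  one <- campaign_config(mix$rna, mix$phage, mix$landscape,
                         sched[1L], n_reads = 0L, seed = 77L)
  simc <- simulate_campaign(one, mode = "expectation")
  manual <- simulate_round(mix$rna, mix$phage, mix$landscape, sched[[1L]],
                           mode = "expectation")
  manual_rna <- amplify(manual$rna, sched[[1L]]$rna_input,
                        mode = "expectation")
  expect_equal(simc$pools[["1"]]$rna$count, manual_rna$count)
  # crash propagates with the round index
  dead <- lapply(1:2, function(i)
    round_config(capture_eff_step1 = 0, capture_eff_step2 = 0,
                 background_step1 = 0, background_step2 = 0))
  campd <- campaign_config(mix$rna, mix$phage, mix$landscape, dead,
                           seed = 1L)
  expect_identical(simulate_campaign(campd,
                                     mode = "expectation")$crashed_round, 1L)
})
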