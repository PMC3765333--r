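expected_counts_ex <- c(180, 20, 0, 20, 360, 20, 0, 20, 180)

test_that("joint EM recovers truth from expected counts when c or delta is 0", {
  e <- em_single_family(expected_counts_ex, "coupling")
  expect_lt(abs(e$c_hat), 1e-3)
  expect_equal(e$delta_hat, 0.20, tolerance = 1e-3)
  expect_true(e$converged)
  expect_true(e$monotone)

  # linkage equilibrium, no recombinant classes
  e2 <- em_single_family(c(50, 50, 0, 50, 100, 50, 0, 50, 50), "coupling")
  expect_lt(abs(e2$c_hat), 1e-3)
  expect_lt(abs(e2$delta_hat), 1e-3)

  # c identifiable when delta = 0: expected counts at c = 0.2, LE
  en <- round(expected_counts("coupling", 0.2, hap_freqs(rep(0.25, 4)), 4000))
  e3 <- em_single_family(en, "coupling")
  expect_equal(e3$c_hat, 0.2, tolerance = 1e-3)
  expect_lt(abs(e3$delta_hat), 1e-3)

  # negative LD, c = 0
  en4 <- round(expected_counts("coupling", 0, hap_freqs_from_ld(0.5, 0.5, -0.1),
                               2000))
  e4 <- em_single_family(en4, "coupling")
  expect_lt(abs(e4$c_hat), 1e-3)
  expect_equal(e4$delta_hat, -0.1, tolerance = 1e-3)
})

test_that("confounding when both c and delta are nonzero is present, not fixed", {
  en <- round(expected_counts("coupling", 0.2, hap_freqs_from_ld(0.5, 0.5, 0.2),
                              2000))
  e <- em_single_family(en, "coupling")
  # the estimator does NOT recover (0.2, 0.2); it lands on the ridge
  expect_gt(abs(e$c_hat - 0.2) + abs(e$delta_hat - 0.2), 0.05)
  # but the fit is as good as the global maximum
  g <- grid_oracle(en, "coupling")
  expect_equal(e$loglik, g$loglik, tolerance = 1e-3)
})

test_that("EM and the grid oracle agree in log-likelihood on random data", {
  set.seed(7)
  cfg <- em_config(n_starts = 5)
  for (i in 1:40) {
    m <- random_pair_model()
    cnt <- simulate_family(
      family_sim_spec(m$phase, m$c, ld_delta(m$h),
                      allele_freqs(m$h)["f_T"], allele_freqs(m$h)["f_M"],
                      N = sample(30:300, 1), seed = 1000 + i))
    fit <- em_single_family(cnt, "coupling", cfg)
    g <- grid_oracle(cnt, "coupling")
    expect_true(fit$monotone)
    expect_lt(abs(fit$loglik - g$loglik), 1e-3)
  }
})

test_that("grid oracle handles degenerate and mirrored inputs", {
  g <- grid_oracle(c(0, 0, 0, 0, 0, 0, 0, 0, 50), "coupling")
  expect_equal(g$c, 0)
  expect_equal(g$loglik, 50 * log(0.5), tolerance = 1e-2)

  n <- as.numeric(simulate_family(
    family_sim_spec("coupling", 0.05, 0.15, N = 200, seed = 5)))
  sw <- n[c(7, 8, 9, 4, 5, 6, 1, 2, 3)]   # swap T/t labels: flips phase
  g1 <- grid_oracle(n, "coupling")
  g2 <- grid_oracle(sw, "repulsion")
  expect_equal(g1$loglik, g2$loglik, tolerance = 1e-6)
  expect_equal(g1$delta, -g2$delta, tolerance = 1e-4)
})

test_that("phase posterior identifies the sire phase and respects symmetry", {
  est <- phase_probability(expected_counts_ex)
  expect_gt(est$phase_posterior, 0.999)
  expect_identical(est$phase, "coupling")

  # all double-heterozygote offspring: symmetric under both phases
  expect_equal(phase_probability(c(0, 0, 0, 0, 10, 0, 0, 0, 0))$phase_posterior,
               0.5)
  # no data
  expect_equal(phase_probability(rep(0, 9))$phase_posterior, 0.5)

  # posterior(counts) + posterior(label-swapped counts) = 1
  set.seed(8)
  for (i in 1:10) {
    cnt <- as.numeric(simulate_family(
      family_sim_spec("coupling", runif(1, 0, 0.3), runif(1, -0.1, 0.2),
                      N = 120, seed = 300 + i)))
    p1 <- phase_probability(cnt)$phase_posterior
    p2 <- phase_probability(swap_locus2(cnt))$phase_posterior
    expect_equal(p1 + p2, 1, tolerance = 1e-6)
  }
})

test_that("monomorphic progeny data are flagged, not silently estimated", {
  e <- em_single_family(c(30, 40, 30, 0, 0, 0, 0, 0, 0), "coupling")
  expect_identical(e$status, "monomorphic")
  e2 <- em_single_family(expected_counts_ex, "coupling")
  expect_identical(e2$status, "ok")
})

test_that("LE-constrained estimator attenuates c under maternal LD", {
  # fully linked data: no recombination signal
  le <- em_le_constrained(expected_counts_ex, "coupling")
  expect_lt(le$c_hat, 1e-3)

  # exact expected counts at (c=0.10, delta=0.20), N=2000: severe attenuation
  en <- c(405, 90, 5, 90, 820, 90, 5, 90, 405)
  le2 <- em_le_constrained(en, "coupling")
  expect_equal(le2$c_hat, 0.0122, tolerance = 2e-3)
  le2b <- em_le_constrained(en, "coupling", allele_freqs = "ml")
  expect_equal(le2b$c_hat, le2$c_hat, tolerance = 1e-3)

  # correctly specified (delta = 0): c recovered
  en3 <- round(expected_counts("coupling", 0.15, hap_freqs(rep(0.25, 4)), 4000))
  le3 <- em_le_constrained(en3, "coupling")
  expect_equal(le3$c_hat, 0.15, tolerance = 2e-3)
})

test_that("multi-family EM reduces to the single family case and pools correctly", {
  cnt <- simulate_family(family_sim_spec("coupling", 0.1, 0, N = 300, seed = 9))
  single <- em_single_family(cnt, "coupling")
  multi <- em_multi_family(list(
    family_observation(cnt, "TtMm", known_phase = "coupling")))
  expect_equal(multi$c_hat, single$c_hat, tolerance = 1e-3)
  expect_equal(multi$delta_hat, single$delta_hat, tolerance = 1e-3)

  # double-homozygous sires: maternal gametes observed, c not estimable
  hom <- family_observation(c(45, 5, 0, 5, 45, 0, 0, 0, 0), "TTMM")
  expect_warning(mh <- em_multi_family(list(hom)), "not estimable")
  expect_true(is.na(mh$c_hat))
  expect_equal(mh$delta_hat, 0.2, tolerance = 0.02)

  # pooled six-family design at (c=0, delta=0.2): delta recovered
  fams <- simulate_multi_family(c(94, 77, 106, 81, 79, 100), c = 0,
                                delta = 0.2, seed = 4)
  est <- em_multi_family(fams)
  expect_lt(abs(est$delta_hat - 0.2), 0.05)
  expect_true(est$monotone)
})

test_that("expected-count likelihood surfaces reproduce the published argmaxes", {
  cases <- list(list(truth = c(0.20, 0.00), argmax = c(0.20, 0.00)),
                list(truth = c(0.20, 0.20), argmax = c(0.10, 0.15)),
                list(truth = c(0.00, 0.00), argmax = c(0.00, 0.00)),
                list(truth = c(0.00, 0.20), argmax = c(0.00, 0.20)))
  for (cs in cases) {
    s <- expected_loglik_surface(cs$truth[1], cs$truth[2], grid_step = 0.05)
    expect_equal(unname(s$argmax), cs$argmax, tolerance = 1e-9)
  }
  # degenerate coarse grid still works
  s2 <- expected_loglik_surface(0.2, 0, grid_step = 0.5)
  expect_equal(dim(s2$loglik), c(2L, 3L))
})

test_that("empty families yield neutral results", {
  e <- em_single_family(rep(0, 9), "coupling")
  expect_identical(e$loglik, 0)
  expect_true(is.na(e$c_hat))
  expect_error(em_multi_family(list(
    family_observation(rep(0, 9), "TtMm"))), "empty")
})
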