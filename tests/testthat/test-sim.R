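test_that("family simulation conserves counts and is seed-deterministic", {
  spec <- family_sim_spec("coupling", 0.1, 0.1, N = 250, seed = 3)
  a <- simulate_family(spec)
  expect_identical(sum(a), 250)
  expect_identical(as.numeric(a), as.numeric(simulate_family(spec)))
  b <- simulate_family(family_sim_spec("coupling", 0.1, 0.1, N = 250, seed = 4))
  expect_false(identical(as.numeric(a), as.numeric(b)))
})

test_that("complete-LD families occupy only the two-haplotype classes", {
  cnt <- simulate_family(family_sim_spec("coupling", 0, 0.25, N = 500,
                                         seed = 12))
  expect_identical(sum(cnt[c(2, 3, 4, 6, 7, 8)]), 0)
})

test_that("empirical class frequencies converge to the model probabilities", {
  set.seed(13)
  for (i in 1:3) {
    m <- random_pair_model()
    N <- 2e5
    cnt <- simulate_family(
      family_sim_spec(m$phase, m$c, ld_delta(m$h),
                      allele_freqs(m$h)["f_T"], allele_freqs(m$h)["f_M"],
                      N = N, seed = 500 + i))
    p <- genotype_class_probs(m$phase, m$c, m$h)
    keep <- p > 0
    expect_identical(sum(cnt[!keep]), 0)
    gof <- suppressWarnings(
      stats::chisq.test(as.numeric(cnt[keep]), p = p[keep] / sum(p[keep])))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("sire draws follow the population haplotype frequencies", {
  s <- simulate_sire(hap_freqs(c(1, 0, 0, 0)), seed = 1)
  expect_identical(s$genotype, "TTMM")
  expect_identical(s$kind, "double_hom")

  set.seed(21)
  two_hap <- hap_freqs(c(0.5, 0, 0, 0.5))
  g <- replicate(200, simulate_sire(two_hap)$genotype)
  expect_true(all(g %in% c("TTMM", "ttmm", "TtMm")))

  set.seed(22)
  unif <- hap_freqs(rep(0.25, 4))
  kinds <- replicate(20000, simulate_sire(unif)$kind)
  frac <- mean(kinds == "double_het")
  # P(double het) = 2 (f_TM f_tm + f_Tm f_tM) = 0.25
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(frac - 0.25), 3 * se)
})

test_that("multi-family simulation is deterministic and sire-consistent", {
  fams <- simulate_multi_family(c(20, 30), c = 0.1, delta = 0.1, seed = 31)
  fams2 <- simulate_multi_family(c(20, 30), c = 0.1, delta = 0.1, seed = 31)
  expect_identical(fams, fams2)
  expect_identical(vapply(fams, function(f) sum(f$counts), numeric(1)),
                   c(20, 30))
  # offspring classes must be reachable from the sire genotype
  for (f in fams) {
    if (substr(f$sire_genotype, 1, 2) == "TT")
      expect_identical(sum(f$counts[7:9]), 0)   # no tt offspring
    if (substr(f$sire_genotype, 1, 2) == "tt")
      expect_identical(sum(f$counts[1:3]), 0)
  }
})

test_that("phased-chromosome transmission respects crossovers and LD chain", {
  # zero crossovers: every paternal gamete is an intact sire chromosome
  spec0 <- synthetic_chrom_spec(n_snps = 60, n_progeny = 20,
                                recomb_count_probs = c(1, 0, 0, 0), seed = 41)
  sim0 <- simulate_phased_chromosome(spec0)
  expect_true(all(lengths(sim0$truth$crossovers) == 0))
  expect_true(all(apply(sim0$truth$paternal_strand, 2,
                        function(s) length(unique(s)) == 1L)))

  # complete-LD maternal chain: each maternal chromosome is one haplotype
  map <- data.frame(chrom = "1", pos = seq(1e6, 5e6, by = 1e6))
  sire <- rbind(rep(1L, 5), rep(2L, 5))
  ph <- matrix(rep(c(0.5, 0, 0, 0.5), each = 4), 4, 4)
  spec1 <- chrom_sim_spec(map, sire, ph, c(1, 0, 0, 0), n_progeny = 40,
                          seed = 42)
  sim1 <- simulate_phased_chromosome(spec1)
  cols <- apply(sim1$truth$maternal, 2, function(m) length(unique(m)))
  expect_true(all(cols == 1L))

  # crossover-count frequencies match the stated probabilities
  pr <- c(0.511494, 0.398467, 0.081418, 0.00862)
  spec2 <- synthetic_chrom_spec(n_snps = 10, n_progeny = 20000,
                                recomb_count_probs = pr, seed = 43)
  sim2 <- simulate_phased_chromosome(spec2)
  k <- lengths(sim2$truth$crossovers)
  for (j in 0:3) {
    se <- sqrt(pr[j + 1] * (1 - pr[j + 1]) / 20000)
    expect_lt(abs(mean(k == j) - pr[j + 1]), 4 * se)
  }
})

test_that("maternal Markov chain matches its per-SNP marginal frequencies", {
  spec <- synthetic_chrom_spec(n_snps = 40, n_progeny = 4000, seed = 44)
  sim <- simulate_phased_chromosome(spec)
  phf <- spec$pair_hapfreqs
  expected <- c(phf[1, 1] + phf[1, 2], phf[, 1] + phf[, 3])
  observed <- rowMeans(sim$truth$maternal == 1L)
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_true(all(abs(observed - expected) < 4 * se + 1e-9))
})

test_that("zero-probability conditioning alleles are reported by SNP", {
  map <- data.frame(chrom = "1", pos = c(1e6, 2e6, 3e6))
  sire <- rbind(c(1L, 1L, 1L), c(2L, 2L, 2L))
  ph <- rbind(c(1, 0, 0, 0),      # SNP1 always allele 1 ...
              c(0, 0, 0.5, 0.5))  # ... but pair 2 conditions on allele 2
  spec <- chrom_sim_spec(map, sire, ph, c(1, 0, 0, 0), n_progeny = 5,
                         seed = 45)
  expect_error(simulate_phased_chromosome(spec), "conditioning allele")
})

test_that("replicate_experiment summarizes, excludes failures, and seeds deterministically", {
  sim <- function(s) {
    set.seed(s)
    rnorm(1)
  }
  est <- function(x) c(value = x)
  r1 <- replicate_experiment(sim, est, 50, seed = 6)
  r2 <- replicate_experiment(sim, est, 50, seed = 6)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$n_fail, 0L)

  r3 <- replicate_experiment(sim, est, 1, seed = 6)
  expect_identical(unname(r3$sd), 0)

  flaky <- function(x) {
    if (x > 0.5) stop("boom")
    c(value = x)
  }
  r4 <- replicate_experiment(sim, flaky, 50, seed = 6)
  expect_gt(r4$n_fail, 0)
  expect_true(all(r4$estimates[, 1] <= 0.5, na.rm = TRUE))
})
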