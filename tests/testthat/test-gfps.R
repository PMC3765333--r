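make_toy_data <- function(progeny, sire, pos = NULL) {
  n <- nrow(progeny)
  if (is.null(pos)) pos <- seq_len(n) * 1e5
  map <- data.frame(snp_id = sprintf("s%d", seq_len(n)), chrom = "1",
                    pos = pos)
  family_dataset(map, sire, progeny)
}

test_that("QC filter applies MAF and call-rate rules", {
  np <- 36
  good <- matrix(rep(c(0L, 1L, 2L), length.out = np), 1)
  prog <- rbind(good, good, good, good,
                matrix(2L, 1, np))                    # SNP5: all allele 1
  prog[1, 1:13] <- NA                                 # SNP1: 23/36 called
  prog2 <- prog
  prog2[1, 13] <- 2L                                  # 24/36 called
  sire <- c(1L, 1L, 1L, 1L, 1L)

  q <- qc_filter(make_toy_data(prog, sire))
  expect_false("s1" %in% q$data$map$snp_id)           # called in only 23
  expect_false("s5" %in% q$data$map$snp_id)           # MAF below 0.10
  expect_identical(q$data$map$snp_id, c("s2", "s3", "s4"))
  expect_identical(q$report$reason[q$report$snp_id == "s1"], "call_rate")
  expect_identical(q$report$reason[q$report$snp_id == "s5"], "maf")

  q2 <- qc_filter(make_toy_data(prog2, sire))
  expect_true("s1" %in% q2$data$map$snp_id)           # 24-of-36 rule

  # zero thresholds: identity
  q0 <- qc_filter(make_toy_data(prog, sire), maf_min = 0, call_rate_min = 0,
                  min_callrate_fraction = 0)
  expect_identical(nrow(q0$data$map), 5L)

  expect_error(qc_filter(make_toy_data(matrix(2L, 2, np), c(1L, 1L))),
               "all 2 SNPs removed")
})

test_that("Mendelian check discards whole SNPs on sire-progeny conflicts", {
  prog <- rbind(c(0L, 1L, 2L),      # conflict: sire hom 2, progeny 0
                c(2L, 1L, 0L),      # sire het: never inconsistent
                c(1L, 1L, 1L))
  sire <- c(2L, 1L, 0L)             # SNP3 sire hom 0: progeny dosage 1 fine?
  # progeny dosage 1 shares allele 2 with a 0-dosage sire: consistent
  m <- mendelian_check(make_toy_data(prog, sire))
  expect_identical(m$data$map$snp_id, c("s2", "s3"))
  expect_identical(m$violations$snp_id, "s1")

  clean <- mendelian_check(make_toy_data(rbind(c(1L, 1L, 2L)), c(1L)))
  expect_identical(nrow(clean$data$map), 1L)
  expect_identical(nrow(clean$violations), 0L)
})

test_that("fragmentation follows the termination rule", {
  sc <- toy_scan(1:6, c_hat = c(0, 0, 0.07, 0, 0))
  fr <- fragmentize(sc, c_threshold = 1e-4)
  expect_identical(nrow(fr), 2L)
  expect_identical(fr$start_idx, c(1L, 4L))
  expect_identical(fr$end_idx, c(3L, 6L))
  expect_equal(fr$terminating_c, c(0.07, NA))

  fr0 <- fragmentize(toy_scan(1:6, rep(0, 5)))
  expect_identical(nrow(fr0), 1L)
  expect_identical(fr0$n_het, 6L)

  frall <- fragmentize(toy_scan(1:6, rep(0.2, 5)))
  expect_identical(nrow(frall), 6L)
  expect_true(all(frall$n_het == 1L))

  # a phase tie splits the fragment with a warning
  expect_warning(
    frt <- fragmentize(toy_scan(1:3, c(0, 0), posterior = c(1, 0.5))),
    "0.5")
  expect_identical(nrow(frt), 2L)
})

test_that("sire fragment phasing chains pairwise phase calls", {
  sc <- toy_scan(1:3, c_hat = c(0, 0), posterior = c(0.99, 0.98))
  hap <- phase_sire_fragment(sc, 1:3)
  expect_identical(hap[1, ], c(1L, 1L, 1L))
  expect_identical(hap[2, ], c(2L, 2L, 2L))

  sc2 <- toy_scan(1:3, c_hat = c(0, 0), posterior = c(0.99, 0.01))
  hap2 <- phase_sire_fragment(sc2, 1:3)
  expect_identical(hap2[1, ], c(1L, 1L, 2L))
  expect_identical(hap2[2, ], c(2L, 2L, 1L))

  # sire-homozygous SNP inside the span appears identically on both strands
  sc3 <- toy_scan(c(1, 3), c_hat = 0, posterior = 0.9)
  hap3 <- phase_sire_fragment(sc3, c(1L, 3L), sire = c(1L, 2L, 1L))
  expect_identical(hap3[, 2], c(1L, 1L))   # dosage 2 = two copies of allele 1
  hap4 <- phase_sire_fragment(sc3, c(1L, 3L), sire = c(1L, 0L, 1L))
  expect_identical(hap4[, 2], c(2L, 2L))
})

test_that("progeny phasing follows the Mendelian deduction rules", {
  # sire haplotypes TMT / tmt over three het SNPs (allele1 = T/M)
  sc <- toy_scan(1:3, c_hat = c(0, 0), posterior = c(1, 1))
  hap <- phase_sire_fragment(sc, 1:3)
  # calf genotypes TT, Mm, Tt -> dosages 2, 1, 1
  prog <- cbind(c(2L, 1L, 1L))
  pp <- phase_progeny(hap, 1:3, prog)
  expect_identical(pp$origin, 1L)
  expect_identical(pp$status, "ok")
  expect_identical(pp$paternal[, 1], c(1L, 1L, 1L))   # T M T
  expect_identical(pp$maternal[, 1], c(1L, 2L, 2L))   # T m t

  # heterozygous at every sire-het SNP: origin unknown
  pp2 <- phase_progeny(hap, 1:3, cbind(c(1L, 1L, 1L)))
  expect_identical(pp2$status, "unknown")
  expect_true(all(is.na(pp2$paternal)))

  # conflicting votes: flagged, not phased by the per-fragment rule
  pp3 <- phase_progeny(hap, 1:3, cbind(c(2L, 1L, 0L)))
  expect_identical(pp3$status, "conflict")
})

test_that("interfragment linkage counts switches and aligns labels", {
  left <- rep(c(1L, 2L), 18)
  right <- left
  right[1:3] <- 3L - right[1:3]
  link <- interfragment_linkage(left, right)
  expect_identical(link$n_informative, 36L)
  expect_identical(link$n_switch, 3L)
  expect_equal(link$c_hat, 3 / 36)
  expect_false(link$flip)

  # majority mismatched: labels flipped, same minimal switch count
  link2 <- interfragment_linkage(left, 3L - right)
  expect_true(link2$flip)
  expect_identical(link2$n_switch, 3L)

  # exact tie flagged unresolved
  link3 <- interfragment_linkage(c(1L, 1L), c(1L, 2L))
  expect_true(link3$unresolved)

  # no informative progeny
  link4 <- interfragment_linkage(c(NA, NA), c(1L, 2L))
  expect_true(is.na(link4$c_hat))
})

test_that("event matching is greedy, one-to-one, and distance-bounded", {
  tr <- data.frame(progeny = "c1", chrom = "1", pos_bp = c(1e6, 5e6))
  m1 <- match_events(tr, tr)
  expect_equal(m1$matched_fraction, 1)
  expect_equal(m1$mean_abs_bp, 0)

  m2 <- match_events(tr, tr[0, ])
  expect_equal(m2$matched_fraction, 0)

  shifted <- transform(tr, pos_bp = pos_bp + 1e6)
  m3 <- match_events(tr, shifted)
  expect_equal(m3$matched_fraction, 1)
  expect_equal(m3$mean_abs_bp, 1e6)

  far <- transform(tr, pos_bp = pos_bp + 4e6)
  m4 <- match_events(tr, far, max_distance = 3e6)
  expect_lt(m4$matched_fraction, 1)

  # one detected event cannot match two true events
  two_true <- data.frame(progeny = "c1", chrom = "1", pos_bp = c(1e6, 1.5e6))
  one_det <- data.frame(progeny = "c1", chrom = "1", pos_bp = 1.2e6)
  m5 <- match_events(two_true, one_det)
  expect_identical(m5$n_matched, 1L)
})

test_that("ROI computation keeps runs above the SNP minimum", {
  n <- 100
  a <- matrix(1L, n, 2)
  ph <- toy_phase(paternal = a, maternal = a)
  roi <- compute_rois(ph, 1, 2, origin = "maternal")
  expect_equal(roi$proportion, 1)

  b <- a
  b[26:100, 2] <- 2L
  ph2 <- toy_phase(paternal = a, maternal = b)
  roi2 <- compute_rois(ph2, 1, 2, origin = "maternal")
  expect_equal(roi2$proportion, 0.25)
  expect_identical(roi2$segments$n_snps, 25L)

  # alternating 19-SNP shared runs: below the minimum, proportion 0
  c2 <- a
  c2[seq(20, 100, by = 20), 2] <- 2L
  ph3 <- toy_phase(paternal = a, maternal = c2)
  roi3 <- compute_rois(ph3, 1, 2, origin = "maternal")
  expect_equal(roi3$proportion, 0)

  # nothing jointly phased
  ph4 <- toy_phase(paternal = a, maternal = matrix(NA_integer_, n, 2))
  roi4 <- compute_rois(ph4, 1, 2, origin = "maternal")
  expect_identical(roi4$status, "no_joint_snps")
})

test_that("genome-wide fragment scan ranks linked fragments first", {
  # 4 fragments x 30 progeny; fragment 4 is a translocated copy of fragment 1
  set.seed(55)
  orig <- matrix(sample(c(1L, 2L), 4 * 30, replace = TRUE), 4, 30)
  orig[4, ] <- orig[1, ]
  frags <- data.frame(fragment = 1:4, chrom = "1",
                      start_bp = c(1, 2, 3, 4) * 1e6,
                      end_bp = c(1, 2, 3, 4) * 1e6 + 5e5)
  ph <- toy_phase(paternal = matrix(1L, 4, 30),
                  maternal = matrix(1L, 4, 30),
                  origin = orig, fragments = frags)
  sc <- genome_wide_fragment_scan(ph, 1)
  expect_identical(sc$fragment[1], 1L)          # query itself first
  expect_equal(sc$c_hat[1], 0)
  expect_identical(sc$fragment[2], 4L)          # donor fragment next
  expect_equal(sc$c_hat[2], 0)
  # unrelated fragments are near c = 0.5
  expect_true(all(sc$c_hat[3:4] > 0.2))
})

test_that("a recombination hotspot pair is detected by the scan", {
  spec <- synthetic_chrom_spec(n_snps = 60, n_progeny = 36,
                               recomb_count_probs = c(1, 0, 0, 0), seed = 61)
  sim <- simulate_phased_chromosome(spec)
  # inject a strand switch after SNP 30 for 10 progeny
  pat_strand <- sim$truth$paternal_strand
  pat_strand[31:60, 1:10] <- 3L - pat_strand[31:60, 1:10]
  hap <- spec$sire_haplotypes
  geno <- sim$genotypes
  for (p in 1:10) {
    pat <- hap[cbind(pat_strand[, p], 1:60)]
    geno[, p] <- (pat == 1L) + (sim$truth$maternal[, p] == 1L)
  }
  data <- family_dataset(transform(spec$snp_map, allele1 = "A", allele2 = "B"),
                         sim$sire_genotype, geno)
  sc <- pairwise_scan(qc_filter(data)$data, "1")
  hot <- which(sc$c_hat > 0.1)
  expect_identical(length(hot), 1L)
  expect_gt(sc$c_hat[hot], 0.15)
  expect_lt(sc$c_hat[hot], 0.45)

  # distance rule: a 60 Mb gap is skipped
  map2 <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                     pos = c(1e6, 2e6, 65e6))
  d2 <- family_dataset(map2, c(1L, 1L, 1L),
                       matrix(1L, 3, 10))
  sc2 <- pairwise_scan(d2, "1")
  expect_true(sc2$skipped[2])
  expect_false(sc2$skipped[1])
})

test_that("end-to-end phasing on a simulated chromosome recovers the truth", {
  spec <- synthetic_chrom_spec(n_snps = 400, n_progeny = 36, seed = 7)
  sim <- simulate_phased_chromosome(spec)
  data <- as_family_dataset(sim)
  ph <- phase_family(data)
  sc <- score_phasing(ph, sim)
  expect_gte(sc$sire_correct, 0.99)
  expect_gte(sc$progeny_correct, 0.99)
  expect_gte(sc$events$matched_fraction, 0.9)

  # phased alleles are consistent with the genotypes wherever both known
  pat <- ph$paternal[[1]]
  mat <- ph$maternal[[1]]
  keep <- match(ph$map$snp_id, spec$snp_map$snp_id)
  dos <- sim$genotypes[keep, ]
  both <- !is.na(pat) & !is.na(mat) & !is.na(dos)
  expect_true(all(((pat == 1L) + (mat == 1L))[both] == dos[both]))

  # informativity: resolved fraction is high under these conditions
  inf <- informativity_report(ph)
  expect_gt(inf$fraction, 0.9)
})

test_that("fragmentation is invariant to chromosome processing order", {
  spec1 <- synthetic_chrom_spec(n_snps = 80, n_progeny = 36, chrom = "1",
                                seed = 71)
  spec2 <- synthetic_chrom_spec(n_snps = 80, n_progeny = 36, chrom = "2",
                                seed = 72)
  sim1 <- simulate_phased_chromosome(spec1)
  sim2 <- simulate_phased_chromosome(spec2)
  d1 <- as_family_dataset(sim1)
  d2 <- as_family_dataset(sim2)
  d1$map$snp_id <- paste0("c1_", d1$map$snp_id)
  d2$map$snp_id <- paste0("c2_", d2$map$snp_id)
  rownames(d1$progeny) <- d1$map$snp_id
  rownames(d2$progeny) <- d2$map$snp_id
  map <- rbind(d1$map, d2$map)
  map_rev <- rbind(d2$map, d1$map)
  both <- family_dataset(map, c(d1$sire, d2$sire),
                         rbind(d1$progeny, d2$progeny))
  both_rev <- family_dataset(map_rev, c(d2$sire, d1$sire),
                             rbind(d2$progeny, d1$progeny))
  f1 <- phase_family(both)$fragments
  f2 <- phase_family(both_rev)$fragments
  for (ch in c("1", "2")) {
    a <- f1[f1$chrom == ch, c("start_idx", "end_idx", "n_het")]
    b <- f2[f2$chrom == ch, c("start_idx", "end_idx", "n_het")]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
})

test_that("paternal ROI between half-sibs is near one half on average", {
  spec <- synthetic_chrom_spec(n_snps = 400, n_progeny = 36, seed = 7)
  sim <- simulate_phased_chromosome(spec)
  ph <- phase_family(as_family_dataset(sim))
  set.seed(77)
  pairs <- t(replicate(40, sample(36, 2)))
  props <- apply(pairs, 1, function(pr)
    compute_rois(ph, pr[1], pr[2], origin = "paternal")$proportion)
  expect_lt(abs(mean(props, na.rm = TRUE) - 0.5), 0.12)
})
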