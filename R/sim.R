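#' Specification of a simulated half-sib family
#'
#' Conditions for one Monte-Carlo half-sib family from a double-heterozygote
#' sire: the sire's linkage phase, the recombination fraction of its
#' meioses, the dam-population LD and allele frequencies, and the family
#' size.
#'
#' @param phase Sire phase, `"coupling"` or `"repulsion"`.
#' @param c Recombination fraction in `[0, 0.5]`.
#' @param delta Maternal LD coefficient.
#' @param f_T,f_M Maternal allele frequencies (default intermediate).
#' @param N Family size (number of half-sib progeny).
#' @param seed RNG seed.
#' @return List of class `"family_sim_spec"`.
#' @export
family_sim_spec <- function(phase = "coupling", c = 0, delta = 0,
                            f_T = 0.5, f_M = 0.5, N = 36L, seed = 1L) {
  phase <- match_phase(phase)
  h <- hap_freqs_from_ld(f_T, f_M, delta)   # validates delta admissibility
  stopifnot(N >= 1, c >= 0, c <= 0.5)
  structure(list(phase = phase, c = c, delta = delta, f_T = f_T, f_M = f_M,
                 h = h, N = as.integer(N), seed = as.integer(seed)),
            class = "family_sim_spec")
}

# Categorical draws by cumulative-probability inversion of uniforms.
draw_classes <- function(probs, n) {
  cp <- cumsum(probs)
  cls <- findInterval(runif(n), cp) + 1L
  pmin(cls, length(probs))
}

#' Simulate offspring genotype counts for one half-sib family
#'
#' Draws `N` offspring from the nine-class genotype distribution of
#' [genotype_class_probs()] by cumulative-probability inversion of uniform
#' deviates.
#'
#' @param spec A [family_sim_spec()].
#' @return A [geno_counts()] vector.
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_sim_spec"))
  set.seed(spec$seed)
  probs <- genotype_class_probs(spec$phase, spec$c, spec$h)
  geno_counts(tabulate(draw_classes(probs, spec$N), 9L))
}

#' Draw a sire from a population of gametes
#'
#' Draws the sire's two haplotypes independently from the maternal-gamete
#' haplotype frequencies and classifies the resulting two-SNP genotype.
#'
#' @param h Population [hap_freqs()].
#' @param seed Optional RNG seed (uses the current RNG stream if `NULL`).
#' @return List with `haplotypes` (two 1-based indices into `TM, Tm, tM,
#'   tm`), `genotype` (e.g. `"TtMm"`), `kind` (`"double_het"`,
#'   `"homo_het"`, `"double_hom"`), and `phase` (`"coupling"`/`"repulsion"`
#'   for a double heterozygote, `NA` otherwise).
#' @export
simulate_sire <- function(h, seed = NULL) {
  h <- if (inherits(h, "hap_freqs")) h else hap_freqs(h)
  if (!is.null(seed)) set.seed(seed)
  hp <- draw_classes(h, 2L)
  n_T <- sum(hp <= 2L)             # haplotypes TM, Tm carry allele T
  n_M <- sum(hp %in% c(1L, 3L))    # haplotypes TM, tM carry allele M
  genotype <- paste0(c("tt", "Tt", "TT")[n_T + 1L],
                     c("mm", "Mm", "MM")[n_M + 1L])
  kind <- sire_geno_kind(genotype)
  phase <- NA_character_
  if (kind == "double_het")
    phase <- if (all(sort(hp) == c(1L, 4L))) "coupling" else "repulsion"
  list(haplotypes = hp, genotype = genotype, kind = kind, phase = phase)
}

#' Simulate a multi-family half-sib design
#'
#' Per family, draws the sire's two haplotypes from the population gamete
#' frequencies implied by `(f_T, f_M, delta)` (so the sire may be a double
#' homozygote, homo-heterozygote, or double heterozygote), then draws the
#' half-sib progeny from the transmission model conditional on the sire's
#' actual haplotypes and the recombination fraction `c`.
#'
#' @param sizes Integer vector of family sizes.
#' @param c Recombination fraction.
#' @param delta,f_T,f_M Dam-population LD and allele frequencies.
#' @param seed RNG seed.
#' @return List of [family_observation()] objects (sire phase NOT disclosed
#'   to the estimator), with the simulated sires attached as attribute
#'   `"truth"`.
#' @export
simulate_multi_family <- function(sizes, c, delta, f_T = 0.5, f_M = 0.5,
                                  seed = 1L) {
  stopifnot(length(sizes) >= 1, all(sizes >= 1))
  h <- hap_freqs_from_ld(f_T, f_M, delta)
  set.seed(seed)
  sires <- vector("list", length(sizes))
  fams <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    sire <- simulate_sire(h)
    probs <- sire_class_probs(sire$haplotypes[1], sire$haplotypes[2], c, h)
    counts <- tabulate(draw_classes(probs, sizes[i]), 9L)
    fams[[i]] <- family_observation(counts, sire$genotype)
    sires[[i]] <- sire
  }
  attr(fams, "truth") <- sires
  fams
}

#' Replicate a simulation + estimation experiment
#'
#' Runs `estimator(simulate(seed_r))` for `n_reps` deterministic
#' per-replicate seeds derived from the master seed, and summarizes each
#' reported parameter by its Monte-Carlo mean and SD (the "mean (SD)" cells
#' of the simulation tables).  Estimator failures (errors or `NA` results)
#' are counted and excluded from the summary.
#'
#' @param simulate Function `seed -> data` (e.g. wrapping
#'   [simulate_family()]).
#' @param estimator Function `data -> named numeric vector` of estimates.
#' @param n_reps Number of replicates.
#' @param seed Master seed; per-replicate seeds are drawn from it once, so
#'   replicates are order-independent.
#' @return List with `mean`, `sd` (named vectors), `n_reps`, `n_fail`, and
#'   the per-replicate `estimates` matrix.
#' @export
replicate_experiment <- function(simulate, estimator, n_reps, seed = 1L) {
  stopifnot(n_reps >= 1)
  seeds <- with_private_seed(seed,
                             sample.int(.Machine$integer.max - 1L, n_reps))
  est <- NULL
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    v <- tryCatch(suppressWarnings(estimator(simulate(seeds[r]))),
                  error = function(e) NULL)
    if (is.null(v)) n_fail <- n_fail + 1L
    if (is.null(est) && !is.null(v))
      est <- matrix(NA_real_, n_reps, length(v),
                    dimnames = list(NULL, names(v)))
    if (!is.null(est) && !is.null(v)) est[r, ] <- v
  }
  if (is.null(est)) stop("estimator failed in every replicate")
  # a parameter can be legitimately NA in single replicates (e.g. c when a
  # replicate draws no double-heterozygote sire); summaries are per column
  m <- colMeans(est, na.rm = TRUE)
  s <- apply(est, 2, stats::sd, na.rm = TRUE)
  s[is.na(s)] <- 0
  list(mean = m, sd = s, n_reps = n_reps, n_fail = n_fail, estimates = est)
}

# ---------------------------------------------------------------------------
# Phased-chromosome simulator
# ---------------------------------------------------------------------------

#' Specification of a simulated phased chromosome
#'
#' Conditions for simulating transmission of one phased chromosome from a
#' sire (heterozygous at every simulated SNP) to `n_progeny` half-sib
#' calves, with maternal chromosomes generated as a first-order Markov chain
#' over consecutive-pair haplotype frequencies.
#'
#' @param snp_map Data frame with columns `chrom` and `pos` (bp, strictly
#'   increasing); optionally `snp_id`.
#' @param sire_haplotypes 2 x n_snps integer matrix of alleles (1 or 2); the
#'   two rows are the sire's phased chromosomes.
#' @param pair_hapfreqs (n_snps - 1) x 4 matrix; row `i` holds the maternal
#'   haplotype frequencies of SNP pair `(i, i+1)` in the order
#'   (allele1-allele1, allele1-allele2, allele2-allele1, allele2-allele2).
#' @param recomb_count_probs Probabilities of 0, 1, 2, 3 crossovers per
#'   paternal meiosis (sums to 1).
#' @param n_progeny Number of half-sib progeny.
#' @param seed RNG seed.
#' @return List of class `"chrom_sim_spec"`.
#' @export
chrom_sim_spec <- function(snp_map, sire_haplotypes, pair_hapfreqs,
                           recomb_count_probs = c(0.511494, 0.398467,
                                                  0.081418, 0.00862),
                           n_progeny = 36L, seed = 1L) {
  n <- nrow(snp_map)
  stopifnot(n >= 2, all(diff(snp_map$pos) > 0),
            is.matrix(sire_haplotypes), nrow(sire_haplotypes) == 2,
            ncol(sire_haplotypes) == n,
            is.matrix(pair_hapfreqs), nrow(pair_hapfreqs) == n - 1,
            ncol(pair_hapfreqs) == 4,
            length(recomb_count_probs) == 4,
            abs(sum(recomb_count_probs) - 1) < 1e-4,
            all(abs(rowSums(pair_hapfreqs) - 1) < 1e-8),
            n_progeny >= 1)
  if (is.null(snp_map$snp_id))
    snp_map$snp_id <- sprintf("snp%05d", seq_len(n))
  structure(list(snp_map = snp_map, sire_haplotypes = sire_haplotypes,
                 pair_hapfreqs = pair_hapfreqs,
                 recomb_count_probs = recomb_count_probs /
                   sum(recomb_count_probs),
                 n_progeny = as.integer(n_progeny),
                 seed = as.integer(seed)),
            class = "chrom_sim_spec")
}

# One maternal chromosome: first SNP from the marginal implied by pair 1,
# each next SNP from the conditional distribution of its pair given the
# previous allele.  Alleles coded 1/2.
sim_maternal_chain <- function(pair_hapfreqs) {
  n <- nrow(pair_hapfreqs) + 1L
  hap <- integer(n)
  p1 <- pair_hapfreqs[1, 1] + pair_hapfreqs[1, 2]
  hap[1] <- if (runif(1) < p1) 1L else 2L
  for (i in seq_len(n - 1L)) {
    prev <- hap[i]
    cells <- if (prev == 1L) pair_hapfreqs[i, 1:2] else pair_hapfreqs[i, 3:4]
    tot <- sum(cells)
    if (tot <= 0)
      stop(sprintf(
        "pair_hapfreqs row %d gives zero probability to conditioning allele %d at SNP %d",
        i, prev, i))
    hap[i + 1L] <- if (runif(1) < cells[1] / tot) 1L else 2L
  }
  hap
}

#' Simulate transmission of a phased chromosome to half-sib progeny
#'
#' The paternal gamete of each progeny draws a crossover count from
#' `recomb_count_probs`, places the crossovers uniformly over the physical
#' map, assembles the two meiotic products from the sire's phased
#' haplotypes, and transmits one of the two at random.  The maternal
#' chromosome is a first-order Markov chain over the consecutive-pair
#' haplotype frequencies.  Genotypes are unordered allele pairs; the full
#' simulation truth is retained for scoring phasing accuracy.
#'
#' @param spec A [chrom_sim_spec()].
#' @return List with `genotypes` (n_snps x n_progeny matrix of allele-1
#'   dosages 0/1/2), `sire_genotype` (allele-1 dosage vector), and `truth`
#'   (list: `paternal_strand` n_snps x n_progeny matrix of transmitted sire
#'   chromosome 1/2, `crossovers` per-progeny bp positions,
#'   `maternal` n_snps x n_progeny allele matrix, and the spec).
#' @export
simulate_phased_chromosome <- function(spec) {
  stopifnot(inherits(spec, "chrom_sim_spec"))
  set.seed(spec$seed)
  n <- nrow(spec$snp_map)
  np <- spec$n_progeny
  pos <- spec$snp_map$pos
  geno <- matrix(0L, n, np)
  pat_strand <- matrix(0L, n, np)
  maternal <- matrix(0L, n, np)
  xovers <- vector("list", np)
  for (p in seq_len(np)) {
    k <- draw_classes(spec$recomb_count_probs, 1L) - 1L
    xp <- sort(runif(k, min = pos[1], max = pos[n]))
    start <- if (runif(1) < 0.5) 1L else 2L
    nflips <- findInterval(pos, xp)           # crossovers left of each SNP
    strand <- 1L + (start - 1L + nflips) %% 2L
    pat <- spec$sire_haplotypes[cbind(strand, seq_len(n))]
    mat <- sim_maternal_chain(spec$pair_hapfreqs)
    pat_strand[, p] <- strand
    maternal[, p] <- mat
    xovers[[p]] <- xp
    geno[, p] <- (pat == 1L) + (mat == 1L)
  }
  rownames(geno) <- spec$snp_map$snp_id
  colnames(geno) <- sprintf("calf%03d", seq_len(np))
  list(genotypes = geno,
       sire_genotype = colSums(spec$sire_haplotypes == 1L),
       truth = list(paternal_strand = pat_strand, crossovers = xovers,
                    maternal = maternal, spec = spec))
}

#' Synthetic chromosome conditions for phasing validation
#'
#' Builds a [chrom_sim_spec()] emulating a livestock SNP-array chromosome:
#' sire heterozygous at every simulated SNP (homozygous SNPs are trivial for
#' phasing and are not simulated), SNP positions uniform over the physical
#' length, maternal allele frequencies uniform on `[0.2, 0.8]`, and
#' consecutive-pair maternal LD with normalized magnitude `|D'|` uniform on
#' `[0.5, 0.95]` (the strong short-range LD typical of dense arrays) and
#' arbitrary sign.  The sire's first chromosome is drawn from the same
#' maternal Markov chain — the sire comes from the same LD population as
#' the dams — and heterozygosity at every retained SNP forces the second
#' chromosome to be its complement.  Crossover-count probabilities default
#' to the genome-wide per-chromosome values
#' `(0.511494, 0.398467, 0.081418, 0.00862)` for 0-3 events.
#'
#' @param n_snps Number of sire-heterozygous SNPs (default 751).
#' @param length_bp Chromosome length in bp (default 1.58e8).
#' @param n_progeny Number of half-sib progeny (default 36).
#' @param chrom Chromosome name.
#' @param seed RNG seed (drives both the map construction and, by default,
#'   the transmission simulation).
#' @inheritParams chrom_sim_spec
#' @return A [chrom_sim_spec()].
#' @export
synthetic_chrom_spec <- function(n_snps = 751L, length_bp = 1.58e8,
                                 n_progeny = 36L, chrom = "1",
                                 recomb_count_probs = c(0.511494, 0.398467,
                                                        0.081418, 0.00862),
                                 seed = 1L) {
  stopifnot(n_snps >= 2)
  set.seed(seed)
  pos <- sort(sample.int(length_bp, n_snps))
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(n_snps)),
                    chrom = chrom, pos = pos)
  p <- runif(n_snps, 0.2, 0.8)   # maternal allele-1 frequencies
  ph <- matrix(0, n_snps - 1L, 4L)
  for (i in seq_len(n_snps - 1L)) {
    b <- delta_bounds(p[i], p[i + 1L])
    d <- runif(1, 0.5, 0.95) * (if (runif(1) < 0.5) b[1] else b[2])
    f <- hap_freqs_from_ld(p[i], p[i + 1L], d)
    ph[i, ] <- as.numeric(f)
  }
  # sire chromosome 1 is a population haplotype; heterozygosity at every
  # SNP makes chromosome 2 its complement
  h1 <- sim_maternal_chain(ph)
  sire <- rbind(h1, 3L - h1)
  rownames(sire) <- NULL
  chrom_sim_spec(map, sire, ph, recomb_count_probs, n_progeny, seed = seed)
}
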