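#' @useDynLib gfps, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom setNames
NULL

#' Offspring genotype classes at a pair of biallelic SNPs
#'
#' Two-SNP offspring genotypes are ordered by the number of copies of the
#' first allele at each locus: `TTMM, TTMm, TTmm, TtMM, TtMm, Ttmm, ttMM,
#' ttMm, ttmm`.  `T/t` denotes the alleles of the first SNP and `M/m` those
#' of the second; all count vectors and probability vectors in the package
#' follow this order.
#'
#' @format Character vector of the nine class labels.
#' @export
GENO_CLASSES <- c("TTMM", "TTMm", "TTmm", "TtMM", "TtMm", "Ttmm",
                  "ttMM", "ttMm", "ttmm")

# Maternal haplotypes (and sire gametes) in index order TM, Tm, tM, tm.
HAP_LABELS <- c("TM", "Tm", "tM", "tm")

# 1-based haplotype indices of the two sire chromosomes per linkage phase.
PHASE_HAPS <- list(coupling = c(1L, 4L), repulsion = c(2L, 3L))

match_phase <- function(phase) {
  match.arg(tolower(phase), c("coupling", "repulsion"))
}

#' Maternal (dam-population) gamete haplotype frequencies
#'
#' Validates and packages the four gamete frequencies `f_TM, f_Tm, f_tM,
#' f_tm` of the dam population.  Allele frequencies and the linkage
#' disequilibrium coefficient are derived quantities:
#' `f_T = f_TM + f_Tm`, `f_M = f_TM + f_tM`, and
#' `delta = f_TM * f_tm - f_Tm * f_tM`.
#'
#' @param f_TM,f_Tm,f_tM,f_tm Haplotype frequencies, each in `[0, 1]`,
#'   summing to 1.  Alternatively `f_TM` may be a length-4 numeric vector.
#' @return A named numeric vector of class `"hap_freqs"`.
#' @examples
#' h <- hap_freqs(0.45, 0.05, 0.05, 0.45)
#' ld_delta(h)        # 0.2
#' allele_freqs(h)    # f_T = f_M = 0.5
#' @export
hap_freqs <- function(f_TM, f_Tm = NULL, f_tM = NULL, f_tm = NULL) {
  f <- if (is.null(f_Tm)) as.numeric(f_TM) else c(f_TM, f_Tm, f_tM, f_tm)
  if (length(f) != 4L || anyNA(f))
    stop("four non-missing haplotype frequencies are required")
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    stop("haplotype frequencies must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1 (got ", format(sum(f)), ")")
  f <- pmin(pmax(f, 0), 1)
  structure(setNames(f, HAP_LABELS), class = "hap_freqs")
}

#' @rdname hap_freqs
#' @param h A `hap_freqs` vector.
#' @export
allele_freqs <- function(h) {
  c(f_T = unname(h[1] + h[2]), f_M = unname(h[1] + h[3]),
    f_t = unname(h[3] + h[4]), f_m = unname(h[2] + h[4]))
}

#' @rdname hap_freqs
#' @export
ld_delta <- function(h) {
  unname(h[1] * h[4] - h[2] * h[3])
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat("Maternal haplotype frequencies:\n")
  print(round(unclass(x), 6))
  af <- allele_freqs(x)
  cat(sprintf("f_T = %.4f, f_M = %.4f, delta = %.4f\n",
              af["f_T"], af["f_M"], ld_delta(x)))
  invisible(x)
}

#' Admissible range of the linkage-disequilibrium coefficient
#'
#' For allele frequencies `f_T`, `f_M`, the LD coefficient `delta` must keep
#' all four gamete frequencies nonnegative:
#' `max(-f_T f_M, -f_t f_m) <= delta <= min(f_T f_m, f_t f_M)`.
#'
#' @param f_T,f_M Allele frequencies in `[0, 1]`.
#' @return Numeric `c(delta_min, delta_max)`.  Bounds collapse to `c(0, 0)`
#'   at monomorphic loci.
#' @export
delta_bounds <- function(f_T, f_M) {
  if (f_T < 0 || f_T > 1 || f_M < 0 || f_M > 1)
    stop("allele frequencies must lie in [0, 1]")
  f_t <- 1 - f_T
  f_m <- 1 - f_M
  c(delta_min = max(-f_T * f_M, -f_t * f_m),
    delta_max = min(f_T * f_m, f_t * f_M))
}

#' Haplotype frequencies from allele frequencies and LD
#'
#' Builds the maternal gamete frequencies from the decomposition
#' `f_TM = delta + f_T f_M`, `f_Tm = -delta + f_T f_m`,
#' `f_tM = -delta + f_t f_M`, `f_tm = delta + f_t f_m`.
#'
#' @param f_T,f_M Allele frequencies in `[0, 1]`.
#' @param delta LD coefficient; must lie within [delta_bounds()].
#' @return A [hap_freqs()] vector.
#' @examples
#' hap_freqs_from_ld(0.5, 0.5, 0.20)  # (0.45, 0.05, 0.05, 0.45)
#' @export
hap_freqs_from_ld <- function(f_T, f_M, delta) {
  b <- delta_bounds(f_T, f_M)
  if (delta < b[1] - 1e-12 || delta > b[2] + 1e-12)
    stop(sprintf("delta = %g outside admissible bounds [%g, %g] for f_T = %g, f_M = %g",
                 delta, b[1], b[2], f_T, f_M))
  f_t <- 1 - f_T
  f_m <- 1 - f_M
  hap_freqs(delta + f_T * f_M, -delta + f_T * f_m,
            -delta + f_t * f_M, delta + f_t * f_m)
}

#' Offspring genotype-class probabilities in a half-sib family
#'
#' Probability of each of the nine two-SNP offspring genotype classes given
#' the sire linkage phase, the recombination fraction `c` in the sire's
#' meioses, and the maternal haplotype frequencies.  A double-heterozygote
#' sire in coupling phase (`TM/tm`) transmits each parental gamete with
#' probability `(1-c)/2` and each recombinant (`Tm`, `tM`) with probability
#' `c/2`; the repulsion phase (`Tm/tM`) swaps the two roles.  The offspring
#' genotype is the unordered union of the sire gamete and a maternal gamete
#' drawn from `h`.
#'
#' @param phase `"coupling"` (`TM/tm`) or `"repulsion"` (`Tm/tM`).
#' @param c Recombination fraction in `[0, 0.5]`.
#' @param h Maternal [hap_freqs()].
#' @return Named numeric vector of nine probabilities summing to 1.
#' @examples
#' genotype_class_probs("coupling", 0, hap_freqs_from_ld(0.5, 0.5, 0.2))
#' @export
genotype_class_probs <- function(phase, c, h) {
  phase <- match_phase(phase)
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c > 0.5)
    stop("recombination fraction c must be a single value in [0, 0.5]")
  h <- if (inherits(h, "hap_freqs")) h else hap_freqs(h)
  haps <- PHASE_HAPS[[phase]]
  sire_class_probs(haps[1], haps[2], c, h)
}

# General transmission model for a sire carrying haplotypes h1/h2 (1-based
# indices into TM, Tm, tM, tm).  Used by genotype_class_probs and by the
# multi-family simulator for non-double-heterozygote sires.
sire_class_probs <- function(h1, h2, c, h) {
  t_of <- c(0L, 0L, 1L, 1L)   # first-locus allele (0 = T) per haplotype index
  m_of <- c(0L, 1L, 0L, 1L)   # second-locus allele (0 = M)
  rec1 <- 2L * t_of[h1] + m_of[h2] + 1L
  rec2 <- 2L * t_of[h2] + m_of[h1] + 1L
  gam <- c(h1, h2, rec1, rec2)
  pg <- c((1 - c) / 2, (1 - c) / 2, c / 2, c / 2)
  probs <- numeric(9)
  for (s in 1:4) {
    g <- gam[s]
    for (m in 1:4) {
      cls <- 3L * (t_of[g] + t_of[m]) + (m_of[g] + m_of[m]) + 1L
      probs[cls] <- probs[cls] + pg[s] * h[m]
    }
  }
  setNames(probs, GENO_CLASSES)
}

#' Offspring genotype counts for one half-sib family
#'
#' Validates a vector of counts of the nine two-SNP offspring genotype
#' classes (order as in [GENO_CLASSES]).
#'
#' @param counts Nonnegative integer vector of length 9.
#' @return Named numeric vector of class `"geno_counts"` with attribute `N`
#'   (the family size).
#' @export
geno_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 9L || anyNA(counts))
    stop("counts must be 9 non-missing values in the order ",
         paste(GENO_CLASSES, collapse = ", "))
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be nonnegative integers")
  structure(setNames(counts, GENO_CLASSES), N = sum(counts),
            class = "geno_counts")
}

#' Multinomial log-likelihood of half-sib genotype counts
#'
#' Computes `sum_j n_j * log(phi_j)` with the convention `0 * log(0) = 0`,
#' where `phi_j` are the class probabilities from [genotype_class_probs()].
#' The multinomial coefficient is omitted: it is constant in the parameters
#' and cancels both in maximization and in the phase posterior.
#'
#' @param counts A [geno_counts()] vector (or coercible).
#' @inheritParams genotype_class_probs
#' @return Log-likelihood (kernel); `-Inf` if some observed class has zero
#'   probability under the parameters.
#' @export
loglik_counts <- function(counts, phase, c, h) {
  counts <- if (inherits(counts, "geno_counts")) counts else geno_counts(counts)
  phi <- genotype_class_probs(phase, c, h)
  pos <- counts > 0
  if (any(pos & phi <= 0)) return(-Inf)
  sum(counts[pos] * log(phi[pos]))
}
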