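# Independent oracles and small generators shared across test files.

# Naive per-class log-likelihood: direct summation over the nine classes,
# written against the closed-form cell sums of the transmission table (not
# the package's enumeration path).
naive_loglik <- function(n, phase, c, f) {
  if (phase == "repulsion") c <- 1 - c
  fTM <- f[1]; fTm <- f[2]; ftM <- f[3]; ftm <- f[4]
  phi <- c(0.5 * (1 - c) * fTM,
           0.5 * (1 - c) * fTm + 0.5 * c * fTM,
           0.5 * c * fTm,
           0.5 * (1 - c) * ftM + 0.5 * c * fTM,
           0.5 * (1 - c) * (ftm + fTM) + 0.5 * c * (ftM + fTm),
           0.5 * (1 - c) * fTm + 0.5 * c * ftm,
           0.5 * c * ftM,
           0.5 * (1 - c) * ftM + 0.5 * c * ftm,
           0.5 * (1 - c) * ftm)
  if (any(n > 0 & phi <= 0)) return(-Inf)
  sum(n[n > 0] * log(phi[n > 0]))
}

# Random admissible (phase, c, h) draw.
random_pair_model <- function() {
  f_T <- runif(1, 0.15, 0.85)
  f_M <- runif(1, 0.15, 0.85)
  b <- delta_bounds(f_T, f_M)
  list(phase = sample(c("coupling", "repulsion"), 1),
       c = runif(1, 0, 0.5),
       h = hap_freqs_from_ld(f_T, f_M, runif(1, b[1], b[2])))
}

# Reorder counts for an allele-label swap at the second SNP (M <-> m):
# flips the sire phase and the sign of delta.
swap_locus2 <- function(n) n[c(3, 2, 1, 6, 5, 4, 9, 8, 7)]

# Tiny hand-built scan object for fragmentation / sire-phasing unit tests:
# het SNPs at the given chromosome-local indices with given c_hat and
# coupling posterior per consecutive pair.
toy_scan <- function(het_idx, c_hat, posterior = rep(1, length(c_hat)),
                     pos = het_idx * 1000) {
  stopifnot(length(c_hat) == length(het_idx) - 1)
  map <- data.frame(snp_id = sprintf("s%d", seq_len(max(het_idx))),
                    chrom = "1", pos = seq_len(max(het_idx)) * 1000)
  out <- data.frame(
    snp1 = sprintf("s%d", het_idx[-length(het_idx)]),
    snp2 = sprintf("s%d", het_idx[-1]),
    idx1 = het_idx[-length(het_idx)], idx2 = het_idx[-1],
    bp1 = map$pos[het_idx[-length(het_idx)]], bp2 = map$pos[het_idx[-1]],
    skipped = FALSE, n = 36L, c_hat = c_hat, delta_hat = 0,
    phase_posterior = posterior, loglik_coupling = 0, loglik_repulsion = 0,
    status = "ok")
  attr(out, "chromosome") <- "1"
  attr(out, "het_idx") <- het_idx
  attr(out, "map") <- map
  class(out) <- c("gfps_scan", class(out))
  out
}

# Minimal gfps_phase skeleton for ROI / fragment-scan unit tests.
toy_phase <- function(paternal, maternal, pos = NULL, origin = NULL,
                      fragments = NULL) {
  np <- ncol(paternal)
  if (is.null(pos)) pos <- seq_len(nrow(paternal)) * 1000
  obj <- list(map = data.frame(snp_id = sprintf("s%d", seq_along(pos)),
                               chrom = "1", pos = pos),
              paternal = list(`1` = paternal),
              maternal = list(`1` = maternal),
              origin = if (!is.null(origin)) list(`1` = origin),
              fragments = fragments,
              progeny_ids = sprintf("calf%03d", seq_len(np)),
              n_progeny = np)
  class(obj) <- "gfps_phase"
  obj
}
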