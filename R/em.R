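#' EM estimation settings
#'
#' @param tol Convergence tolerance: maximum absolute change in
#'   `(f_TM, f_Tm, f_tM, f_tm, c)` between iterations.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @param n_starts Number of seeded random restarts in addition to the
#'   default zero-recombination start (see [em_single_family()]).  The
#'   best-likelihood solution is kept.  The default is 0: the likelihood
#'   can carry an exact `(c, delta)` ridge at intermediate allele
#'   frequencies, and on a ridge the EM limit depends on its start, so the
#'   estimator is *defined* by the default start; restarts are for
#'   verifying attainment of the global maximum (e.g. against
#'   [grid_oracle()]), not for routine estimation.
#' @param seed RNG seed used (only) to draw the restart points; the global
#'   RNG state is left untouched.
#' @return List of class `"em_config"`.
#' @export
em_config <- function(tol = 1e-8, max_iter = 10000L, n_starts = 0L,
                      seed = 11L) {
  stopifnot(tol > 0, max_iter >= 1, n_starts >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "em_config")
}

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# restored on exit.
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# R mirror of the C++ sire-gamete slot table: the four gametes a sire with
# haplotypes (h1, h2) can transmit; slots 3-4 are the recombinants.
sire_gamete_slots <- function(h1, h2) {
  t_of <- c(0L, 0L, 1L, 1L)
  m_of <- c(0L, 1L, 0L, 1L)
  c(h1, h2,
    2L * t_of[h1] + m_of[h2] + 1L,
    2L * t_of[h2] + m_of[h1] + 1L)
}

# Zero-recombination complete-data start for the EM.  Each genotype class is
# allocated to the maternal haplotypes compatible with a *parental* sire
# gamete (the double-ambiguous class splits equally between its two parental
# cells); classes possible only through a recombinant gamete are allocated
# via the recombinant cells and define the starting recombination fraction
# c0 = (obligate-recombinant count) / N.  Lightly smoothed so no frequency
# starts at exactly 0.
zero_rec_start <- function(counts, h1, h2) {
  t_of <- c(0L, 0L, 1L, 1L)
  m_of <- c(0L, 1L, 0L, 1L)
  slots <- sire_gamete_slots(h1, h2)
  cls_of <- function(g, m) 3L * (t_of[g] + t_of[m]) + (m_of[g] + m_of[m]) + 1L
  par_cells <- vector("list", 9)   # maternal haps reachable via parental gametes
  rec_cells <- vector("list", 9)
  for (s in 1:4) {
    for (m in 1:4) {
      cls <- cls_of(slots[s], m)
      if (s <= 2) par_cells[[cls]] <- c(par_cells[[cls]], m)
      else rec_cells[[cls]] <- c(rec_cells[[cls]], m)
    }
  }
  f0 <- numeric(4)
  obligate <- 0
  for (j in 1:9) {
    if (counts[j] == 0) next
    cells <- par_cells[[j]]
    if (is.null(cells)) {
      cells <- rec_cells[[j]]
      obligate <- obligate + counts[j]
    }
    f0[unique(cells)] <- f0[unique(cells)] + counts[j] / length(unique(cells))
  }
  N <- sum(counts)
  list(f = (f0 + 0.25) / (N + 1), c = obligate / N)
}

# Starting points for the EM.  The default is the zero-recombination start
# alone: it defines the estimator (see em_single_family).  With
# cfg$n_starts > 0 the goal is the global maximum instead, so a
# mirrored-phase start is added — if the data arose from the opposite sire
# phase, the likelihood peaks at the c = 0.5 boundary where the two phases
# coincide, a basin random restarts can miss — plus the seeded random
# starts.  Returns a list of list(f, c).
em_starts <- function(counts, cfg, h1, h2) {
  starts <- list(zero_rec_start(counts, h1, h2))
  pair <- sort(c(h1, h2))
  if (cfg$n_starts > 0 &&
      (identical(pair, c(1L, 4L)) || identical(pair, c(2L, 3L)))) {
    mir <- if (identical(pair, c(1L, 4L))) c(2L, 3L) else c(1L, 4L)
    zs <- zero_rec_start(counts, mir[1], mir[2])
    starts <- c(starts, list(list(f = zs$f, c = 0.5)))
  }
  if (cfg$n_starts > 0) {
    rnd <- with_private_seed(cfg$seed, {
      lapply(seq_len(cfg$n_starts), function(i) {
        f <- -log(runif(4))        # Dirichlet(1,1,1,1)
        f <- f / sum(f)
        list(f = 0.9 * f + 0.025, c = runif(1, 0.01, 0.49))
      })
    })
    starts <- c(starts, rnd)
  }
  starts
}

# Is a locus monomorphic among the offspring?  (All counts in the homozygous
# top or bottom band for locus 1, or left/right band for locus 2.)
monomorphic_locus <- function(counts) {
  l1 <- sum(counts[1:3]) == sum(counts) || sum(counts[7:9]) == sum(counts)
  l2 <- sum(counts[c(1, 4, 7)]) == sum(counts) ||
    sum(counts[c(3, 6, 9)]) == sum(counts)
  c(locus1 = l1, locus2 = l2)
}

# Core fit for a given sire haplotype pair (1-based indices into TM,Tm,tM,tm).
em_fit_haps <- function(counts, h1, h2, cfg, constrain_le = FALSE) {
  best <- NULL
  for (s in em_starts(counts, cfg, h1, h2)) {
    f0 <- s$f
    if (constrain_le) {
      fT <- f0[1] + f0[2]
      fM <- f0[1] + f0[3]
      f0 <- c(fT * fM, fT * (1 - fM), (1 - fT) * fM, (1 - fT) * (1 - fM))
    }
    fit <- .em_fit_cpp(as.numeric(counts), h1 - 1L, h2 - 1L, f0, s$c,
                       cfg$tol, cfg$max_iter, TRUE, constrain_le)
    # replace only on a clear improvement: near-ties keep the first
    # (zero-recombination) solution, whose start defines ridge behavior
    if (is.null(best) ||
        (is.finite(fit$loglik) &&
         fit$loglik > best$loglik + 1e-6 * (1 + abs(best$loglik))))
      best <- fit
  }
  best
}

#' Single-family joint EM for recombination fraction and LD
#'
#' Maximizes the half-sib multinomial likelihood over the maternal haplotype
#' frequencies and the recombination fraction `c`, for a double-heterozygote
#' sire of the given linkage phase.  The E-step distributes each ambiguous
#' genotype class over its latent (sire gamete, maternal haplotype) cells;
#' the M-step re-estimates the four haplotype frequencies and `c` as
#' expected-count proportions, with `c` clamped to `[0, 0.5]`.  The observed
#' -data log-likelihood is nondecreasing across iterations.
#'
#' The default start is the zero-recombination complete-data estimate:
#' haplotype frequencies from allocating each genotype class to the maternal
#' gametes compatible with a parental sire gamete, and `c` started at the
#' observed fraction of obligate-recombinant offspring.  When no offspring
#' requires a recombinant gamete the start has `c = 0`, which is a fixed
#' point of the EM map, so fully linked data yield `c_hat` exactly 0.  This
#' matters because `c` and `delta` are exactly confounded along a likelihood
#' ridge at intermediate allele frequencies: the EM limit on a ridge depends
#' on the start, and the zero-recombination start defines the estimator that
#' resolves ridge ambiguity in favor of the no-recombination interpretation
#' — the behavior phasing requires.
#'
#' @param counts A [geno_counts()] vector (or 9 raw counts).
#' @param phase Sire phase, `"coupling"` or `"repulsion"`.
#' @param cfg An [em_config()].
#' @return List with `c_hat`, `h_hat` ([hap_freqs()]), `delta_hat`,
#'   `loglik`, `n_iter`, `converged`, `monotone`, `status`.
#' @examples
#' em_single_family(c(180, 20, 0, 20, 360, 20, 0, 20, 180), "coupling")
#' @export
em_single_family <- function(counts, phase, cfg = em_config()) {
  counts <- if (inherits(counts, "geno_counts")) counts else geno_counts(counts)
  phase <- match_phase(phase)
  if (sum(counts) == 0)
    return(list(c_hat = NA_real_, h_hat = NULL, delta_hat = NA_real_,
                loglik = 0, n_iter = 0L, converged = TRUE, monotone = TRUE,
                status = "empty"))
  mono <- monomorphic_locus(counts)
  haps <- PHASE_HAPS[[phase]]
  fit <- em_fit_haps(counts, haps[1], haps[2], cfg)
  h <- hap_freqs(fit$f / sum(fit$f))
  list(c_hat = fit$c, h_hat = h, delta_hat = ld_delta(h),
       loglik = fit$loglik, n_iter = fit$n_iter, converged = fit$converged,
       monotone = fit$monotone,
       status = if (any(mono)) "monomorphic" else "ok")
}

#' LE-constrained recombination-fraction estimator
#'
#' The classical single-parent linkage estimator that ignores maternal LD:
#' the maternal haplotype frequencies are constrained to allele-frequency
#' products (`delta` forced to 0) and the likelihood is maximized over `c`.
#' It is biased whenever true LD is nonzero and serves as a comparison
#' baseline for the joint estimator.
#'
#' With `allele_freqs = "plugin"` (default) the maternal allele frequencies
#' are first estimated from the offspring in which the maternal allele is
#' directly observed — the homozygotes at each sire-heterozygous SNP, whose
#' second allele must be maternal — and the likelihood is then maximized
#' over `c` alone.  With `allele_freqs = "ml"` the allele frequencies are
#' profiled out by the LE-constrained EM instead.
#'
#' @inheritParams em_single_family
#' @param allele_freqs `"plugin"` (moment estimates, then 1-D maximization
#'   in `c`) or `"ml"` (joint LE-constrained EM).
#' @return List with `c_hat`, `f_T_hat`, `f_M_hat`, `loglik`, `converged`.
#' @export
em_le_constrained <- function(counts, phase, cfg = em_config(),
                              allele_freqs = c("plugin", "ml")) {
  counts <- if (inherits(counts, "geno_counts")) counts else geno_counts(counts)
  phase <- match_phase(phase)
  allele_freqs <- match.arg(allele_freqs)
  if (sum(counts) == 0)
    return(list(c_hat = NA_real_, f_T_hat = NA_real_, f_M_hat = NA_real_,
                loglik = 0, n_iter = 0L, converged = TRUE, monotone = TRUE))
  if (allele_freqs == "ml") {
    haps <- PHASE_HAPS[[phase]]
    fit <- em_fit_haps(counts, haps[1], haps[2], cfg, constrain_le = TRUE)
    return(list(c_hat = fit$c, f_T_hat = fit$f[1] + fit$f[2],
                f_M_hat = fit$f[1] + fit$f[3], loglik = fit$loglik,
                n_iter = fit$n_iter, converged = fit$converged,
                monotone = fit$monotone))
  }
  n <- as.numeric(counts)
  n_TT <- sum(n[1:3])
  n_tt <- sum(n[7:9])
  n_MM <- sum(n[c(1, 4, 7)])
  n_mm <- sum(n[c(3, 6, 9)])
  f_T <- if (n_TT + n_tt > 0) n_TT / (n_TT + n_tt) else 0.5
  f_M <- if (n_MM + n_mm > 0) n_MM / (n_MM + n_mm) else 0.5
  f_T <- min(max(f_T, 0.02), 0.98)
  f_M <- min(max(f_M, 0.02), 0.98)
  h <- hap_freqs_from_ld(f_T, f_M, 0)
  obj <- function(cc) loglik_counts(counts, phase, cc, h)
  opt <- stats::optimize(obj, c(0, 0.5), maximum = TRUE, tol = 1e-7)
  # the boundary c = 0 is not an interior point optimize() can return; take
  # whichever of the optimizer's point and the boundaries is best
  cand <- c(0, opt$maximum, 0.5)
  ll <- vapply(cand, obj, numeric(1))
  best <- which.max(ll)
  list(c_hat = cand[best], f_T_hat = f_T, f_M_hat = f_M, loglik = ll[best],
       converged = TRUE)
}

log_sum_exp <- function(a, b) {
  if (a == -Inf && b == -Inf) return(-Inf)
  m <- max(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Sire linkage-phase posterior from half-sib genotype counts
#'
#' Fits the joint EM independently under each sire phase and forms the
#' posterior probability of the coupling phase `TM/tm` from the two
#' maximized (profile) likelihoods, `L_c / (L_c + L_r)`, computed on the log
#' scale.  The reported parameter estimates are those of the
#' higher-likelihood phase.
#'
#' @inheritParams em_single_family
#' @return Object of class `"joint_estimate"`: a list with `c_hat`, `h_hat`,
#'   `delta_hat`, `loglik_coupling`, `loglik_repulsion`, `phase_posterior`
#'   (probability of `TM/tm`), `phase` (the selected phase), `n_iter`,
#'   `converged`, `status`.
#' @examples
#' est <- phase_probability(c(180, 20, 0, 20, 360, 20, 0, 20, 180))
#' est$phase_posterior   # ~1: only coupling explains these counts
#' @export
phase_probability <- function(counts, cfg = em_config()) {
  counts <- if (inherits(counts, "geno_counts")) counts else geno_counts(counts)
  if (sum(counts) == 0) {
    out <- list(c_hat = NA_real_, h_hat = NULL, delta_hat = NA_real_,
                loglik_coupling = 0, loglik_repulsion = 0,
                phase_posterior = 0.5, phase = NA_character_, n_iter = 0L,
                converged = TRUE, status = "empty")
    class(out) <- "joint_estimate"
    return(out)
  }
  fc <- em_single_family(counts, "coupling", cfg)
  fr <- em_single_family(counts, "repulsion", cfg)
  if (fc$loglik == -Inf && fr$loglik == -Inf)
    stop("counts impossible under both phases")
  denom <- log_sum_exp(fc$loglik, fr$loglik)
  post <- exp(fc$loglik - denom)
  best <- if (fc$loglik >= fr$loglik) fc else fr
  out <- list(c_hat = best$c_hat, h_hat = best$h_hat,
              delta_hat = best$delta_hat,
              loglik_coupling = fc$loglik, loglik_repulsion = fr$loglik,
              phase_posterior = post,
              phase = if (fc$loglik >= fr$loglik) "coupling" else "repulsion",
              n_iter = fc$n_iter + fr$n_iter,
              converged = fc$converged && fr$converged,
              status = best$status)
  class(out) <- "joint_estimate"
  out
}

#' @export
print.joint_estimate <- function(x, ...) {
  cat("Joint estimate for one SNP pair\n")
  cat(sprintf("  c_hat = %.4f, delta_hat = %.4f  (phase %s, P(TM/tm) = %.4f)\n",
              x$c_hat, x$delta_hat, x$phase, x$phase_posterior))
  if (!is.null(x$h_hat))
    cat("  haplotype frequencies:",
        paste(sprintf("%s=%.4f", names(x$h_hat), x$h_hat), collapse = ", "),
        "\n")
  cat(sprintf("  loglik: coupling %.4f, repulsion %.4f; status: %s\n",
              x$loglik_coupling, x$loglik_repulsion, x$status))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Multi-family pooled EM
# ---------------------------------------------------------------------------

SIRE_GENOTYPES <- c("TTMM", "TTMm", "TTmm", "TtMM", "TtMm", "Ttmm",
                    "ttMM", "ttMm", "ttmm")

# Haplotype pair(s) compatible with a two-SNP sire genotype.  For the double
# heterozygote the phase is unresolved and both orderings are returned.
sire_geno_haps <- function(genotype) {
  switch(genotype,
         TTMM = list(c(1L, 1L)), TTMm = list(c(1L, 2L)),
         TTmm = list(c(2L, 2L)), TtMM = list(c(1L, 3L)),
         TtMm = list(c(1L, 4L), c(2L, 3L)),   # coupling, repulsion
         Ttmm = list(c(2L, 4L)), ttMM = list(c(3L, 3L)),
         ttMm = list(c(3L, 4L)), ttmm = list(c(4L, 4L)),
         stop("unknown sire genotype: ", genotype))
}

sire_geno_kind <- function(genotype) {
  het1 <- substr(genotype, 1, 2) == "Tt"
  het2 <- substr(genotype, 3, 4) == "Mm"
  if (het1 && het2) "double_het"
  else if (het1 || het2) "homo_het"
  else "double_hom"
}

#' One family's data for multi-family estimation
#'
#' @param counts [geno_counts()] of the nine offspring classes.
#' @param sire_genotype Two-SNP sire genotype string, e.g. `"TtMm"`,
#'   `"TTMm"`, `"ttmm"`.
#' @param known_phase Optional `"coupling"`/`"repulsion"` if the
#'   double-heterozygote sire's phase is known; normally `NULL` (phase is a
#'   latent variable handled as a two-component mixture).
#' @return List of class `"family_observation"`.
#' @export
family_observation <- function(counts, sire_genotype, known_phase = NULL) {
  counts <- if (inherits(counts, "geno_counts")) counts else geno_counts(counts)
  sire_genotype <- match.arg(sire_genotype, SIRE_GENOTYPES)
  if (!is.null(known_phase)) known_phase <- match_phase(known_phase)
  structure(list(counts = counts, sire_genotype = sire_genotype,
                 known_phase = known_phase,
                 kind = sire_geno_kind(sire_genotype)),
            class = "family_observation")
}

#' Pooled EM over multiple half-sib families
#'
#' Estimates common maternal haplotype frequencies (hence `delta`) and a
#' common recombination fraction from several half-sib families whose sires
#' may be double homozygotes, homo-heterozygotes, or double heterozygotes.
#' Each iteration runs a per-family E-step at the current pooled parameters
#' and pools the per-family expected-count estimates by family-size-weighted
#' averages.  Sires that are not heterozygous at both SNPs contribute to the
#' haplotype frequencies but carry no information on `c` (their recombinant
#' gametes are indistinguishable from parentals), so `c` is pooled over
#' double-heterozygote families only.  An unknown double-heterozygote phase
#' is treated as a latent variable: the two phase components are weighted by
#' their per-iteration posterior.
#'
#' @param families List of [family_observation()] objects.
#' @param cfg An [em_config()].
#' @return Object of class `"joint_estimate"` with pooled `c_hat`, `h_hat`,
#'   `delta_hat`, total `loglik`, per-family `phase_posterior`s, `n_iter`,
#'   `converged`.  `c_hat` is `NA` (with a warning) if no family has a
#'   double-heterozygote sire.
#' @export
em_multi_family <- function(families, cfg = em_config()) {
  stopifnot(length(families) >= 1)
  families <- lapply(families, function(fam) {
    if (!inherits(fam, "family_observation"))
      stop("families must be family_observation objects")
    fam
  })
  Ns <- vapply(families, function(fam) sum(fam$counts), numeric(1))
  if (sum(Ns) == 0) stop("all families are empty")
  dh <- vapply(families, function(fam) fam$kind == "double_het", logical(1))
  c_estimable <- any(dh)
  if (!c_estimable)
    warning("no double-heterozygote sire: recombination fraction not estimable")

  pooled_counts <- Reduce(`+`, lapply(families, function(fam)
    as.numeric(fam$counts)))
  run <- function(f0, c0) {
    f <- f0
    cc <- c0
    post <- rep(NA_real_, length(families))
    total_ll <- -Inf
    converged <- FALSE
    iter <- 0L
    monotone <- TRUE
    ll_prev <- -Inf
    while (iter < cfg$max_iter) {
      iter <- iter + 1L
      f_acc <- numeric(4)
      c_num <- 0
      c_den <- 0
      total_ll <- 0
      for (i in seq_along(families)) {
        fam <- families[[i]]
        n <- as.numeric(fam$counts)
        hp <- sire_geno_haps(fam$sire_genotype)
        if (fam$kind == "double_het" && is.null(fam$known_phase)) {
          ec <- .em_estep_cpp(n, hp[[1]][1] - 1L, hp[[1]][2] - 1L, f, cc)
          er <- .em_estep_cpp(n, hp[[2]][1] - 1L, hp[[2]][2] - 1L, f, cc)
          lse <- log_sum_exp(ec$loglik, er$loglik)
          w <- if (is.finite(lse)) exp(ec$loglik - lse) else 0.5
          post[i] <- w
          f_i <- w * ec$f_i + (1 - w) * er$f_i
          c_i <- w * ec$c_i + (1 - w) * er$c_i
          total_ll <- total_ll + lse - log(2)
        } else {
          pair <- if (fam$kind == "double_het")
            sire_geno_haps(fam$sire_genotype)[[
              if (fam$known_phase == "coupling") 1L else 2L]]
          else hp[[1]]
          e1 <- .em_estep_cpp(n, pair[1] - 1L, pair[2] - 1L, f, cc)
          f_i <- e1$f_i
          c_i <- e1$c_i
          if (fam$kind == "double_het") post[i] <-
              if (fam$known_phase == "coupling") 1 else 0
          total_ll <- total_ll + e1$loglik
        }
        f_acc <- f_acc + sum(fam$counts) * f_i
        if (dh[i]) {
          c_num <- c_num + sum(fam$counts) * c_i
          c_den <- c_den + sum(fam$counts)
        }
      }
      if (total_ll < ll_prev - 1e-8 * (1 + abs(ll_prev))) monotone <- FALSE
      ll_prev <- total_ll
      f_new <- f_acc / sum(Ns)
      f_new <- f_new / sum(f_new)
      c_new <- if (c_den > 0) min(max(c_num / c_den, 0), 0.5) else cc
      dmax <- max(abs(f_new - f), if (c_estimable) abs(c_new - cc) else 0)
      f <- f_new
      cc <- c_new
      if (dmax < cfg$tol) { converged <- TRUE; break }
    }
    list(f = f, c = cc, loglik = total_ll, post = post, n_iter = iter,
         converged = converged, monotone = monotone)
  }

  # Pooled start: uniform haplotype frequencies, c = 0.25.  Sire phases are
  # latent, so no per-family zero-recombination allocation applies; the
  # pooled likelihood mixes sire genotypes and is well-behaved from a
  # neutral interior start.
  starts <- list(list(f = rep(0.25, 4), c = 0.25))
  if (cfg$n_starts > 0)
    starts <- c(starts, with_private_seed(cfg$seed, {
      lapply(seq_len(cfg$n_starts), function(i) {
        f <- -log(runif(4))
        f <- f / sum(f)
        list(f = 0.9 * f + 0.025, c = runif(1, 0.01, 0.49))
      })
    }))
  best <- NULL
  for (s in starts) {
    fit <- run(s$f, s$c)
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik))
      best <- fit
  }
  h <- hap_freqs(best$f / sum(best$f))
  out <- list(c_hat = if (c_estimable) best$c else NA_real_, h_hat = h,
              delta_hat = ld_delta(h), loglik = best$loglik,
              loglik_coupling = NA_real_, loglik_repulsion = NA_real_,
              phase_posterior = best$post, phase = NA_character_,
              n_iter = best$n_iter, converged = best$converged,
              monotone = best$monotone, status = "ok")
  class(out) <- "joint_estimate"
  out
}

# ---------------------------------------------------------------------------
# Brute-force oracle and expected-count likelihood surfaces
# ---------------------------------------------------------------------------

#' Brute-force grid maximization of the pair likelihood
#'
#' Exhaustively maximizes the half-sib multinomial log-likelihood over a
#' lattice in `(c, f_T, f_M, delta)` (with `delta` restricted to its
#' admissible bounds at each frequency pair), then repeatedly shrinks the
#' lattice around the incumbent with a tenfold finer step.  Serves as an
#' independent verifier for the EM estimators: it evaluates the likelihood
#' through closed-form class-probability expressions, not through the EM's
#' latent-cell machinery.
#'
#' @inheritParams em_single_family
#' @param grid_step Initial lattice step (default 0.02).
#' @param refine Number of tenfold refinement passes (default 3).
#' @return List with `c`, `f_T`, `f_M`, `delta`, `loglik`.
#' @export
grid_oracle <- function(counts, phase, grid_step = 0.02, refine = 3L) {
  counts <- if (inherits(counts, "geno_counts")) counts else geno_counts(counts)
  phase <- match_phase(phase)
  .grid_search_cpp(as.numeric(counts), phase == "coupling", grid_step,
                   as.integer(refine))
}

#' Expected genotype-class counts
#'
#' @inheritParams genotype_class_probs
#' @param N Family size used to scale the probabilities.
#' @return Named numeric vector of expected counts (possibly fractional).
#' @export
expected_counts <- function(phase, c, h, N = 1) {
  N * genotype_class_probs(phase, c, h)
}

#' Expected-count log-likelihood surface over (c, delta)
#'
#' Replaces the observed counts by their expected values at the true
#' parameters (the infinite-sample limit, up to scale) and evaluates the
#' log-likelihood on a `(c, delta)` lattice with the allele frequencies held
#' at their true values.  The lattice argmax shows whether `c` and `delta`
#' are separable: they are when either true value is 0, and confounded
#' (biased argmax) when both are nonzero.
#'
#' @param true_c,true_delta True recombination fraction and LD.
#' @param f_T,f_M Allele frequencies (held fixed; default intermediate).
#' @param grid_step Lattice step for both axes (default 0.05).
#' @param N Scale for the expected counts (surface shape is N-invariant).
#' @param phase Sire phase generating the expected counts.
#' @return List with `c_grid`, `delta_grid`, `loglik` (matrix, rows = c),
#'   and `argmax = c(c, delta)`.
#' @examples
#' s <- expected_loglik_surface(0.20, 0.20)
#' s$argmax   # confounded: maximum away from the truth
#' @export
expected_loglik_surface <- function(true_c, true_delta, f_T = 0.5, f_M = 0.5,
                                    grid_step = 0.05, N = 1,
                                    phase = "coupling") {
  phase <- match_phase(phase)
  h_true <- hap_freqs_from_ld(f_T, f_M, true_delta)
  en <- expected_counts(phase, true_c, h_true, N)
  c_grid <- seq(0, 0.5, by = grid_step)
  b <- delta_bounds(f_T, f_M)
  ks <- seq(ceiling((b[1] - 1e-12) / grid_step),
            floor((b[2] + 1e-12) / grid_step))
  delta_grid <- sort(unique(round(c(b[1], ks * grid_step, b[2]), 12)))
  ll <- matrix(-Inf, length(c_grid), length(delta_grid),
               dimnames = list(format(c_grid), format(delta_grid)))
  pos <- en > 0
  for (i in seq_along(c_grid)) {
    for (j in seq_along(delta_grid)) {
      h <- hap_freqs_from_ld(f_T, f_M, delta_grid[j])
      phi <- genotype_class_probs(phase, c_grid[i], h)
      ll[i, j] <- if (any(pos & phi <= 0)) -Inf
        else sum(en[pos] * log(phi[pos]))
    }
  }
  # Exact expected counts can have tied global maxima (e.g. truth (c=0,
  # delta=0.2) is mimicked exactly by (c=0.1, delta at its upper bound)).
  # Ties are broken toward the smaller c, then the smaller |delta|: the
  # no-recombination solution is the one relevant for phasing.
  top <- which(ll >= max(ll) - 1e-9, arr.ind = TRUE)
  ord <- order(c_grid[top[, 1]], abs(delta_grid[top[, 2]]))
  amax <- top[ord[1], ]
  list(c_grid = c_grid, delta_grid = delta_grid, loglik = ll,
       argmax = c(c = c_grid[amax[1]], delta = delta_grid[amax[2]]))
}
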