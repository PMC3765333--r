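#' Half-sib family SNP dataset
#'
#' Container for one genotyped half-sib family: a SNP map, the sire's
#' genotypes, and the progeny genotype matrix.  Genotypes are stored as
#' allele-1 dosages (0, 1, 2, or `NA` for no-calls), with the map recording
#' which physical alleles the codes refer to.
#'
#' @param map Data frame with columns `snp_id`, `chrom`, `pos` (bp,
#'   strictly increasing within chromosome) and optionally `allele1`,
#'   `allele2` (default `"A"`, `"B"`).
#' @param sire Integer vector of sire allele-1 dosages, one per SNP.
#' @param progeny Numeric matrix, SNPs x progeny, of allele-1 dosages.
#' @return List of class `"family_dataset"`.
#' @export
family_dataset <- function(map, sire, progeny) {
  stopifnot(is.data.frame(map),
            all(c("snp_id", "chrom", "pos") %in% names(map)))
  if (is.null(map$allele1)) map$allele1 <- "A"
  if (is.null(map$allele2)) map$allele2 <- "B"
  n <- nrow(map)
  progeny <- as.matrix(progeny)
  stopifnot(length(sire) == n, nrow(progeny) == n)
  if (anyDuplicated(map$snp_id)) stop("duplicated SNP ids in map")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  bad <- function(x) any(!is.na(x) & !(x %in% 0:2))
  if (bad(sire) || bad(progeny)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(colnames(progeny)))
    colnames(progeny) <- sprintf("calf%03d", seq_len(ncol(progeny)))
  rownames(progeny) <- map$snp_id
  structure(list(map = map, sire = as.integer(sire), progeny = progeny),
            class = "family_dataset")
}

#' @export
print.family_dataset <- function(x, ...) {
  cat(sprintf("Half-sib family dataset: %d SNPs on %d chromosome(s), %d progeny\n",
              nrow(x$map), length(unique(x$map$chrom)), ncol(x$progeny)))
  cat(sprintf("  sire heterozygous at %d SNPs\n",
              sum(x$sire == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Convert a simulated phased chromosome to a family dataset
#'
#' @param sim Output of [simulate_phased_chromosome()].
#' @return A [family_dataset()].
#' @export
as_family_dataset <- function(sim) {
  map <- sim$truth$spec$snp_map
  map$allele1 <- "A"
  map$allele2 <- "B"
  family_dataset(map, sim$sire_genotype, sim$genotypes)
}

subset_snps <- function(data, keep) {
  family_dataset(data$map[keep, , drop = FALSE], data$sire[keep],
                 data$progeny[keep, , drop = FALSE])
}

#' Quality-control filter for SNPs
#'
#' Removes SNPs with a missing sire genotype, an insufficient progeny call
#' rate, or a low minor allele frequency.  A SNP passes the call-rate rule
#' if its call fraction is at least `call_rate_min` *or* it is called in at
#' least `ceiling(min_callrate_fraction * n_progeny)` progeny (the 24-of-36
#' rule generalized).  MAF is computed over the called alleles of sire plus
#' progeny.
#'
#' @param data A [family_dataset()].
#' @param maf_min Minimum minor allele frequency (default 0.10).
#' @param call_rate_min Minimum per-SNP call fraction (default 0.80).
#' @param min_callrate_fraction Alternative minimum fraction of progeny with
#'   calls (default 2/3).
#' @return List with `data` (filtered dataset) and `report` (per-SNP data
#'   frame with the computed statistics and removal reason).
#' @export
qc_filter <- function(data, maf_min = 0.10, call_rate_min = 0.80,
                      min_callrate_fraction = 2 / 3) {
  stopifnot(inherits(data, "family_dataset"))
  np <- ncol(data$progeny)
  n_called <- rowSums(!is.na(data$progeny))
  min_called <- ceiling(min_callrate_fraction * np)
  ok_call <- (n_called / np >= call_rate_min) | (n_called >= min_called)
  a1 <- rowSums(data$progeny, na.rm = TRUE) +
    ifelse(is.na(data$sire), 0, data$sire)
  tot <- 2 * (n_called + !is.na(data$sire))
  p <- ifelse(tot > 0, a1 / tot, NA_real_)
  maf <- pmin(p, 1 - p)
  ok_maf <- !is.na(maf) & maf >= maf_min
  ok_sire <- !is.na(data$sire)
  keep <- ok_call & ok_maf & ok_sire
  reason <- rep("", nrow(data$map))
  reason[!ok_sire] <- "sire_missing"
  reason[ok_sire & !ok_call] <- "call_rate"
  reason[ok_sire & ok_call & !ok_maf] <- "maf"
  report <- data.frame(snp_id = data$map$snp_id, n_called = n_called,
                       call_rate = n_called / np, maf = maf, keep = keep,
                       reason = reason)
  if (!any(keep))
    stop(sprintf(
      "all %d SNPs removed by QC (sire missing: %d, call rate: %d, MAF: %d)",
      nrow(report), sum(!ok_sire), sum(ok_sire & !ok_call),
      sum(ok_sire & ok_call & !ok_maf)))
  list(data = subset_snps(data, keep), report = report)
}

#' Mendelian-consistency check against the sire
#'
#' A progeny genotype is inconsistent when it shares no allele with the
#' sire (opposite homozygotes).  Any SNP with at least one inconsistent
#' progeny is discarded for the whole family — such conflicts flag
#' genotyping errors, and a single bad call poisons the transmission counts
#' of the entire SNP.
#'
#' @param data A [family_dataset()].
#' @return List with `data` (filtered) and `violations` (data frame of
#'   `snp_id`, `progeny` pairs).
#' @export
mendelian_check <- function(data) {
  stopifnot(inherits(data, "family_dataset"))
  if (anyNA(data$sire)) stop("sire genotype must be called at every SNP")
  viol <- (data$sire == 2L & data$progeny == 0) |
    (data$sire == 0L & data$progeny == 2)
  viol[is.na(viol)] <- FALSE
  idx <- which(viol, arr.ind = TRUE)
  violations <- data.frame(
    snp_id = data$map$snp_id[idx[, 1]],
    progeny = colnames(data$progeny)[idx[, 2]])
  keep <- rowSums(viol) == 0
  list(data = subset_snps(data, keep), violations = violations)
}

# Genotype-class counts for a pair of sire-heterozygous SNPs: allele 1 of
# each SNP plays T / M.  Progeny missing either call are excluded.
pair_counts <- function(dosA, dosB) {
  ok <- !is.na(dosA) & !is.na(dosB)
  cls <- 3L * (2L - dosA[ok]) + (2L - dosB[ok]) + 1L
  geno_counts(tabulate(cls, 9L))
}

#' Pairwise joint-estimation scan along a chromosome
#'
#' Walks the consecutive pairs of sire-heterozygous SNPs on one chromosome
#' (the second SNP of each pair is the first of the next) and jointly
#' estimates the recombination fraction, maternal LD and sire phase for
#' each pair with [phase_probability()].  Sire-homozygous SNPs carry no
#' phase information (both sire chromosomes have the same allele) and are
#' passed over; pairs farther apart than `max_pair_bp` are skipped and
#' force a fragment boundary.
#'
#' @param data A QC'd [family_dataset()].
#' @param chromosome Chromosome to scan.
#' @param max_pair_bp Maximum pair span in bp (default 50 Mb).
#' @param cfg An [em_config()].
#' @return Data frame of class `"gfps_scan"`, one row per consecutive
#'   sire-het pair: SNP ids and chromosome-local indices, bp positions,
#'   `skipped`, `n` (informative progeny), `c_hat`, `delta_hat`,
#'   `phase_posterior` (probability of coupling, i.e. allele-1 alleles on
#'   the same chromosome), `loglik_coupling`, `loglik_repulsion`, `status`.
#'   The chromosome-local index of every sire-het SNP is kept in attribute
#'   `het_idx`; the chromosome map in attribute `map`.
#' @export
pairwise_scan <- function(data, chromosome, max_pair_bp = 50e6,
                          cfg = em_config()) {
  stopifnot(inherits(data, "family_dataset"))
  sel <- which(data$map$chrom == chromosome)
  if (length(sel) == 0) stop("no SNPs on chromosome ", chromosome)
  map <- data$map[sel, , drop = FALSE]
  sire <- data$sire[sel]
  prog <- data$progeny[sel, , drop = FALSE]
  het <- which(sire == 1L)
  cols <- c("snp1", "snp2", "idx1", "idx2", "bp1", "bp2", "skipped", "n",
            "c_hat", "delta_hat", "phase_posterior", "loglik_coupling",
            "loglik_repulsion", "status")
  if (length(het) < 2) {
    warning("chromosome ", chromosome, " has fewer than 2 sire-het SNPs")
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    rows <- vector("list", length(het) - 1L)
    for (k in seq_len(length(het) - 1L)) {
      i <- het[k]
      j <- het[k + 1L]
      gap <- map$pos[j] - map$pos[i]
      if (gap > max_pair_bp) {
        rows[[k]] <- data.frame(
          snp1 = map$snp_id[i], snp2 = map$snp_id[j], idx1 = i, idx2 = j,
          bp1 = map$pos[i], bp2 = map$pos[j], skipped = TRUE, n = NA_integer_,
          c_hat = NA_real_, delta_hat = NA_real_, phase_posterior = NA_real_,
          loglik_coupling = NA_real_, loglik_repulsion = NA_real_,
          status = "skipped_distance")
        next
      }
      cnt <- pair_counts(prog[i, ], prog[j, ])
      est <- phase_probability(cnt, cfg)
      rows[[k]] <- data.frame(
        snp1 = map$snp_id[i], snp2 = map$snp_id[j], idx1 = i, idx2 = j,
        bp1 = map$pos[i], bp2 = map$pos[j], skipped = FALSE,
        n = sum(cnt), c_hat = est$c_hat, delta_hat = est$delta_hat,
        phase_posterior = est$phase_posterior,
        loglik_coupling = est$loglik_coupling,
        loglik_repulsion = est$loglik_repulsion, status = est$status)
    }
    out <- do.call(rbind, rows)
  }
  attr(out, "chromosome") <- chromosome
  attr(out, "het_idx") <- het
  attr(out, "map") <- map
  class(out) <- c("gfps_scan", class(out))
  out
}

#' Fragmentation of a scanned chromosome
#'
#' Splits the chromosome into fragments (haplotype blocks): maximal runs of
#' consecutive sire-het SNPs whose pairwise recombination-fraction
#' estimates are all `<= c_threshold`.  A pair with `c_hat > c_threshold`
#' (a recombination event or a genotyping/assembly error), a pair skipped
#' for distance, or a pair whose phase call does not reach
#' `min_phase_posterior` terminates the current fragment at its left SNP
#' and opens the next at its right SNP.
#'
#' @param scan A [pairwise_scan()] result.
#' @param c_threshold Fragment-termination threshold on `c_hat` (default
#'   1e-4: the EM returns tiny positive values from finite tolerance, so
#'   "greater than 0" is applied numerically).
#' @param min_phase_posterior Minimum winning-phase posterior needed to
#'   chain a pair (default 0.5, i.e. only an exact tie splits, with a
#'   warning).
#' @return Data frame of fragments: `fragment`, `chrom`, `start_idx`,
#'   `end_idx` (chromosome-local SNP indices, inclusive, 1-based),
#'   `start_bp`, `end_bp`, `n_het`, `terminating_c` (`NA` for the
#'   chromosome-final fragment).  Attribute `het_lists` holds the
#'   chromosome-local het-SNP indices of each fragment.
#' @export
fragmentize <- function(scan, c_threshold = 1e-4, min_phase_posterior = 0.5) {
  het <- attr(scan, "het_idx")
  map <- attr(scan, "map")
  if (length(het) == 0)
    return(structure(data.frame(), het_lists = list()))
  if (length(het) == 1L) {
    out <- data.frame(fragment = 1L, chrom = attr(scan, "chromosome"),
                      start_idx = het, end_idx = het,
                      start_bp = map$pos[het], end_bp = map$pos[het],
                      n_het = 1L, terminating_c = NA_real_)
    attr(out, "het_lists") <- list(het)
    return(out)
  }
  post_ok <- !is.na(scan$phase_posterior) &
    pmax(scan$phase_posterior, 1 - scan$phase_posterior) > min_phase_posterior
  tie <- !is.na(scan$phase_posterior) &
    scan$phase_posterior == 0.5 & min_phase_posterior <= 0.5
  if (any(tie))
    warning(sum(tie), " pair(s) with phase posterior exactly 0.5 split fragments")
  linked <- !scan$skipped & !is.na(scan$c_hat) & scan$c_hat <= c_threshold &
    post_ok
  frag_of <- cumsum(c(1L, as.integer(!linked)))   # fragment id per het SNP
  ids <- unique(frag_of)
  het_lists <- lapply(ids, function(fid) het[frag_of == fid])
  term <- vapply(ids, function(fid) {
    k <- max(which(frag_of == fid))               # last het SNP of fragment
    if (k >= length(het)) NA_real_ else scan$c_hat[k]
  }, numeric(1))
  out <- data.frame(
    fragment = seq_along(ids),
    chrom = attr(scan, "chromosome"),
    start_idx = vapply(het_lists, min, integer(1)),
    end_idx = vapply(het_lists, max, integer(1)),
    n_het = lengths(het_lists),
    terminating_c = term)
  out$start_bp <- map$pos[out$start_idx]
  out$end_bp <- map$pos[out$end_idx]
  attr(out, "het_lists") <- het_lists
  out
}

#' Reconstruct the sire's two haplotypes over one fragment
#'
#' Chains the pairwise phase calls of a fragment left to right: a pair
#' called coupling (posterior > 0.5) keeps the allele-1-bearing chromosome
#' on the same strand, a repulsion call crosses it over.  The orientation
#' of the whole fragment (which strand is "haplotype 1") is arbitrary;
#' sire-homozygous SNPs inside the span carry the same allele on both
#' strands.
#'
#' @param scan A [pairwise_scan()] result.
#' @param het_snps Chromosome-local indices of the fragment's sire-het SNPs
#'   (one entry of the `het_lists` attribute of [fragmentize()]).
#' @param sire Sire dosage vector for the chromosome (to fill homozygous
#'   SNPs); optional.
#' @return Matrix with 2 rows (strands) and `end - start + 1` columns
#'   (SNPs of the inclusive span), allele codes 1/2, `NA` where unknown;
#'   attribute `span` gives the chromosome-local index range.
#' @export
phase_sire_fragment <- function(scan, het_snps, sire = NULL) {
  stopifnot(length(het_snps) >= 1)
  span <- min(het_snps):max(het_snps)
  hap <- matrix(NA_integer_, 2, length(span))
  # state: allele of strand 1 at the current het SNP
  a1 <- 1L
  hap[, span == het_snps[1]] <- c(1L, 2L)
  if (length(het_snps) > 1) {
    for (k in seq_len(length(het_snps) - 1L)) {
      row <- which(scan$idx1 == het_snps[k] & scan$idx2 == het_snps[k + 1L])
      if (length(row) != 1 || is.na(scan$phase_posterior[row]))
        stop("scan does not cover the pair starting at index ", het_snps[k])
      coupling <- scan$phase_posterior[row] >= 0.5
      if (!coupling) a1 <- 3L - a1
      hap[, span == het_snps[k + 1L]] <- c(a1, 3L - a1)
    }
  }
  if (!is.null(sire)) {
    for (i in seq_along(span)) {
      d <- sire[span[i]]
      if (!is.na(d) && d == 2L) hap[, i] <- 1L
      if (!is.na(d) && d == 0L) hap[, i] <- 2L
    }
  }
  attr(hap, "span") <- range(span)
  hap
}

# Origin votes of all progeny at the het SNPs of one fragment: at a sire-het
# SNP a homozygous progeny received the sire allele it is homozygous for,
# which identifies the transmitted strand.  Returns an n_het x n_progeny
# matrix with entries 1, 2 or NA.
origin_votes <- function(hap, het_snps, prog_chr) {
  span <- attr(hap, "span")
  votes <- matrix(NA_integer_, length(het_snps), ncol(prog_chr))
  for (k in seq_along(het_snps)) {
    col <- het_snps[k] - span[1] + 1L
    dos <- prog_chr[het_snps[k], ]
    allele <- ifelse(is.na(dos), NA_integer_,
                     ifelse(dos == 2L, 1L, ifelse(dos == 0L, 2L, NA_integer_)))
    votes[k, ] <- ifelse(is.na(allele), NA_integer_,
                         ifelse(allele == hap[1, col], 1L, 2L))
  }
  votes
}

#' Phase the progeny of one fragment
#'
#' Determines, for each progeny, which sire strand the fragment was
#' inherited from: every SNP where the progeny is homozygous and the sire
#' heterozygous votes for the strand carrying that allele.  Unanimous votes
#' fix the origin; the paternal allele is then the strand allele at every
#' SNP of the span and the maternal allele is the genotype minus the
#' paternal one.  No votes (progeny heterozygous or missing throughout)
#' leave the origin unknown; conflicting votes flag a within-fragment
#' recombination event or genotyping error and the span is not phased by
#' this per-fragment rule (see [phase_family()] for the run-based
#' resolution that recovers such progeny).
#'
#' @param hap Sire haplotypes from [phase_sire_fragment()].
#' @param het_snps The fragment's sire-het SNP indices (chromosome-local).
#' @param prog_chr Progeny dosage matrix for the chromosome.
#' @return List with `origin` (strand 1/2 or `NA` per progeny), `status`
#'   (`"ok"`, `"unknown"`, `"conflict"` per progeny), `votes` (het-SNP x
#'   progeny matrix), `paternal`, `maternal` (span x progeny allele
#'   matrices, codes 1/2/NA).
#' @export
phase_progeny <- function(hap, het_snps, prog_chr) {
  span <- attr(hap, "span")
  idx <- span[1]:span[2]
  votes <- origin_votes(hap, het_snps, prog_chr)
  np <- ncol(prog_chr)
  origin <- rep(NA_integer_, np)
  status <- rep("unknown", np)
  for (p in seq_len(np)) {
    v <- votes[, p]
    v <- v[!is.na(v)]
    if (length(v) == 0) next
    if (all(v == v[1])) {
      origin[p] <- v[1]
      status[p] <- "ok"
    } else {
      status[p] <- "conflict"
    }
  }
  pat <- matrix(NA_integer_, length(idx), np)
  mat <- matrix(NA_integer_, length(idx), np)
  for (p in seq_len(np)) {
    if (is.na(origin[p])) next
    pa <- hap[origin[p], ]
    pat[, p] <- pa
    dos <- prog_chr[idx, p]
    m <- dos - (pa == 1L)          # allele-1 count left for the dam gamete
    m_allele <- ifelse(is.na(m) | m < 0 | m > 1, NA_integer_,
                       ifelse(m == 1L, 1L, 2L))
    m_allele[is.na(pa)] <- NA_integer_
    mat[, p] <- m_allele
  }
  list(origin = origin, status = status, votes = votes,
       paternal = pat, maternal = mat, span = span)
}

#' Linkage between adjacent fragments ("super-alleles")
#'
#' Treats whole phased fragments as single highly informative alleles whose
#' inheritance is traced through the progeny: for each pair of adjacent
#' fragments, the relative orientation of their strand labels is chosen to
#' minimize the number of progeny whose paternal origin switches across the
#' boundary (a tie is flagged unresolved), and the boundary recombination
#' fraction is the fraction of informative progeny that switch.
#'
#' @param origins_left,origins_right Per-progeny origins (1/2/`NA`) in the
#'   left and right fragment.
#' @return List with `flip` (should the right fragment's labels be
#'   swapped), `n_informative`, `n_switch` (after alignment), `c_hat`,
#'   `unresolved` (tie), and `switched` (logical per progeny, `NA` when
#'   uninformative).
#' @export
interfragment_linkage <- function(origins_left, origins_right) {
  ok <- !is.na(origins_left) & !is.na(origins_right)
  n <- sum(ok)
  if (n == 0)
    return(list(flip = FALSE, n_informative = 0L, n_switch = NA_integer_,
                c_hat = NA_real_, unresolved = TRUE,
                switched = rep(NA, length(origins_left))))
  sw_keep <- sum(origins_left[ok] != origins_right[ok])
  flip <- sw_keep > n - sw_keep
  unresolved <- sw_keep * 2L == n
  n_switch <- min(sw_keep, n - sw_keep)
  right <- if (flip) 3L - origins_right else origins_right
  switched <- ifelse(ok, origins_left != right, NA)
  list(flip = flip, n_informative = n, n_switch = n_switch,
       c_hat = n_switch / n, unresolved = unresolved, switched = switched)
}

# Sire-chain correction pass.  A recombination event hits each meiosis
# independently with probability <= 1/2, so an inter-SNP point where MORE
# than half of the informative progeny appear to switch strands cannot be
# recombination — it is a mis-called pair phase (or mis-oriented fragment)
# flipping the sire chain.  Walking left to right, such majority-switch
# points flip the strand labeling from there on; this is the within-
# chromosome extension of the minimize-recombinants rule used to align
# adjacent fragments.  Returns the corrected votes and the per-SNP flip
# indicator (TRUE where strand labels must be swapped).
correct_chain <- function(votes) {
  n <- nrow(votes)
  np <- ncol(votes)
  flip <- logical(n)
  o <- FALSE
  last <- rep(NA_integer_, np)
  for (k in seq_len(n)) {
    v <- votes[k, ]
    if (all(is.na(v))) {
      flip[k] <- o
      next
    }
    vc <- if (o) 3L - v else v
    have <- !is.na(vc) & !is.na(last)
    if (sum(have) > 0 && 2L * sum(vc[have] != last[have]) > sum(have)) {
      o <- !o
      vc <- 3L - vc
    }
    flip[k] <- o
    upd <- !is.na(vc)
    last[upd] <- vc[upd]
  }
  corrected <- votes
  corrected[flip, ] <- 3L - corrected[flip, , drop = FALSE]
  list(votes = corrected, flip = flip)
}

# Per-progeny origin assignment and event detection from the chromosome-wide
# vote sequence.  votes: n_snp x n_prog matrix in *global strand labels*
# (after fragment orientation), NA where uninformative.  Returns per progeny
# the assigned strand per SNP (runs of agreeing votes extended outward;
# gaps between disagreeing votes left NA) and the detected events.
assign_runs <- function(votes, pos) {
  n <- nrow(votes)
  np <- ncol(votes)
  assigned <- matrix(NA_integer_, n, np)
  events <- list()
  for (p in seq_len(np)) {
    iv <- which(!is.na(votes[, p]))
    if (length(iv) == 0) next
    v <- votes[iv, p]
    if (length(iv) == 1L) {
      assigned[, p] <- v
      next
    }
    chg <- which(v[-1] != v[-length(v)])
    if (length(chg) == 0) {
      assigned[, p] <- v[1]
      next
    }
    # boundaries of same-vote blocks in vote-sequence coordinates
    starts <- c(1L, chg + 1L)
    ends <- c(chg, length(v))
    for (b in seq_along(starts)) {
      lo <- if (b == 1L) 1L else iv[starts[b]]
      hi <- if (b == length(starts)) n else iv[ends[b]]
      assigned[lo:hi, p] <- v[starts[b]]
    }
    for (e in chg) {
      events[[length(events) + 1L]] <- data.frame(
        progeny = p, left_idx = iv[e], right_idx = iv[e + 1L],
        left_bp = pos[iv[e]], right_bp = pos[iv[e + 1L]],
        pos_bp = (pos[iv[e]] + pos[iv[e + 1L]]) / 2)
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
  else data.frame(progeny = integer(0), left_idx = integer(0),
                  right_idx = integer(0), left_bp = numeric(0),
                  right_bp = numeric(0), pos_bp = numeric(0))
  list(assigned = assigned, events = ev)
}

#' Run the full genome fragmentation phasing strategy
#'
#' The complete pipeline for one half-sib family: QC and Mendelian
#' filtering, the pairwise joint-estimation scan, fragmentation, sire and
#' progeny phasing per fragment, alignment of adjacent fragments by
#' super-allele linkage, per-progeny recombination-event detection from
#' origin changes, and the informativity accounting.
#'
#' Events are detected per progeny as changes in the inherited strand along
#' the chromosome-wide sequence of origin-informative SNPs — this covers
#' both switches between fragments and recombination events hidden inside a
#' fragment (which surface as conflicting origin votes).  Each event is
#' bounded by the last informative SNP before and the first informative SNP
#' after the switch and assigned to the interval midpoint.
#'
#' @param data A [family_dataset()].
#' @param qc Apply [qc_filter()] and [mendelian_check()] first (default
#'   TRUE).
#' @param maf_min,call_rate_min,min_callrate_fraction Passed to
#'   [qc_filter()].
#' @param max_pair_bp,cfg Passed to [pairwise_scan()].
#' @param c_threshold,min_phase_posterior Passed to [fragmentize()].
#' @return Object of class `"gfps_phase"`: list with `map` (the analyzed
#'   SNPs), `scan`, `fragments` (with `orientation` and `unresolved`
#'   columns), `boundaries` (per adjacent-fragment linkage results),
#'   `sire_haplotypes` (per chromosome, 2 x n_snp, globally oriented),
#'   `origin` (per chromosome, fragment x progeny matrices, global labels),
#'   `origin_status`, `assigned` (per chromosome, SNP x progeny strand
#'   assignment), `paternal`, `maternal` (per chromosome allele matrices),
#'   `events` (data frame), `informativity`, `qc_report`,
#'   `mendel_violations`.
#' @export
phase_family <- function(data, qc = TRUE, maf_min = 0.10,
                         call_rate_min = 0.80, min_callrate_fraction = 2 / 3,
                         max_pair_bp = 50e6, cfg = em_config(),
                         c_threshold = 1e-4, min_phase_posterior = 0.5) {
  stopifnot(inherits(data, "family_dataset"))
  qc_report <- NULL
  mendel <- NULL
  if (qc) {
    q <- qc_filter(data, maf_min, call_rate_min, min_callrate_fraction)
    qc_report <- q$report
    m <- mendelian_check(q$data)
    mendel <- m$violations
    data <- m$data
  }
  chroms <- unique(data$map$chrom)
  res <- list(map = data$map, qc_report = qc_report,
              mendel_violations = mendel,
              scan = NULL, fragments = NULL, boundaries = NULL,
              sire_haplotypes = list(), origin = list(),
              origin_status = list(), assigned = list(),
              paternal = list(), maternal = list(), events = NULL,
              informativity = NULL, n_progeny = ncol(data$progeny),
              progeny_ids = colnames(data$progeny))
  all_scan <- list()
  all_frag <- list()
  all_bound <- list()
  all_events <- list()
  all_inf <- list()
  frag_offset <- 0L
  for (ch in chroms) {
    sel <- which(data$map$chrom == ch)
    map_chr <- data$map[sel, , drop = FALSE]
    sire_chr <- data$sire[sel]
    prog_chr <- data$progeny[sel, , drop = FALSE]
    np <- ncol(prog_chr)
    n_chr <- length(sel)
    scan <- pairwise_scan(data, ch, max_pair_bp, cfg)
    frags <- fragmentize(scan, c_threshold, min_phase_posterior)
    het_lists <- attr(frags, "het_lists")
    nf <- nrow(frags)
    strandA <- rep(NA_integer_, n_chr)
    strandB <- rep(NA_integer_, n_chr)
    # homozygous sire SNPs are phase-trivial everywhere on the chromosome
    strandA[sire_chr == 2L] <- 1L
    strandB[sire_chr == 2L] <- 1L
    strandA[sire_chr == 0L] <- 2L
    strandB[sire_chr == 0L] <- 2L
    votes_chr <- matrix(NA_integer_, n_chr, np)
    origin_chr <- matrix(NA_integer_, max(nf, 1L), np)
    status_chr <- matrix(NA_character_, max(nf, 1L), np)
    orientation <- rep(1L, max(nf, 1L))
    unresolved <- rep(FALSE, max(nf, 1L))
    bounds <- list()
    prev_last_vote <- rep(NA_integer_, np)   # strand of last vote so far
    if (nf > 0) {
      for (f in seq_len(nf)) {
        hap <- phase_sire_fragment(scan, het_lists[[f]], sire_chr)
        pp <- phase_progeny(hap, het_lists[[f]], prog_chr)
        # orient this fragment against the last votes of the chained left
        # block, minimizing origin switches at the boundary
        first_vote <- apply(pp$votes, 2, function(v) {
          v <- v[!is.na(v)]
          if (length(v)) v[1] else NA_integer_
        })
        flip <- FALSE
        if (f > 1L && !all(is.na(prev_last_vote)) && !all(is.na(first_vote))) {
          link <- interfragment_linkage(prev_last_vote, first_vote)
          flip <- link$flip
        }
        orientation[f] <- if (flip) 2L else 1L
        span <- attr(hap, "span")
        rows <- span[1]:span[2]
        if (flip) hap <- hap[2:1, , drop = FALSE]
        strandA[rows] <- hap[1, ]
        strandB[rows] <- hap[2, ]
        v <- pp$votes
        if (flip) v <- 3L - v
        votes_chr[het_lists[[f]], ] <- v
        lastv <- apply(v, 2, function(x) {
          x <- x[!is.na(x)]
          if (length(x)) x[length(x)] else NA_integer_
        })
        upd <- !is.na(lastv)
        prev_last_vote[upd] <- lastv[upd]
      }
      # chain correction: a point where a majority of informative progeny
      # appear to switch strands marks a mis-called pair phase, not
      # recombination; flip the labeling from there on
      corr <- correct_chain(votes_chr)
      votes_chr <- corr$votes
      fl <- corr$flip
      if (any(fl)) {
        tmp <- strandA[fl]
        strandA[fl] <- strandB[fl]
        strandB[fl] <- tmp
      }
      # fragment-level origins and boundary linkage from corrected votes
      for (f in seq_len(nf)) {
        vts <- votes_chr[het_lists[[f]], , drop = FALSE]
        for (p in seq_len(np)) {
          v <- vts[, p]
          v <- v[!is.na(v)]
          if (length(v) == 0) {
            status_chr[f, p] <- "unknown"
          } else if (all(v == v[1])) {
            origin_chr[f, p] <- v[1]
            status_chr[f, p] <- "ok"
          } else {
            status_chr[f, p] <- "conflict"
          }
        }
      }
      if (nf > 1) {
        for (f in seq_len(nf - 1L)) {
          link <- interfragment_linkage(origin_chr[f, ], origin_chr[f + 1L, ])
          unresolved[f + 1L] <- link$unresolved
          bounds[[length(bounds) + 1L]] <- data.frame(
            chrom = ch, left_fragment = f + frag_offset,
            right_fragment = f + 1L + frag_offset,
            n_informative = link$n_informative, n_switch = link$n_switch,
            c_hat = link$c_hat, unresolved = link$unresolved)
        }
      }
    }
    runs <- assign_runs(votes_chr, map_chr$pos)
    # paternal allele: strand allele of the assigned strand; maternal is the
    # remaining genotype allele where the genotype is called
    pat <- matrix(NA_integer_, n_chr, np)
    mat <- matrix(NA_integer_, n_chr, np)
    for (p in seq_len(np)) {
      a <- runs$assigned[, p]
      pa <- ifelse(is.na(a), NA_integer_, ifelse(a == 1L, strandA, strandB))
      # homozygous sire SNPs are paternally determined even with no origin
      pa[is.na(pa) & sire_chr == 2L] <- 1L
      pa[is.na(pa) & sire_chr == 0L] <- 2L
      pat[, p] <- pa
      m <- prog_chr[, p] - (pa == 1L)
      mat[, p] <- ifelse(is.na(m) | m < 0 | m > 1, NA_integer_,
                         ifelse(m == 1L, 1L, 2L))
    }
    ev <- runs$events
    if (nrow(ev)) {
      ev$chrom <- ch
      ev$progeny <- colnames(prog_chr)[ev$progeny]
    } else {
      ev$chrom <- character(0)
      ev$progeny <- character(0)
    }
    # informativity: sire-het, progeny-het SNPs resolved by an origin run
    het_mask <- sire_chr == 1L
    prog_het <- !is.na(prog_chr) & prog_chr == 1L
    eligible <- prog_het & het_mask
    resolved <- eligible & !is.na(runs$assigned)
    all_inf[[as.character(ch)]] <- data.frame(
      chrom = ch, n_total = sum(eligible), n_resolved = sum(resolved),
      fraction = if (sum(eligible)) sum(resolved) / sum(eligible) else NA_real_)
    if (nf > 0) {
      frags$fragment <- frags$fragment + frag_offset
      frags$orientation <- orientation
      frags$unresolved <- unresolved
    }
    res$sire_haplotypes[[as.character(ch)]] <- rbind(strandA, strandB)
    res$origin[[as.character(ch)]] <- origin_chr
    res$origin_status[[as.character(ch)]] <- status_chr
    res$assigned[[as.character(ch)]] <- runs$assigned
    res$paternal[[as.character(ch)]] <- pat
    res$maternal[[as.character(ch)]] <- mat
    all_scan[[as.character(ch)]] <- scan
    if (nf > 0) all_frag[[as.character(ch)]] <- frags
    all_bound <- c(all_bound, bounds)
    all_events[[as.character(ch)]] <- ev
    frag_offset <- frag_offset + nf
  }
  res$scan <- do.call(rbind, lapply(all_scan, as.data.frame))
  rownames(res$scan) <- NULL
  res$fragments <- do.call(rbind, all_frag)
  rownames(res$fragments) <- NULL
  res$boundaries <- if (length(all_bound)) do.call(rbind, all_bound)
  else data.frame()
  res$events <- do.call(rbind, all_events)
  rownames(res$events) <- NULL
  res$informativity <- do.call(rbind, all_inf)
  rownames(res$informativity) <- NULL
  class(res) <- "gfps_phase"
  res
}

#' @export
print.gfps_phase <- function(x, ...) {
  cat(sprintf("GFPS phasing of %d SNPs (%d chromosomes), %d progeny\n",
              nrow(x$map), length(x$sire_haplotypes), x$n_progeny))
  cat(sprintf("  %d fragments, %d recombination events detected\n",
              if (is.null(x$fragments)) 0L else nrow(x$fragments),
              if (is.null(x$events)) 0L else nrow(x$events)))
  if (!is.null(x$informativity) && nrow(x$informativity))
    cat(sprintf("  informativity (sire-het/progeny-het resolved): %.1f%%\n",
                100 * sum(x$informativity$n_resolved) /
                  max(sum(x$informativity$n_total), 1)))
  invisible(x)
}

#' Genome-wide linkage scan of one fragment against all others
#'
#' Computes the super-allele recombination fraction between a query
#' fragment and every other fragment from the per-progeny fragment origins:
#' the fraction of doubly informative progeny whose origin labels differ,
#' folded for label orientation (`c_hat <= 0.5`).  A fragment unlinked to
#' its physical neighbors but tightly linked to a distant fragment flags an
#' array-assembly error.
#'
#' @param phased A [phase_family()] result.
#' @param fragment Query fragment id (row of `phased$fragments`).
#' @return Data frame of all fragments ranked by `c_hat` (query first):
#'   `fragment`, `chrom`, `start_bp`, `end_bp`, `n_informative`, `c_hat`.
#' @export
genome_wide_fragment_scan <- function(phased, fragment) {
  stopifnot(inherits(phased, "gfps_phase"))
  fr <- phased$fragments
  stopifnot(fragment %in% fr$fragment)
  orig <- function(fid) {
    ch <- as.character(fr$chrom[fr$fragment == fid])
    local <- sum(fr$chrom == fr$chrom[fr$fragment == fid] &
                   fr$fragment <= fid)
    phased$origin[[ch]][local, ]
  }
  q <- orig(fragment)
  out <- fr[, c("fragment", "chrom", "start_bp", "end_bp")]
  out$n_informative <- NA_integer_
  out$c_hat <- NA_real_
  for (i in seq_len(nrow(fr))) {
    o <- orig(fr$fragment[i])
    ok <- !is.na(q) & !is.na(o)
    n <- sum(ok)
    out$n_informative[i] <- n
    if (n > 0) {
      k <- sum(q[ok] != o[ok])
      out$c_hat[i] <- min(k, n - k) / n
    }
  }
  out[order(out$fragment != fragment, out$c_hat), ]
}

#' Match detected recombination events against simulation truth
#'
#' Greedy nearest-neighbor one-to-one matching of detected to true events
#' within `max_distance`, per progeny and chromosome.
#'
#' @param true_events Data frame with `progeny`, `chrom`, `pos_bp`.
#' @param detected_events Data frame with the same columns.
#' @param max_distance Maximum matching distance in bp (default 3 Mb).
#' @return List with `matched_fraction` (of true events), `mean_abs_bp`
#'   (mean absolute distance of matches), `n_true`, `n_detected`,
#'   `n_matched`.
#' @export
match_events <- function(true_events, detected_events, max_distance = 3e6) {
  n_true <- nrow(true_events)
  n_det <- nrow(detected_events)
  n_matched <- 0L
  dsum <- 0
  if (n_true && n_det) {
    keys <- unique(true_events[, c("progeny", "chrom")])
    for (r in seq_len(nrow(keys))) {
      ti <- which(true_events$progeny == keys$progeny[r] &
                    true_events$chrom == keys$chrom[r])
      di <- which(detected_events$progeny == keys$progeny[r] &
                    detected_events$chrom == keys$chrom[r])
      if (!length(di)) next
      d <- abs(outer(true_events$pos_bp[ti], detected_events$pos_bp[di], "-"))
      while (length(ti) && length(di)) {
        m <- which(d == min(d), arr.ind = TRUE)[1, ]
        if (d[m[1], m[2]] > max_distance) break
        n_matched <- n_matched + 1L
        dsum <- dsum + d[m[1], m[2]]
        ti <- ti[-m[1]]
        di <- di[-m[2]]
        d <- d[-m[1], -m[2], drop = FALSE]
        if (!length(d)) break
      }
    }
  }
  list(matched_fraction = if (n_true) n_matched / n_true else NA_real_,
       mean_abs_bp = if (n_matched) dsum / n_matched else NA_real_,
       n_true = n_true, n_detected = n_det, n_matched = n_matched)
}

#' Per-chromosome informativity gained by phasing
#'
#' Fraction of SNPs that are heterozygous in both sire and progeny (hence
#' uninformative one SNP at a time) whose transmitted sire strand was
#' resolved through the fragment origin of that progeny.
#'
#' @param phased A [phase_family()] result.
#' @return Data frame `chrom`, `n_total`, `n_resolved`, `fraction`.
#' @export
informativity_report <- function(phased) {
  stopifnot(inherits(phased, "gfps_phase"))
  phased$informativity
}

#' Regions of identity between two phased individuals
#'
#' Maximal runs of SNPs at which two individuals carry identical, known
#' alleles on their same-origin (paternal or maternal) haplotypes.  Runs of
#' at least `min_snps` SNPs are regions of identity (ROIs) — a
#' generalization of runs of homozygosity to a pair of individuals; the
#' reported proportion is the summed length of kept runs over all jointly
#' phased SNPs (`basis = "snp"`) or over the spanned bp (`basis = "bp"`).
#'
#' @param phased A [phase_family()] result.
#' @param ind1,ind2 Progeny identifiers (names or column indices).
#' @param origin `"paternal"` or `"maternal"`.
#' @param min_snps Minimum SNPs per kept run (default 20).
#' @param basis Proportion denominator: `"snp"` (default) or `"bp"`.
#' @return List of class `"roi_record"`: `segments` (data frame `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`), `proportion`, `n_joint` (jointly
#'   phased SNPs), `origin`, `status` (`"ok"` or `"no_joint_snps"`).
#' @export
compute_rois <- function(phased, ind1, ind2,
                         origin = c("paternal", "maternal"), min_snps = 20,
                         basis = c("snp", "bp")) {
  stopifnot(inherits(phased, "gfps_phase"))
  origin <- match.arg(origin)
  basis <- match.arg(basis)
  ids <- phased$progeny_ids
  i1 <- if (is.character(ind1)) match(ind1, ids) else as.integer(ind1)
  i2 <- if (is.character(ind2)) match(ind2, ids) else as.integer(ind2)
  stopifnot(!is.na(i1), !is.na(i2))
  segs <- list()
  n_joint <- 0L
  n_in_runs <- 0L
  bp_joint <- 0
  bp_in_runs <- 0
  for (ch in names(phased[[origin]])) {
    a <- phased[[origin]][[ch]][, i1]
    b <- phased[[origin]][[ch]][, i2]
    pos <- phased$map$pos[phased$map$chrom == ch]
    known <- !is.na(a) & !is.na(b)
    n_joint <- n_joint + sum(known)
    same <- known & a == b
    r <- rle(same)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_rows <- which(r$values & r$lengths >= min_snps)
    for (k in run_rows) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start_bp = pos[starts[k]], end_bp = pos[ends[k]],
        n_snps = r$lengths[k])
      n_in_runs <- n_in_runs + r$lengths[k]
      bp_in_runs <- bp_in_runs + pos[ends[k]] - pos[starts[k]]
    }
    if (sum(known) > 1)
      bp_joint <- bp_joint + max(pos[known]) - min(pos[known])
  }
  segments <- if (length(segs)) do.call(rbind, segs)
  else data.frame(chrom = character(0), start_bp = numeric(0),
                  end_bp = numeric(0), n_snps = integer(0))
  prop <- if (basis == "snp") {
    if (n_joint > 0) n_in_runs / n_joint else NA_real_
  } else {
    if (bp_joint > 0) bp_in_runs / bp_joint else NA_real_
  }
  structure(list(segments = segments, proportion = prop, n_joint = n_joint,
                 origin = origin, ind1 = ids[i1], ind2 = ids[i2],
                 status = if (n_joint > 0) "ok" else "no_joint_snps"),
            class = "roi_record")
}

#' @export
print.roi_record <- function(x, ...) {
  cat(sprintf("ROI (%s) between %s and %s: proportion %.3f over %d jointly phased SNPs, %d segment(s)\n",
              x$origin, x$ind1, x$ind2,
              if (is.na(x$proportion)) NA else x$proportion, x$n_joint,
              nrow(x$segments)))
  invisible(x)
}
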