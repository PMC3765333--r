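#' Read a half-sib family from PLINK PED/MAP text files
#'
#' Reads the standard whitespace-delimited PED format (family id,
#' individual id, father, mother, sex, phenotype, then two allele columns
#' per SNP; `0` denotes a missing allele) together with its MAP file
#' (chromosome, SNP id, genetic position, bp — or the 3-column variant
#' without the genetic position).  The sire row is identified by
#' `sire_id`; all other rows are treated as progeny.  Allele 1 of each SNP
#' is the first allele observed in file order.
#'
#' @param ped_file,map_file Paths.
#' @param sire_id Individual id of the sire.
#' @return A [family_dataset()].
#' @export
read_plink_family <- function(ped_file, map_file, sire_id) {
  mp <- utils::read.table(map_file, header = FALSE,
                          colClasses = "character")
  if (ncol(mp) == 4) {
    map <- data.frame(snp_id = mp[[2]], chrom = mp[[1]],
                      pos = as.numeric(mp[[4]]))
  } else if (ncol(mp) == 3) {
    map <- data.frame(snp_id = mp[[2]], chrom = mp[[1]],
                      pos = as.numeric(mp[[3]]))
  } else stop("MAP file must have 3 or 4 columns")
  ped <- utils::read.table(ped_file, header = FALSE,
                           colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp)
    stop(sprintf("PED has %d columns; expected %d for %d SNPs",
                 ncol(ped), 6 + 2 * n_snp, n_snp))
  ids <- ped[[2]]
  si <- match(sire_id, ids)
  if (is.na(si)) stop("sire id ", sire_id, " not found in PED")
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, 2 * n_snp, 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * n_snp, 2), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  allele1 <- character(n_snp)
  allele2 <- character(n_snp)
  dosage <- matrix(NA_integer_, n_snp, nrow(ped))
  for (j in seq_len(n_snp)) {
    obs <- c(rbind(a1[, j], a2[, j]))
    seen <- unique(obs[!is.na(obs)])
    if (length(seen) > 2)
      stop("more than two alleles at SNP ", map$snp_id[j])
    allele1[j] <- if (length(seen) >= 1) seen[1] else "A"
    allele2[j] <- if (length(seen) == 2) seen[2] else "B"
    dosage[j, ] <- (a1[, j] == allele1[j]) + (a2[, j] == allele1[j])
  }
  map$allele1 <- allele1
  map$allele2 <- allele2
  prog <- dosage[, -si, drop = FALSE]
  colnames(prog) <- ids[-si]
  family_dataset(map, dosage[, si], prog)
}

#' Read a half-sib family from a transposed genotype TSV
#'
#' Dialect: rows are SNPs and columns individuals; genotypes are written
#' `"A/B"` with `"."` or `"0"` for a missing allele.  The first three
#' columns are `chrom`, `snp_id`, `pos`; remaining column names are the
#' individual ids.
#'
#' @param file Path.
#' @param sire_id Column name of the sire.
#' @return A [family_dataset()].
#' @export
read_genotype_tsv <- function(file, sire_id) {
  tb <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#")
  stopifnot(ncol(tb) >= 4)
  map <- data.frame(snp_id = tb[[2]], chrom = tb[[1]],
                    pos = as.numeric(tb[[3]]))
  ids <- colnames(tb)[-(1:3)]
  if (!sire_id %in% ids) stop("sire id ", sire_id, " not found")
  g <- as.matrix(tb[, -(1:3), drop = FALSE])
  parts <- strsplit(g, "/", fixed = TRUE)
  a1 <- matrix(vapply(parts, `[`, character(1), 1L), nrow(g), ncol(g))
  a2 <- matrix(vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_,
                      character(1)), nrow(g), ncol(g))
  a1[a1 %in% c("0", ".")] <- NA
  a2[a2 %in% c("0", ".")] <- NA
  n_snp <- nrow(map)
  allele1 <- character(n_snp)
  allele2 <- character(n_snp)
  dosage <- matrix(NA_integer_, n_snp, length(ids))
  for (j in seq_len(n_snp)) {
    obs <- c(rbind(a1[j, ], a2[j, ]))
    seen <- unique(obs[!is.na(obs)])
    if (length(seen) > 2)
      stop("more than two alleles at SNP ", map$snp_id[j])
    allele1[j] <- if (length(seen) >= 1) seen[1] else "A"
    allele2[j] <- if (length(seen) == 2) seen[2] else "B"
    dosage[j, ] <- (a1[j, ] == allele1[j]) + (a2[j, ] == allele1[j])
  }
  map$allele1 <- allele1
  map$allele2 <- allele2
  si <- match(sire_id, ids)
  prog <- dosage[, -si, drop = FALSE]
  colnames(prog) <- ids[-si]
  family_dataset(map, dosage[, si], prog)
}

# TSV writer with "# key: value" header comments.
write_tsv_commented <- function(df, file, header = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (h in names(header))
    writeLines(sprintf("# %s: %s", h, header[[h]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

run_header <- function(seed = NULL, extra = list()) {
  h <- c(list(tool = "gfps",
              version = as.character(utils::packageVersion("gfps")),
              date = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
         if (!is.null(seed)) list(seed = seed), extra)
  vapply(h, as.character, character(1))
}

#' Write GFPS phasing outputs as TSV files
#'
#' Writes the pairwise scan, fragments (BED-like: chromosome, start/end bp,
#' id, SNP count, terminating recombination estimate), phased haplotypes
#' (long format: individual, SNP, paternal and maternal alleles, assigned
#' strand, status), recombination events, and informativity to a directory.
#'
#' @param phased A [phase_family()] result.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the file headers (optional).
#' @return Invisibly, the vector of file paths.
#' @export
write_phase_outputs <- function(phased, dir, seed = NULL) {
  stopifnot(inherits(phased, "gfps_phase"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- run_header(seed)
  paths <- c(scan = file.path(dir, "pairwise_scan.tsv"),
             fragments = file.path(dir, "fragments.tsv"),
             phased = file.path(dir, "phased_haplotypes.tsv"),
             events = file.path(dir, "events.tsv"),
             informativity = file.path(dir, "informativity.tsv"))
  write_tsv_commented(phased$scan, paths["scan"], hdr)
  fr <- phased$fragments
  write_tsv_commented(
    data.frame(chrom = fr$chrom, start_bp = fr$start_bp, end_bp = fr$end_bp,
               fragment = fr$fragment, n_het = fr$n_het,
               terminating_c = fr$terminating_c,
               orientation = fr$orientation, unresolved = fr$unresolved),
    paths["fragments"], hdr)
  long <- list()
  for (ch in names(phased$paternal)) {
    mp <- phased$map[phased$map$chrom == ch, , drop = FALSE]
    pat <- phased$paternal[[ch]]
    mat <- phased$maternal[[ch]]
    asg <- phased$assigned[[ch]]
    for (p in seq_len(ncol(pat))) {
      code <- function(m) ifelse(is.na(m), ".",
                                 ifelse(m == 1L, mp$allele1, mp$allele2))
      long[[length(long) + 1L]] <- data.frame(
        individual = phased$progeny_ids[p], chrom = ch, snp_id = mp$snp_id,
        pos = mp$pos, paternal = code(pat[, p]), maternal = code(mat[, p]),
        strand = ifelse(is.na(asg[, p]), ".", c("A", "B")[asg[, p]]))
    }
  }
  write_tsv_commented(do.call(rbind, long), paths["phased"], hdr)
  write_tsv_commented(phased$events, paths["events"], hdr)
  write_tsv_commented(phased$informativity, paths["informativity"], hdr)
  invisible(paths)
}

#' Write a simulated chromosome as genotype TSV + truth TSV
#'
#' The genotype file follows the transposed dialect of
#' [read_genotype_tsv()] (sire column first); the truth file records each
#' progeny's crossover positions and maternal haplotype string.
#'
#' @param sim Output of [simulate_phased_chromosome()].
#' @param geno_file,truth_file Output paths.
#' @param seed Seed recorded in headers.
#' @return Invisibly, the two paths.
#' @export
write_chrom_sim <- function(sim, geno_file, truth_file, seed = NULL) {
  spec <- sim$truth$spec
  map <- spec$snp_map
  np <- spec$n_progeny
  code <- function(d) c("B/B", "A/B", "A/A")[d + 1L]
  g <- data.frame(chrom = map$chrom, snp_id = map$snp_id, pos = map$pos)
  g$sire <- code(sim$sire_genotype)
  for (p in seq_len(np)) g[[sprintf("calf%03d", p)]] <- code(sim$genotypes[, p])
  write_tsv_commented(g, geno_file, run_header(seed))
  tr <- data.frame(
    individual = sprintf("calf%03d", seq_len(np)),
    chrom = map$chrom[1],
    crossovers_bp = vapply(sim$truth$crossovers, function(x)
      paste(round(x), collapse = ","), character(1)),
    maternal = vapply(seq_len(np), function(p)
      paste(c("A", "B")[sim$truth$maternal[, p]], collapse = ""),
      character(1)))
  write_tsv_commented(tr, truth_file, run_header(seed))
  invisible(c(geno_file, truth_file))
}
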