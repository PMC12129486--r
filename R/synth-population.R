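#' Simulate a Hardy-Weinberg population with a dominant causal locus
#'
#' Draws diploid genotypes at `L` unlinked biallelic sites under
#' Hardy-Weinberg equilibrium and assigns a binary phenotype controlled by a
#' single fully (or partially) dominant causal site. The causal allele
#' frequency is derived from the target phenotype frequency `f_pheno` by the
#' dominance conversion d = 1 - sqrt(1 - f), so that carriers (dosage >= 1)
#' occur at frequency `f_pheno` in expectation.
#'
#' @param n Number of diploid individuals (>= 2).
#' @param L Number of sites (>= 1).
#' @param f_pheno Target phenotype frequency in (0, 1). The causal site is
#'   placed at `causal_index`.
#' @param penetrance Probability that a carrier expresses the phenotype
#'   (1 = fully penetrant). Non-carriers never express it.
#' @param maf_sampler Function of one integer argument returning that many
#'   alternate-allele frequencies for the non-causal sites. Default: uniform
#'   on [0.05, 0.5].
#' @param causal_index Column index of the causal site, or `NA` for a purely
#'   neutral panel (then `f_pheno` sets prevalence of a genotype-independent
#'   phenotype, useful as a null model).
#' @param seed Integer seed; the draw is bit-reproducible given
#'   (parameters, seed).
#'
#' @return An object of class `population_sim`: list with `genotypes`
#'   (n x L integer matrix of alternate-allele dosages 0/1/2), `phenotypes`
#'   (0/1 vector), `causal_index`, `allele_freqs` (the frequencies the sites
#'   were drawn at), and `seed`.
#' @examples
#' pop <- simulate_population(n = 500, L = 50, f_pheno = 0.39, seed = 1)
#' mean(pop$phenotypes)           # close to 0.39
#' pop$allele_freqs[pop$causal_index]  # 1 - sqrt(1 - 0.39)
#' @export
simulate_population <- function(n, L, f_pheno = 0.39, penetrance = 1,
                                maf_sampler = function(k) runif(k, 0.05, 0.5),
                                causal_index = ceiling(L / 2), seed = NULL) {
  if (f_pheno <= 0 || f_pheno >= 1) stop("f_pheno must lie in (0, 1)")
  if (n < 2) stop("n must be >= 2")
  if (L < 1) stop("L must be >= 1")
  if (penetrance < 0 || penetrance > 1) stop("penetrance must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  freqs <- maf_sampler(L)
  has_causal <- !is.na(causal_index)
  if (has_causal) {
    if (causal_index < 1 || causal_index > L) stop("causal_index out of range")
    freqs[causal_index] <- dominant_freq(f_pheno)
  }
  geno <- matrix(rbinom(n * L, 2L, rep(freqs, each = n)), nrow = n, ncol = L)

  if (has_causal) {
    carrier <- geno[, causal_index] >= 1L
    pheno <- integer(n)
    pheno[carrier] <- rbinom(sum(carrier), 1L, penetrance)
  } else {
    pheno <- rbinom(n, 1L, f_pheno)
  }

  structure(list(genotypes = geno, phenotypes = pheno,
                 causal_index = if (has_causal) as.integer(causal_index) else NA_integer_,
                 allele_freqs = freqs, seed = seed),
            class = "population_sim")
}

#' @export
print.population_sim <- function(x, ...) {
  cat("Hardy-Weinberg population simulation\n")
  cat(sprintf("  %d individuals x %d sites\n", nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  phenotype prevalence: %.3f\n", mean(x$phenotypes)))
  if (!is.na(x$causal_index))
    cat(sprintf("  causal site %d, allele frequency %.4f\n",
                x$causal_index, x$allele_freqs[x$causal_index]))
  invisible(x)
}

#' Simulate low-coverage sequencing read counts
#'
#' Overlays shotgun-style read counts on the genotypes of a
#' [simulate_population()] draw: the number of reads per individual per site
#' is Poisson(`coverage`), each read samples one of the two chromosomes
#' uniformly and reports its allele, flipped with probability `error_rate`.
#' Most cells are empty at the coverages this emulates (~0.35x).
#'
#' @param pop A `population_sim` object.
#' @param coverage Mean read depth per site per individual (> 0).
#' @param error_rate Per-read allele miscall probability, in [0, 0.5).
#' @param seed Integer seed.
#' @return Object of class `read_count_sim`: list with integer matrices
#'   `ref_counts` and `alt_counts` (same shape as the genotypes), `coverage`,
#'   `error_rate`, `source` (the input `population_sim`), and `seed`.
#' @examples
#' pop <- simulate_population(100, 20, f_pheno = 0.39, seed = 1)
#' rc <- simulate_reads(pop, coverage = 0.35, error_rate = 0.01, seed = 2)
#' mean(rc$ref_counts + rc$alt_counts == 0)  # ~ exp(-0.35)
#' @export
simulate_reads <- function(pop, coverage, error_rate = 0, seed = NULL) {
  stopifnot(inherits(pop, "population_sim"))
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)

  g <- pop$genotypes
  depth <- matrix(rpois(length(g), coverage), nrow = nrow(g))
  # a read drawn from a dosage-g individual reports alt w.p. g/2, then flips
  p_alt <- (g / 2) * (1 - error_rate) + (1 - g / 2) * error_rate
  alt <- matrix(rbinom(length(g), as.vector(depth), as.vector(p_alt)),
                nrow = nrow(g))
  structure(list(ref_counts = depth - alt, alt_counts = alt,
                 coverage = coverage, error_rate = error_rate,
                 source = pop, seed = seed),
            class = "read_count_sim")
}

#' @export
print.read_count_sim <- function(x, ...) {
  depth <- x$ref_counts + x$alt_counts
  cat("Low-coverage read-count simulation\n")
  cat(sprintf("  %d individuals x %d sites, coverage %.3g, error rate %.3g\n",
              nrow(depth), ncol(depth), x$coverage, x$error_rate))
  cat(sprintf("  mean depth %.3f, empty cells %.1f%%\n",
              mean(depth), 100 * mean(depth == 0)))
  invisible(x)
}

#' Convert a read-count simulation to an allele-count matrix
#'
#' Repackages a [simulate_reads()] result as the [allele_count_matrix()]
#' container consumed by the association-mapping functions, with synthetic
#' site coordinates on a single chromosome (one site per kb by default).
#'
#' @param rc A `read_count_sim` object.
#' @param chrom Chromosome label for the synthetic sites.
#' @param spacing_bp Distance between consecutive synthetic sites.
#' @return An `allele_count_matrix`.
#' @export
as_allele_counts <- function(rc, chrom = "chr_sim", spacing_bp = 1000L) {
  stopifnot(inherits(rc, "read_count_sim"))
  L <- ncol(rc$ref_counts)
  allele_count_matrix(rc$ref_counts, rc$alt_counts,
                      site_ids = data.frame(chrom = chrom,
                                            pos = seq_len(L) * spacing_bp))
}

#' Simulate preference-difference scores for dichotomous choice trials
#'
#' Per-individual preference differences (proportion of trial time spent with
#' stimulus A minus stimulus B) drawn from Normal(`effect`, `sd`) and
#' truncated to [-1, 1] by rejection, since a difference of proportions
#' cannot leave that interval.
#'
#' @param n Number of individuals.
#' @param effect True mean preference difference.
#' @param sd Standard deviation of the preference difference (> 0).
#' @param group_label Free-text label (e.g. "wild-caught, ornamented").
#' @param seed Integer seed.
#' @return Object of class `trial_data`: list with `diffs`, `group_label`,
#'   `sd` (sample standard deviation), `n`, and `seed`.
#' @examples
#' td <- simulate_trials(17, effect = 0.2, sd = 0.25, seed = 1)
#' range(td$diffs)
#' @export
simulate_trials <- function(n, effect, sd, group_label = "", seed = NULL) {
  if (sd <= 0) stop("sd must be > 0")
  if (!is.null(seed)) set.seed(seed)
  diffs <- rnorm(n, effect, sd)
  while (any(bad <- abs(diffs) > 1))
    diffs[bad] <- rnorm(sum(bad), effect, sd)
  structure(list(diffs = diffs, group_label = group_label,
                 sd = stats::sd(diffs), n = n, seed = seed),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Choice-trial preference differences%s\n",
              if (nzchar(x$group_label)) paste0(" [", x$group_label, "]") else ""))
  cat(sprintf("  n = %d, mean = %.3f, sd = %.3f\n", x$n, mean(x$diffs), x$sd))
  invisible(x)
}

#' Write / read per-site allele read counts as long-format TSV
#'
#' Serialization for [allele_count_matrix()] objects in the long format
#' `chrom  pos  individual  ref_count  alt_count`, the exchange format of the
#' association-mapping tools. Only non-empty cells are written; absent cells
#' are zero-read on reading.
#'
#' @param counts An `allele_count_matrix`.
#' @param path File path.
#' @return `write_allele_counts()` returns `path` invisibly;
#'   `read_allele_counts()` returns an `allele_count_matrix`.
#' @export
write_allele_counts <- function(counts, path) {
  stopifnot(inherits(counts, "allele_count_matrix"))
  n <- nrow(counts$ref_counts); L <- ncol(counts$ref_counts)
  keep <- which(counts$ref_counts + counts$alt_counts > 0)
  df <- data.frame(
    chrom = rep(counts$site_ids$chrom, each = n)[keep],
    pos = rep(counts$site_ids$pos, each = n)[keep],
    individual = rep(seq_len(n), times = L)[keep],
    ref_count = as.vector(counts$ref_counts)[keep],
    alt_count = as.vector(counts$alt_counts)[keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param n_individuals Number of individuals the matrix should span (cells
#'   never sequenced do not appear in the file).
#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path, n_individuals = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "integer",
                                  "integer", "integer"))
  sites <- unique(df[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  key <- paste(sites$chrom, sites$pos)
  j <- match(paste(df$chrom, df$pos), key)
  n <- if (is.null(n_individuals)) max(df$individual) else n_individuals
  ref <- matrix(0L, n, nrow(sites)); alt <- matrix(0L, n, nrow(sites))
  ref[cbind(df$individual, j)] <- df$ref_count
  alt[cbind(df$individual, j)] <- df$alt_count
  allele_count_matrix(ref, alt, site_ids = data.frame(chrom = sites$chrom,
                                                      pos = sites$pos))
}
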