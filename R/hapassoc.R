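#' Fisher's exact test for a 2x2 phenotype-by-haplotype table
#'
#' Exact hypergeometric test of association between a binary phenotype and a
#' binary haplotype state. The two-sided p-value follows the standard
#' convention of summing the point probabilities of all tables (with the
#' observed margins) no more probable than the observed one, up to a
#' relative tolerance of 1e-7; the one-sided p-value is taken in the
#' direction of the observed association.
#'
#' @param table 2x2 matrix of non-negative counts (rows = phenotype classes,
#'   columns = haplotype states), or a length-4 vector `c(a, b, c, d)` read
#'   row-wise.
#' @param sided `"two"` (default) or `"one"`.
#' @return The p-value.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))        # 2/252
#' fisher_exact(c(7, 0, 0, 6), sided = "one")                  # 1/1716
#' @export
fisher_exact <- function(table, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (any(table < 0) || sum(table) < 1) stop("invalid 2x2 table")
  if (sided == "two") {
    fisher.test(table, alternative = "two.sided")$p.value
  } else {
    min(fisher.test(table, alternative = "greater")$p.value,
        fisher.test(table, alternative = "less")$p.value)
  }
}

#' Probability that a sample of dominant-phenotype individuals is all heterozygous
#'
#' For a fully dominant allele at phenotype frequency `f_pheno` under
#' Hardy-Weinberg equilibrium (allele frequency d = 1 - sqrt(1 - f)), a
#' phenotype-positive individual is heterozygous with probability
#' 2d(1-d)/f. The analytic probability that all of `n_sampled` independent
#' phenotype-positive individuals are heterozygous is that quantity to the
#' n-th power; the simulation estimate draws genotypes by rejection from HWE
#' conditioned on carrying the dominant allele. Observing no homozygote in a
#' small sample of carriers is thus unremarkable at intermediate phenotype
#' frequencies.
#'
#' @param f_pheno Phenotype frequency in (0, 1).
#' @param n_sampled Number of phenotype-positive individuals sampled.
#' @param method `"analytic"` (default) or `"simulation"`.
#' @param n_reps Simulation replicates (default 10000).
#' @param seed Integer seed (simulation only).
#' @return The probability; for `method = "simulation"` with attributes
#'   `se` (binomial standard error) and `n_reps`.
#' @examples
#' prob_all_het(0.39, 7)                          # 0.3992
#' prob_all_het(0.39, 7, "simulation", seed = 1)  # ~0.399
#' @export
prob_all_het <- function(f_pheno, n_sampled, method = c("analytic", "simulation"),
                         n_reps = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (f_pheno <= 0 || f_pheno >= 1) stop("f_pheno must lie in (0, 1)")
  if (n_sampled == 0) return(1)
  d <- dominant_freq(f_pheno)
  if (method == "analytic") return((2 * d * (1 - d) / f_pheno)^n_sampled)
  if (!is.null(seed)) set.seed(seed)
  need <- n_reps * n_sampled
  het <- logical(0)
  while (length(het) < need) {
    g <- rbinom(2L * need, 2L, d)
    g <- g[g >= 1L]            # rejection: keep phenotype-positive draws
    het <- c(het, g == 1L)
  }
  all_het <- rowSums(matrix(!het[seq_len(need)], nrow = n_reps)) == 0
  est <- mean(all_het)
  structure(est, se = sqrt(est * (1 - est) / n_reps), n_reps = n_reps)
}

#' Diagnostic fixed differences between two haplotype groups
#'
#' Scans an alignment of two haplotype groups for positions usable as
#' diagnostic markers: sites where every sequence in group A carries one
#' base, every sequence in group B carries a different base, no sequence has
#' a gap or ambiguity at the site, and the site lies more than
#' `indel_buffer_bp` from every indel position (alignment noise near indels
#' makes such sites unreliable).
#'
#' @param group_a,group_b Character matrices (sequences x positions) over
#'   A, C, G, T, -, N (case-insensitive), equal alignment length; or lists
#'   of equal-length character strings.
#' @param indel_positions Integer vector of 1-based indel coordinates in the
#'   alignment (may be empty).
#' @param indel_buffer_bp Exclusion distance around indels (default 5);
#'   a site at distance <= buffer from any indel is excluded.
#' @return Sorted integer vector of diagnostic positions.
#' @examples
#' a <- rbind(c("T", "T", "A"), c("T", "T", "A"))
#' b <- rbind(c("C", "T", "A"), c("C", "T", "A"))
#' diagnostic_snps(a, b, indel_positions = integer(0))  # position 1
#' @export
diagnostic_snps <- function(group_a, group_b, indel_positions = integer(0),
                            indel_buffer_bp = 5L) {
  group_a <- as_alignment_matrix(group_a)
  group_b <- as_alignment_matrix(group_b)
  if (ncol(group_a) == 0 || ncol(group_b) == 0)
    stop("zero-length alignment")
  if (ncol(group_a) != ncol(group_b))
    stop("groups must share one alignment length")
  if (length(indel_positions) &&
      (min(indel_positions) < 1 || max(indel_positions) > ncol(group_a)))
    stop("indel_positions outside the alignment")
  bases <- c("A", "C", "G", "T")
  fixed_base <- function(m, j) {
    u <- unique(m[, j])
    if (length(u) == 1 && u %in% bases) u else NA_character_
  }
  out <- integer(0)
  for (j in seq_len(ncol(group_a))) {
    if (length(indel_positions) &&
        min(abs(indel_positions - j)) <= indel_buffer_bp) next
    a <- fixed_base(group_a, j)
    if (is.na(a)) next
    b <- fixed_base(group_b, j)
    if (is.na(b) || a == b) next
    out <- c(out, j)
  }
  out
}

as_alignment_matrix <- function(x) {
  if (is.matrix(x)) return(toupper(x))
  if (is.list(x) || is.character(x)) {
    chars <- strsplit(toupper(unlist(x)), "")
    if (length(unique(lengths(chars))) != 1)
      stop("sequences must have equal length")
    return(do.call(rbind, chars))
  }
  stop("unsupported alignment input")
}

#' Read an aligned haplotype group from FASTA
#'
#' Reads an aligned (equal-length) FASTA file into the character-matrix form
#' consumed by [diagnostic_snps()].
#'
#' @param path FASTA file path.
#' @return Character matrix, sequences x positions, uppercase.
#' @export
read_haplotype_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = FALSE, forceDNAtolower = FALSE)
  as_alignment_matrix(lapply(seqs, paste, collapse = ""))
}

#' Two-proportion z-test
#'
#' Pooled-variance two-proportion z statistic with a two-sided normal
#' p-value, for comparing a phenotype frequency between two samples (e.g.
#' between sampling years). Degenerate pooled proportions (0 or 1) give
#' z = 0, p = 1, flagged.
#'
#' @param x1,n1 Successes and sample size in sample 1 (`n1 >= 1`).
#' @param x2,n2 Successes and sample size in sample 2.
#' @return List with `z`, `p` and `degenerate`.
#' @examples
#' two_prop_z(30, 100, 60, 100)  # z = -4.26, p = 2.0e-5
#' @export
two_prop_z <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("sample sizes must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("invalid counts")
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1)
    return(list(z = 0, p = 1, degenerate = TRUE))
  z <- (x1 / n1 - x2 / n2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}
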