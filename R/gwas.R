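#' Per-site allele read-count matrix
#'
#' Container for low-coverage case-control association: per-individual,
#' per-site reference and alternate read counts, with site coordinates.
#' A cell may be all-zero (individual not covered at that site).
#'
#' @param ref_counts,alt_counts Non-negative integer matrices,
#'   n_individuals x n_sites.
#' @param site_ids Data frame with columns `chrom` and `pos` (1-based),
#'   one row per site. Defaults to consecutive positions on one chromosome.
#' @return Object of class `allele_count_matrix`.
#' @export
allele_count_matrix <- function(ref_counts, alt_counts, site_ids = NULL) {
  ref_counts <- as.matrix(ref_counts); alt_counts <- as.matrix(alt_counts)
  if (!identical(dim(ref_counts), dim(alt_counts)))
    stop("ref_counts and alt_counts must have identical dimensions")
  if (any(ref_counts < 0) || any(alt_counts < 0))
    stop("read counts must be non-negative")
  if (is.null(site_ids))
    site_ids <- data.frame(chrom = "chr_sim", pos = seq_len(ncol(ref_counts)))
  if (nrow(site_ids) != ncol(ref_counts))
    stop("site_ids must have one row per site")
  structure(list(ref_counts = ref_counts, alt_counts = alt_counts,
                 site_ids = site_ids),
            class = "allele_count_matrix")
}

# Binomial log-likelihood sum with the 0*log(0) = 0 convention.
binom_ll <- function(alt, ref, p) {
  ll <- numeric(length(p))
  pos <- alt > 0
  ll[pos] <- alt[pos] * log(p[pos])
  neg <- ref > 0
  ll[neg] <- ll[neg] + ref[neg] * log(1 - p[neg])
  ll
}

# Vectorized core of the case-control likelihood-ratio test.
lrt_core <- function(case_ref, case_alt, ctrl_ref, ctrl_alt) {
  n_case <- case_ref + case_alt
  n_ctrl <- ctrl_ref + ctrl_alt
  p_case <- ifelse(n_case > 0, case_alt / n_case, NA_real_)
  p_ctrl <- ifelse(n_ctrl > 0, ctrl_alt / n_ctrl, NA_real_)
  p_pool <- (case_alt + ctrl_alt) / (n_case + n_ctrl)
  stat <- 2 * (binom_ll(case_alt, case_ref, p_case) +
               binom_ll(ctrl_alt, ctrl_ref, p_ctrl) -
               binom_ll(case_alt + ctrl_alt, case_ref + ctrl_ref, p_pool))
  stat <- pmax(stat, 0)  # guard tiny negative rounding
  usable <- n_case > 0 & n_ctrl > 0 & p_pool > 0 & p_pool < 1
  stat[!usable] <- NA_real_
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p = p, usable = usable)
}

#' Case-control allele-frequency likelihood-ratio test at one site
#'
#' Tests whether the alternate-allele frequency differs between phenotype
#' classes at a biallelic site, under a binomial model for pooled read
#' counts: reads in each class are Binomial draws at a class frequency, and
#' the statistic is 2 * (log-likelihood at the two ML class frequencies
#' minus log-likelihood at the pooled ML frequency), referred to
#' chi-square with 1 df. The statistic is non-negative, zero exactly when
#' the class frequencies coincide, and symmetric in the class labels.
#'
#' @param case_ref,case_alt Pooled reference/alternate read counts in cases.
#' @param ctrl_ref,ctrl_alt Pooled counts in controls. All four arguments may
#'   be vectors over sites.
#' @return List with `statistic`, `p`, and `usable` (FALSE where a class had
#'   no reads or the pooled site is monomorphic; there `statistic` and `p`
#'   are `NA`).
#' @examples
#' site_lrt(10, 10, 10, 10)$p            # identical frequencies: p = 1
#' site_lrt(0, 20, 20, 0)$statistic      # maximal difference: 2*40*log(2)
#' @export
site_lrt <- function(case_ref, case_alt, ctrl_ref, ctrl_alt) {
  lrt_core(case_ref, case_alt, ctrl_ref, ctrl_alt)
}

#' Run the case-control GWAS over all sites
#'
#' Pools reads within each phenotype class per site and applies the binomial
#' likelihood-ratio test ([site_lrt()]) site by site. Sites with no reads in
#' either class, or monomorphic in the pooled reads, are flagged unusable
#' (`NA` p-value).
#'
#' @param counts An [allele_count_matrix()].
#' @param phenotypes Binary 0/1 vector, one per individual; both classes must
#'   be non-empty.
#' @return Object of class `gwas_result`: list with `p_values`, `lrt_stats`,
#'   `usable`, `site_ids`, `n_case`, `n_ctrl`. `threshold` and `perm_min_p`
#'   are `NULL` until a permutation threshold is attached (see
#'   [permutation_threshold()]).
#' @examples
#' pop <- simulate_population(120, 40, f_pheno = 0.39, seed = 1)
#' rc <- simulate_reads(pop, coverage = 2, seed = 2)
#' res <- run_gwas(as_allele_counts(rc), pop$phenotypes)
#' which.min(res$p_values) == pop$causal_index
#' @export
run_gwas <- function(counts, phenotypes) {
  stopifnot(inherits(counts, "allele_count_matrix"))
  phenotypes <- as.integer(phenotypes)
  if (length(phenotypes) != nrow(counts$ref_counts))
    stop("phenotypes must have one entry per individual")
  if (!all(phenotypes %in% c(0L, 1L)))
    stop("phenotypes must be 0/1")
  if (length(unique(phenotypes)) < 2)
    stop("both phenotype classes must be non-empty")
  case <- phenotypes == 1L
  fit <- lrt_core(colSums(counts$ref_counts[case, , drop = FALSE]),
                  colSums(counts$alt_counts[case, , drop = FALSE]),
                  colSums(counts$ref_counts[!case, , drop = FALSE]),
                  colSums(counts$alt_counts[!case, , drop = FALSE]))
  structure(list(p_values = fit$p, lrt_stats = fit$statistic,
                 usable = fit$usable, site_ids = counts$site_ids,
                 n_case = sum(case), n_ctrl = sum(!case),
                 threshold = NULL, perm_min_p = NULL),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat("Case-control allele-frequency GWAS\n")
  cat(sprintf("  %d sites (%d usable), %d cases / %d controls\n",
              length(x$p_values), sum(x$usable), x$n_case, x$n_ctrl))
  if (any(x$usable)) {
    i <- which.min(x$p_values)
    cat(sprintf("  minimum p = %.3g at %s:%d\n", x$p_values[i],
                x$site_ids$chrom[i], x$site_ids$pos[i]))
  }
  if (!is.null(x$threshold))
    cat(sprintf("  permutation threshold (FWER %.2g, %d permutations): %.3g\n",
                attr(x$threshold, "fwer"), length(x$perm_min_p), x$threshold))
  invisible(x)
}

#' Permutation-based genome-wide significance threshold
#'
#' Calibrates genome-wide significance by permutation: phenotypes are
#' shuffled among individuals uniformly without replacement, the GWAS is
#' re-run, and the minimum p-value recorded, `n_perm` times. The threshold
#' is the empirical lower-`fwer` quantile of the minima, taken as the
#' `ceiling(n_perm * fwer)`-th smallest minimum (inverse-ECDF convention).
#' A true-data p-value less than or equal to the threshold is declared
#' genome-wide significant.
#'
#' @param counts An [allele_count_matrix()].
#' @param phenotypes Binary 0/1 vector.
#' @param n_perm Number of permutations (>= 20; study convention 500).
#' @param fwer Target family-wise error rate (default 0.05).
#' @param seed Integer seed for the shuffles.
#' @return Numeric threshold with attributes `perm_min_p` (the `n_perm`
#'   minima), `fwer` and `n_perm`.
#' @export
permutation_threshold <- function(counts, phenotypes, n_perm = 500L,
                                  fwer = 0.05, seed = NULL) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  if (!is.null(seed)) set.seed(seed)
  phenotypes <- as.integer(phenotypes)
  n <- length(phenotypes)
  ref <- counts$ref_counts; alt <- counts$alt_counts
  tot_ref <- colSums(ref); tot_alt <- colSums(alt)
  # all shuffles at once: per-class pooled counts via crossproducts
  perm <- vapply(seq_len(n_perm), function(b) sample(phenotypes), integer(n))
  cr <- crossprod(ref, perm)   # sites x permutations
  ca <- crossprod(alt, perm)
  fit <- lrt_core(as.vector(cr), as.vector(ca),
                  as.vector(tot_ref - cr), as.vector(tot_alt - ca))
  pmat <- matrix(fit$p, ncol = n_perm)
  minima <- apply(pmat, 2, function(col)
    if (all(is.na(col))) 1 else min(col, na.rm = TRUE))
  k <- ceiling(n_perm * fwer)
  structure(sort(minima)[k], perm_min_p = minima, fwer = fwer,
            n_perm = n_perm)
}
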