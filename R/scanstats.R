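# Per-column summaries of a haplotype window: non-missing count m,
# derived count n1, restricted to columns with >= 2 non-missing alleles.
window_site_counts <- function(window) {
  a <- window$alleles
  m <- colSums(!is.na(a))
  n1 <- colSums(a == 1L, na.rm = TRUE)
  list(m = m, n1 = n1)
}

#' Nucleotide diversity of a haplotype window (ratio of sums)
#'
#' Missing-data-aware pairwise diversity: for each site, the number of
#' allele pairs that differ among non-missing alleles enters the numerator
#' and the number of comparable pairs the denominator; invariant covered
#' sites (`n_monomorphic_covered`) contribute zero differences and full pair
#' counts. Dividing sums (rather than averaging per-site ratios) keeps sites
#' with different call rates correctly weighted. The result is per-site
#' (per-bp) diversity; multiply by the covered length for a window total.
#'
#' @param window A [haplotype_window()].
#' @return Per-site diversity (>= 0), or `NA` if no site has two comparable
#'   alleles.
#' @examples
#' # 4 haplotypes, 100 covered sites, variant sites with derived counts 2, 1
#' w <- haplotype_window(rbind(c(1, 1), c(1, 0), c(0, 0), c(0, 0)),
#'                       positions = c(10, 20), window_length = 100,
#'                       n_monomorphic_covered = 98)
#' pi_window(w)  # (2*2 + 1*3) / (100 * 6) = 7/600
#' @export
pi_window <- function(window) {
  stopifnot(inherits(window, "haplotype_window"))
  n_hap <- nrow(window$alleles)
  sc <- window_site_counts(window)
  diffs <- sum(sc$n1 * (sc$m - sc$n1))
  pairs <- sum(choose(sc$m, 2)) +
    window$n_monomorphic_covered * choose(n_hap, 2)
  if (pairs == 0) return(NA_real_)
  diffs / pairs
}

# Tajima (1989) normalizing constants for sample size n.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D of a haplotype window
#'
#' Normalized difference between mean pairwise diversity and Watterson's
#' estimator over segregating sites, D = (pi_sum - S/a1) /
#' sqrt(e1*S + e2*S*(S-1)) with the classical constants computed from the
#' sample size. Positive values indicate an excess of intermediate-frequency
#' variants, the footprint of balancing selection. Only sites genotyped in
#' every haplotype are used, so the sample size is well-defined; with no
#' segregating site the statistic is undefined (`NA`), not zero.
#'
#' @param window A [haplotype_window()] with at least 4 haplotypes.
#' @return Tajima's D, or `NA` when undefined.
#' @examples
#' w <- haplotype_window(rbind(c(1, 1), c(1, 0), c(0, 0), c(0, 0)),
#'                       positions = c(10, 20), window_length = 100,
#'                       n_monomorphic_covered = 98)
#' tajimas_d(w)  # (7/6 - 2/a1) / sqrt(var term) = 0.5916
#' @export
tajimas_d <- function(window) {
  stopifnot(inherits(window, "haplotype_window"))
  a <- window$alleles
  n <- nrow(a)
  if (n < 4) return(NA_real_)
  complete <- colSums(is.na(a)) == 0
  a <- a[, complete, drop = FALSE]
  n1 <- colSums(a == 1L)
  seg <- n1 > 0 & n1 < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  n1 <- n1[seg]
  pi_sum <- sum(n1 * (n - n1)) / choose(n, 2)
  k <- tajima_constants(n)
  (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Non-central deviation statistic NCD1
#'
#' Root-mean-square deviation of the minor-allele frequencies of the
#' window's segregating sites from a target frequency `tf`:
#' `sqrt(mean((MAF - tf)^2))`. Long-term balancing selection holds allele
#' frequencies near the equilibrium frequency, so windows under balancing
#' selection show small NCD1 (bounded by `max(tf, 1 - tf)`; 0 when every
#' MAF equals `tf`). Uses within-window polymorphic sites only, without an
#' outgroup or fixed differences.
#'
#' @param window A [haplotype_window()].
#' @param tf Target frequency in (0, 0.5] (default 0.3).
#' @return NCD1, or `NA` with no segregating site.
#' @examples
#' w <- haplotype_window(cbind(c(1,0,0,0,0,0,0,0,0,0),
#'                             c(1,1,1,1,1,0,0,0,0,0)),
#'                       positions = c(5, 15), window_length = 100)
#' ncd1(w, tf = 0.3)  # MAFs 0.1, 0.5 -> sqrt((0.04+0.04)/2) = 0.2
#' @export
ncd1 <- function(window, tf = 0.3) {
  stopifnot(inherits(window, "haplotype_window"))
  if (tf <= 0 || tf > 0.5) stop("tf must lie in (0, 0.5]")
  sc <- window_site_counts(window)
  freq <- ifelse(sc$m > 0, sc$n1 / sc$m, NA_real_)
  seg <- !is.na(freq) & freq > 0 & freq < 1
  if (!any(seg)) return(NA_real_)
  maf <- pmin(freq[seg], 1 - freq[seg])
  sqrt(mean((maf - tf)^2))
}
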