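#' Construct a haplotype window
#'
#' Container for a sample of haplotypes over a genomic interval, the input to
#' the balancing-selection statistics [pi_window()], [tajimas_d()] and
#' [ncd1()]. Alleles are coded 0 (ancestral/reference), 1 (derived/alternate)
#' and `NA` (missing). Invariant covered sites are carried only as a count,
#' `n_monomorphic_covered`, which enters the denominator of the ratio-of-sums
#' diversity estimator.
#'
#' @param alleles n_haplotypes x n_sites matrix over {0, 1, NA}.
#' @param positions 1-based site coordinates, strictly increasing, inside
#'   `[window_start, window_start + window_length)`.
#' @param window_start,window_length Window coordinates in bp.
#' @param n_monomorphic_covered Number of invariant sites with calls in all
#'   haplotypes (0 contribution to diversity numerators, full pair counts in
#'   denominators).
#' @return Object of class `haplotype_window`.
#' @export
haplotype_window <- function(alleles, positions, window_start = 1L,
                             window_length, n_monomorphic_covered = 0L) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (length(positions) != ncol(alleles))
    stop("positions must have one entry per column of alleles")
  if (length(positions) && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(positions) &&
      (min(positions) < window_start ||
       max(positions) >= window_start + window_length))
    stop("positions must lie within [window_start, window_start + window_length)")
  if (any(!is.na(alleles) & alleles != 0L & alleles != 1L))
    stop("alleles must be 0, 1 or NA")
  structure(list(alleles = alleles, positions = as.integer(positions),
                 window_start = as.integer(window_start),
                 window_length = as.integer(window_length),
                 n_monomorphic_covered = as.integer(n_monomorphic_covered)),
            class = "haplotype_window")
}

#' @export
print.haplotype_window <- function(x, ...) {
  cat(sprintf("Haplotype window: %d haplotypes, %d variant sites, %d bp at %d\n",
              nrow(x$alleles), ncol(x$alleles), x$window_length, x$window_start))
  cat(sprintf("  invariant covered sites: %d\n", x$n_monomorphic_covered))
  invisible(x)
}

# Single-population Kingman coalescent with infinite-sites mutation.
# Returns a list of derived-carrier index sets, one per segregating site.
# While k lineages remain the waiting time is Exp(k(k-1)/2); each lineage
# accumulates Poisson(theta/2 * t) mutations over an interval of length t.
coalescent_mutation_sets <- function(n_hap, theta) {
  lineages <- as.list(seq_len(n_hap))
  sets <- list()
  k <- n_hap
  while (k >= 2) {
    t_k <- rexp(1, rate = k * (k - 1) / 2)
    n_mut <- rpois(k, theta / 2 * t_k)
    hit <- which(n_mut > 0)
    for (i in hit)
      sets <- c(sets, rep(lineages[i], n_mut[i]))
    pair <- sample.int(k, 2)
    lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages[[pair[2]]] <- NULL
    k <- k - 1
  }
  sets
}

# Lay mutation carrier-sets onto uniform positions within length_bp.
# Infinite sites on a finite grid: positions are distinct (drawn without
# replacement); more segregating sites than base pairs is an error.
sets_to_window <- function(sets, n_hap, length_bp) {
  S <- length(sets)
  if (S > length_bp)
    stop("more segregating sites than base pairs; increase length_bp")
  alleles <- matrix(0L, nrow = n_hap, ncol = S)
  for (j in seq_len(S)) alleles[sets[[j]], j] <- 1L
  pos <- sort(sample.int(length_bp, S))
  haplotype_window(alleles, positions = pos, window_start = 1L,
                   window_length = length_bp,
                   n_monomorphic_covered = length_bp - S)
}

#' Simulate a neutral haplotype window under the coalescent
#'
#' Standard single-population neutral coalescent with infinite-sites
#' mutation: while k lineages remain, coalescence waits Exp(choose(k, 2))
#' (time in units of 2N generations) and each lineage accumulates
#' Poisson(theta/2 * t) mutations. Mutations are placed at distinct uniform
#' positions in the window. The expected number of segregating sites is
#' theta * sum(1/(1:(n_hap-1))).
#'
#' @param n_hap Number of haplotypes sampled (>= 2).
#' @param theta Population-scaled mutation rate 4*N*mu for the whole window
#'   (> 0).
#' @param length_bp Window length in base pairs.
#' @param seed Integer seed.
#' @return A [haplotype_window()] with `n_monomorphic_covered` set to
#'   `length_bp` minus the number of segregating sites.
#' @examples
#' w <- simulate_neutral_window(20, theta = 10, length_bp = 8800, seed = 1)
#' ncol(w$alleles)  # around 10 * sum(1/(1:19)) ~ 35 sites
#' @export
simulate_neutral_window <- function(n_hap, theta, length_bp = 8800L,
                                    seed = NULL) {
  if (n_hap < 2) stop("n_hap must be >= 2")
  if (theta <= 0) stop("theta must be > 0")
  if (!is.null(seed)) set.seed(seed)
  sets <- coalescent_mutation_sets(n_hap, theta)
  sets_to_window(sets, n_hap, length_bp)
}

#' Simulate a haplotype window shaped by long-term balancing selection
#'
#' Structural emulation of an old balanced polymorphism: haplotypes are
#' partitioned into two allelic classes with expected frequencies `tf` and
#' `1 - tf`, neutral coalescent variation is laid over the whole sample, and
#' `Poisson(theta_within * t_split)` additional class-diagnostic sites —
#' mutations accumulated on the internal branch separating the classes over
#' divergence time `t_split` (in units of 2N generations) — are fixed between
#' the classes. The result shows elevated diversity and an excess of
#' intermediate-frequency variants near the class frequency; at
#' `t_split = 0` the generator reduces exactly to
#' [simulate_neutral_window()]. Selection is emulated structurally, not via
#' fitness.
#'
#' @param n_hap Number of haplotypes (>= 2).
#' @param tf Expected frequency of the minor allelic class, in (0, 1).
#' @param theta_within Population-scaled mutation rate of the window.
#' @param t_split Divergence time of the two classes in coalescent units
#'   (total internal branch length is `2 * t_split`). The default 5 emulates
#'   an allelic split far predating the within-class coalescent, as expected
#'   for a polymorphism older than a species split.
#' @param length_bp Window length in bp.
#' @param seed Integer seed.
#' @return A [haplotype_window()]; the class assignment is attached as
#'   attribute `"class_labels"` (1 = minor class).
#' @examples
#' w <- simulate_balanced_window(46, tf = 0.3, theta_within = 5,
#'                               t_split = 3, seed = 1)
#' sum(attr(w, "class_labels"))  # expected 46 * 0.3 = 13.8
#' @export
simulate_balanced_window <- function(n_hap, tf = 0.3, theta_within,
                                     t_split = 5, length_bp = 8800L,
                                     seed = NULL) {
  if (tf <= 0 || tf >= 1) stop("tf must lie in (0, 1)")
  if (t_split < 0) stop("t_split must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    cls <- rbinom(n_hap, 1L, tf)
    if (any(cls == 1L) && any(cls == 0L)) break
  }
  sets <- coalescent_mutation_sets(n_hap, theta_within)
  n_div <- rpois(1, theta_within * t_split)
  if (n_div > 0)
    sets <- c(sets, rep(list(which(cls == 1L)), n_div))
  w <- sets_to_window(sets, n_hap, length_bp)
  attr(w, "class_labels") <- cls
  w
}

#' Write haplotype windows as a minimal VCF
#'
#' Serializes one or more [haplotype_window()]s as a VCF 4.2 file with
#' phased pseudo-diploid genotypes (haplotypes paired in order; a trailing
#' odd haplotype is written haploid). Windows are laid end to end along one
#' chromosome in the order given, each occupying its `window_length`.
#' Only variant sites are written; all statistics here treat unwritten
#' positions as covered and invariant when `assume_invariant_covered = TRUE`
#' in [scan_windows()].
#'
#' @param windows A `haplotype_window` or list of them (equal haplotype
#'   counts).
#' @param path Output file path.
#' @param chrom Chromosome name to write.
#' @return `path`, invisibly.
#' @export
write_windows_vcf <- function(windows, path, chrom = "chr_sim") {
  if (inherits(windows, "haplotype_window")) windows <- list(windows)
  n_hap <- nrow(windows[[1]]$alleles)
  if (any(vapply(windows, function(w) nrow(w$alleles), 0L) != n_hap))
    stop("all windows must contain the same number of haplotypes")
  n_dip <- n_hap %/% 2
  odd <- n_hap %% 2 == 1
  samples <- c(sprintf("ind%03d", seq_len(n_dip)),
               if (odd) sprintf("hap%03d", n_hap))
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s>", chrom),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  offset <- 0L
  for (w in windows) {
    a <- w$alleles
    gt_chr <- matrix(ifelse(is.na(a), ".", as.character(a)),
                     nrow = nrow(a), ncol = ncol(a))
    for (j in seq_len(ncol(a))) {
      gt <- paste(gt_chr[seq_len(n_dip) * 2 - 1, j],
                  gt_chr[seq_len(n_dip) * 2, j], sep = "|")
      if (odd) gt <- c(gt, gt_chr[n_hap, j])
      lines <- c(lines,
                 paste(c(chrom, offset + w$positions[j], ".", "A", "T", ".",
                         "PASS", ".", "GT", gt), collapse = "\t"))
    }
    offset <- offset + w$window_length
  }
  writeLines(lines, path)
  invisible(path)
}
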