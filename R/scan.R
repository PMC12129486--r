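#' Windowed balancing-selection scan over a VCF
#'
#' Tiles a chromosome into non-overlapping windows of `window_bp` base pairs
#' starting at coordinate 1 (half-open `[start, start + window_bp)`) and
#' computes nucleotide diversity ([pi_window()]), Tajima's D ([tajimas_d()])
#' and [ncd1()] in each, together with empirical quantile ranks across
#' windows (upper tail for pi and D, lower tail for NCD1 — the directions in
#' which balancing selection is extreme). Diploid genotypes are split into
#' two pseudo-haplotypes per individual, ignoring phase; all three statistics
#' are phase-free. Undefined statistics propagate as `NA`.
#'
#' @param vcf Path to a VCF 4.2 file, or a `vcfR::vcfR` object.
#' @param chrom Chromosome to scan (default: the first in the file).
#' @param window_bp Window size in bp (default 8800).
#' @param tf NCD1 target frequency (default 0.3).
#' @param assume_invariant_covered If `TRUE` (default), positions without a
#'   VCF record are treated as covered invariant sites, so each window
#'   contributes `window_bp - n_variants` monomorphic sites to the diversity
#'   denominator. If `FALSE`, only variant records enter and per-bp diversity
#'   is not comparable across call rates.
#' @return A data frame of class `window_stats` with columns `chrom`,
#'   `start`, `length_bp`, `n_snps`, `pi`, `tajimas_d`, `ncd1`,
#'   `quantile_pi`, `quantile_d`, `quantile_ncd1`.
#' @export
scan_windows <- function(vcf, chrom = NULL, window_bp = 8800L, tf = 0.3,
                         assume_invariant_covered = TRUE) {
  v <- if (inherits(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(chrom)) chrom <- fix[1, "CHROM"]
  on_chrom <- fix[, "CHROM"] == chrom
  pos <- as.integer(fix[on_chrom, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")[on_chrom, , drop = FALSE]
  hap <- gt_to_haplotypes(gt)          # n_hap x n_records
  ord <- order(pos)
  pos <- pos[ord]; hap <- hap[, ord, drop = FALSE]

  # drop records monomorphic among calls: they are invariant sites
  n1 <- colSums(hap == 1L, na.rm = TRUE)
  m <- colSums(!is.na(hap))
  variant <- m > 0 & n1 > 0 & n1 < m
  inv_pos <- pos[!variant]
  pos <- pos[variant]; hap <- hap[, variant, drop = FALSE]

  n_win <- max(1L, ceiling(max(c(pos, inv_pos, 1L)) / window_bp))
  starts <- (seq_len(n_win) - 1L) * window_bp + 1L
  res <- data.frame(chrom = chrom, start = starts, length_bp = window_bp,
                    n_snps = 0L, pi = NA_real_, tajimas_d = NA_real_,
                    ncd1 = NA_real_)
  win_of <- (pos - 1L) %/% window_bp + 1L
  inv_win <- (inv_pos - 1L) %/% window_bp + 1L
  for (w in seq_len(n_win)) {
    j <- which(win_of == w)
    res$n_snps[w] <- length(j)
    n_inv <- if (assume_invariant_covered) window_bp - length(j)
             else sum(inv_win == w)
    if (length(j) == 0 && n_inv == 0) next
    hw <- haplotype_window(hap[, j, drop = FALSE],
                           positions = pos[j] - starts[w] + 1L,
                           window_start = 1L, window_length = window_bp,
                           n_monomorphic_covered = n_inv)
    res$pi[w] <- pi_window(hw)
    res$tajimas_d[w] <- tajimas_d(hw)
    res$ncd1[w] <- ncd1(hw, tf = tf)
  }
  res$quantile_pi <- quantile_ranks(res$pi, "upper")
  res$quantile_d <- quantile_ranks(res$tajimas_d, "upper")
  res$quantile_ncd1 <- quantile_ranks(res$ncd1, "lower")
  class(res) <- c("window_stats", "data.frame")
  res
}

# Split VCF GT strings (records x samples) into a haplotype matrix
# (haplotypes x records); handles haploid, "/" and "|" separators, "."
# missing. A bare "." from a polyploid sample expands to all-missing.
gt_to_haplotypes <- function(gt) {
  n_rec <- nrow(gt)
  cols <- lapply(seq_len(ncol(gt)), function(s) {
    parts <- strsplit(ifelse(is.na(gt[, s]), ".", gt[, s]), "[/|]")
    lens <- lengths(parts)
    pl <- max(lens)
    short <- lens < pl
    if (any(short)) {
      if (any(vapply(parts[short], function(x) any(x != "."), logical(1))))
        stop("inconsistent ploidy in sample ", colnames(gt)[s])
      parts[short] <- list(rep(".", pl))
    }
    m <- matrix(suppressWarnings(as.integer(unlist(parts))),
                nrow = pl, ncol = n_rec)
    if (any(m > 1, na.rm = TRUE)) stop("only biallelic sites are supported")
    m
  })
  do.call(rbind, cols)
}

#' Empirical tail quantile of a focal value among a set of values
#'
#' The fraction of values at least as extreme as the focal one, with the
#' focal value included in its own tail: upper tail counts
#' `values >= focal`, lower tail `values <= focal`. "Top X%" statements
#' therefore include ties and are conservative.
#'
#' @param focal Finite scalar.
#' @param all_values Non-empty numeric vector (NAs dropped).
#' @param tail `"upper"` or `"lower"`.
#' @return Fraction in (0, 1].
#' @examples
#' empirical_quantile(3, c(1, 2, 3, 4), "upper")  # 2/4
#' @export
empirical_quantile <- function(focal, all_values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  all_values <- all_values[!is.na(all_values)]
  if (!length(all_values)) stop("all_values must be non-empty")
  if (!is.finite(focal)) stop("focal must be finite")
  if (tail == "upper") mean(all_values >= focal) else mean(all_values <= focal)
}

# Vectorized per-element tail ranks (NA in -> NA out).
quantile_ranks <- function(x, tail) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  vals <- x[ok]
  out[ok] <- vapply(vals, empirical_quantile, numeric(1),
                    all_values = vals, tail = tail)
  out
}

#' Restrict scan windows to a recombination-matched subset
#'
#' Keeps the windows whose recombination rate is at or below the
#' `quantile_cut` empirical quantile of all windows' rates (the
#' `ceiling(quantile_cut * N)`-th smallest rate; ties at the threshold are
#' included). Comparing a low-recombination focal window only against
#' windows of comparable recombination rate removes the confounding of
#' diversity statistics by recombination-rate variation.
#'
#' @param stats A `window_stats` data frame from [scan_windows()].
#' @param rho_per_bp Recombination rate per bp for each window, aligned 1:1
#'   with `stats` rows.
#' @param quantile_cut Quantile of the rate distribution to keep
#'   (default 0.08).
#' @return The retained rows of `stats`, with a `rho_per_bp` column added;
#'   quantile ranks are recomputed within the subset.
#' @export
recomb_matched <- function(stats, rho_per_bp, quantile_cut = 0.08) {
  if (length(rho_per_bp) != nrow(stats))
    stop("rho_per_bp must align 1:1 with scan windows")
  if (any(rho_per_bp < 0)) stop("recombination rates must be >= 0")
  thr <- sort(rho_per_bp)[ceiling(quantile_cut * length(rho_per_bp))]
  keep <- rho_per_bp <= thr
  out <- stats[keep, , drop = FALSE]
  out$rho_per_bp <- rho_per_bp[keep]
  out$quantile_pi <- quantile_ranks(out$pi, "upper")
  out$quantile_d <- quantile_ranks(out$tajimas_d, "upper")
  out$quantile_ncd1 <- quantile_ranks(out$ncd1, "lower")
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Read a recombination map aligned to scan windows
#'
#' TSV with columns `chrom`, `window_start`, `rho_per_bp`. Returns the rates
#' matched to the rows of a `window_stats` data frame, erroring on
#' misalignment.
#'
#' @param path TSV path.
#' @param stats A `window_stats` data frame to align against.
#' @return Numeric vector of `rho_per_bp`, one per window.
#' @export
read_recomb_map <- function(path, stats) {
  df <- read.table(path, header = TRUE, sep = "\t")
  i <- match(paste(stats$chrom, stats$start),
             paste(df$chrom, df$window_start))
  if (anyNA(i)) stop("recombination map does not cover every scan window")
  df$rho_per_bp[i]
}
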