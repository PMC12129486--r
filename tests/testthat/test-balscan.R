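test_that("ratio-of-sums diversity matches hand-counted pairs", {
  expect_equal(pi_window(worked_window()), 7 / 600)

  # all haplotypes identical: pi = 0
  mono <- haplotype_window(matrix(0L, 4, 0), positions = integer(0),
                           window_length = 50, n_monomorphic_covered = 50)
  expect_equal(pi_window(mono), 0)

  # a site with exactly 2 non-missing, differing alleles contributes 1/1
  w <- haplotype_window(cbind(c(1L, 0L, NA, NA)), positions = 5L,
                        window_length = 10, n_monomorphic_covered = 0L)
  expect_equal(pi_window(w), 1)

  # zero comparable pairs: undefined
  empty <- haplotype_window(matrix(NA_integer_, 3, 1), positions = 1L,
                            window_length = 10, n_monomorphic_covered = 0L)
  expect_true(is.na(pi_window(empty)))
})

test_that("diversity is invariant to haplotype order and allele relabeling", {
  set.seed(51)
  w <- simulate_neutral_window(12, 5, 3000)
  perm <- sample(12)
  w_perm <- haplotype_window(w$alleles[perm, ], w$positions, w$window_start,
                             w$window_length, w$n_monomorphic_covered)
  w_flip <- haplotype_window(1L - w$alleles, w$positions, w$window_start,
                             w$window_length, w$n_monomorphic_covered)
  expect_equal(pi_window(w_perm), pi_window(w))
  expect_equal(pi_window(w_flip), pi_window(w))
  expect_equal(tajimas_d(w_flip), tajimas_d(w))
  expect_equal(ncd1(w_flip), ncd1(w))
})

test_that("Tajima's D matches the hand-evaluated 4-haplotype case", {
  # derived counts {2, 1} at n = 4: pi_sum = 7/6, theta_W = 2/a1, D = 0.5916
  expect_equal(tajimas_d(worked_window()), 0.59158, tolerance = 1e-4)
  # no segregating site: undefined, not zero
  mono <- haplotype_window(matrix(0L, 5, 0), positions = integer(0),
                           window_length = 100, n_monomorphic_covered = 100)
  expect_true(is.na(tajimas_d(mono)))
  # sites with any missing call are excluded from D
  w <- haplotype_window(cbind(c(1L, 1L, 0L, 0L), c(1L, NA, 0L, 0L)),
                        positions = c(1L, 2L), window_length = 10)
  one_site <- haplotype_window(cbind(c(1L, 1L, 0L, 0L)), positions = 1L,
                               window_length = 10)
  expect_equal(tajimas_d(w), tajimas_d(one_site))
})

test_that("NCD1 measures RMS deviation of MAFs from the target", {
  # MAFs {0.1, 0.5} at tf = 0.3: sqrt((0.04 + 0.04)/2) = 0.2
  w <- haplotype_window(cbind(c(1L, rep(0L, 9)), c(rep(1L, 5), rep(0L, 5))),
                        positions = c(5L, 15L), window_length = 100)
  expect_equal(ncd1(w, tf = 0.3), 0.2)
  # identity cases: all MAFs at the target give exactly 0
  expect_equal(ncd1(w <- haplotype_window(
    cbind(c(1L, 1L, 1L, rep(0L, 7)), c(rep(0L, 7), 1L, 1L, 1L)),
    positions = c(1L, 9L), window_length = 20), tf = 0.3), 0)
  single <- haplotype_window(cbind(c(1L, 1L, 0L, 0L)), positions = 3L,
                             window_length = 10)
  expect_equal(ncd1(single, tf = 0.5), 0)
  # no SNPs: undefined
  mono <- haplotype_window(matrix(1L, 4, 1), positions = 1L,
                           window_length = 10)
  expect_true(is.na(ncd1(mono)))
})

test_that("empirical tail quantiles count the focal value into its tail", {
  expect_equal(empirical_quantile(3, c(1, 2, 3, 4), "upper"), 0.5)
  expect_equal(empirical_quantile(5, c(1:4, 5), "upper"), 1 / 5)
  vals <- runif(999)
  top <- max(vals) + 1
  expect_equal(empirical_quantile(top, c(vals, top), "upper"), 1 / 1000)
  expect_equal(empirical_quantile(3, 1:5, "lower"), 3 / 5)
  expect_error(empirical_quantile(Inf, 1:3), "finite")
})

test_that("recombination matching keeps the low-rho quantile with ties", {
  stats_df <- data.frame(chrom = "c", start = seq(1, by = 8800, length.out = 50),
                         length_bp = 8800, n_snps = 1,
                         pi = runif(50), tajimas_d = rnorm(50),
                         ncd1 = runif(50, 0, 0.3),
                         quantile_pi = NA, quantile_d = NA, quantile_ncd1 = NA)
  class(stats_df) <- c("window_stats", "data.frame")
  rho <- seq_len(50) * 1e-5
  kept <- recomb_matched(stats_df, rho, quantile_cut = 0.08)
  expect_equal(nrow(kept), ceiling(0.08 * 50))
  expect_true(all(kept$rho_per_bp <= sort(rho)[4]))
  # quantile_cut = 1 is the identity filter
  expect_equal(nrow(recomb_matched(stats_df, rho, 1)), 50)
  # ties at the threshold are included
  kept_tie <- recomb_matched(stats_df, rep(7.595e-5, 50), 0.08)
  expect_equal(nrow(kept_tie), 50)
  expect_error(recomb_matched(stats_df, rho[-1]), "align")
})

test_that("VCF scan tiles windows and is invariant to record order", {
  set.seed(52)
  wins <- replicate(10, simulate_neutral_window(20, 5, 8800),
                    simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_windows_vcf(wins, path, chrom = "chr2")
  res <- scan_windows(path, chrom = "chr2", window_bp = 8800)
  expect_equal(nrow(res), 10)
  expect_equal(res$start, seq(1, by = 8800, length.out = 10))
  expect_equal(res$n_snps,
               vapply(wins, function(w) ncol(w$alleles), 0L))
  # per-window statistics agree with direct evaluation on the source windows
  expect_equal(res$pi, vapply(wins, pi_window, 0), tolerance = 1e-12)
  expect_equal(res$tajimas_d, vapply(wins, tajimas_d, 0), tolerance = 1e-12)
  expect_equal(res$ncd1, vapply(wins, function(w) ncd1(w, 0.3), 0),
               tolerance = 1e-12)

  # shuffling record order leaves the scan unchanged
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  set.seed(53)
  shuffled <- c(lines[hdr], sample(lines[!hdr]))
  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(shuffled, path2)
  res2 <- scan_windows(path2, chrom = "chr2", window_bp = 8800)
  expect_equal(res2, res)
})

test_that("scan handles missing calls and empty windows", {
  set.seed(54)
  w <- simulate_neutral_window(20, 5, 8800)
  # mask a couple of reference calls per column, keeping every site variant
  for (j in seq_len(min(5, ncol(w$alleles)))) {
    zeros <- which(w$alleles[, j] == 0L)
    w$alleles[zeros[1:2], j] <- NA_integer_
  }
  gap <- haplotype_window(matrix(integer(0), 20, 0), integer(0),
                          window_length = 8800,
                          n_monomorphic_covered = 8800L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_windows_vcf(list(w, gap, w), path, chrom = "chrM")
  res <- scan_windows(path, chrom = "chrM", window_bp = 8800)
  expect_equal(nrow(res), 3)
  expect_equal(res$pi[2], 0)            # covered but invariant
  expect_true(is.na(res$tajimas_d[2]))  # no SNPs: undefined
  expect_equal(res$pi[1], pi_window(w), tolerance = 1e-12)
  expect_equal(res$quantile_pi[1], empirical_quantile(res$pi[1], res$pi, "upper"))
})
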