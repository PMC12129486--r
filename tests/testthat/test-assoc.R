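test_that("site LRT matches closed forms and is symmetric and non-negative", {
  eq <- site_lrt(10, 10, 10, 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)

  split <- site_lrt(0, 20, 20, 0)
  expect_equal(split$statistic, -2 * 40 * log(0.5), tolerance = 1e-12)
  expect_equal(split$p, pchisq(80 * log(2), 1, lower.tail = FALSE))

  # label symmetry and non-negativity over random tables
  set.seed(31)
  for (i in 1:50) {
    cnt <- rpois(4, 8)
    a <- site_lrt(cnt[1], cnt[2], cnt[3], cnt[4])
    b <- site_lrt(cnt[3], cnt[4], cnt[1], cnt[2])
    if (!is.na(a$statistic)) {
      expect_gte(a$statistic, 0)
      expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    }
  }
  # zero reads in one class: flagged, not fabricated
  expect_true(is.na(site_lrt(0, 0, 10, 5)$p))
  expect_false(site_lrt(0, 0, 10, 5)$usable)
})

test_that("run_gwas flags monomorphic sites and validates phenotypes", {
  ref <- matrix(2L, 10, 3); alt <- matrix(0L, 10, 3)
  counts <- allele_count_matrix(ref, alt)
  ph <- rep(c(0L, 1L), 5)
  res <- run_gwas(counts, ph)
  expect_true(all(is.na(res$p_values)))
  expect_false(any(res$usable))
  expect_error(run_gwas(counts, rep(1L, 10)), "classes")
  expect_error(run_gwas(counts, ph[-1]), "individual")
})

test_that("LRT p-values are calibrated when reads are independent", {
  # one read per individual: pooled reads are iid Bernoulli(p), the LRT's
  # model holds exactly and null p-values are uniform
  set.seed(32)
  n <- 400; L <- 4000
  freq <- runif(L, 0.05, 0.5)
  g <- matrix(rbinom(n * L, 2L, rep(freq, each = n)), n, L)
  alt <- matrix(rbinom(n * L, 1L, as.vector(g) / 2), n, L)
  counts <- allele_count_matrix(1L - alt, alt)
  ph <- rbinom(n, 1L, 0.39)
  res <- run_gwas(counts, ph)
  p <- res$p_values[res$usable]
  expect_gt(length(p), 3500)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("clustered reads overdisperse the pooled-count LRT", {
  # reads from the same individual share its genotype (correlation 0.5), so
  # pooling multi-read cells inflates the statistic: the null rejection rate
  # exceeds alpha, which is why genome-wide significance is calibrated by
  # permutation rather than by the chi-square tail
  pop <- simulate_population(200, 3000, f_pheno = 0.39, causal_index = NA,
                             seed = 33)
  rc <- simulate_reads(pop, coverage = 4, seed = 34)
  res <- run_gwas(as_allele_counts(rc), pop$phenotypes)
  p <- res$p_values[res$usable]
  expect_gt(mean(p < 0.05), 0.06)
})

test_that("permutation threshold follows the inverse-ECDF order statistic", {
  pop <- simulate_population(60, 100, f_pheno = 0.39, causal_index = NA,
                             seed = 34)
  rc <- simulate_reads(pop, coverage = 0.5, seed = 35)
  counts <- as_allele_counts(rc)
  thr <- permutation_threshold(counts, pop$phenotypes, n_perm = 40,
                               fwer = 0.05, seed = 36)
  minima <- attr(thr, "perm_min_p")
  expect_length(minima, 40)
  expect_equal(as.numeric(thr), sort(minima)[ceiling(40 * 0.05)])
  expect_error(permutation_threshold(counts, pop$phenotypes, n_perm = 10),
               "n_perm")
})

test_that("pseudo-haploid calls sample reads uniformly and preserve frequency", {
  # a cell with 3 ref / 1 alt reads is called alt with probability 1/4
  counts <- allele_count_matrix(matrix(3L, 2000, 1), matrix(1L, 2000, 1))
  ph <- pseudo_haploid(counts, seed = 37)
  expect_lt(abs(mean(ph$calls) - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
  # zero-read cells are missing; fixed cells deterministic
  counts2 <- allele_count_matrix(rbind(c(0L, 5L), c(2L, 0L)),
                                 rbind(c(0L, 0L), c(1L, 3L)))
  ph2 <- pseudo_haploid(counts2, seed = 38)
  expect_true(is.na(ph2$calls[1, 1]))
  expect_identical(ph2$calls[1, 2], 0L)
  # reproducibility
  expect_identical(pseudo_haploid(counts2, seed = 5)$calls,
                   pseudo_haploid(counts2, seed = 5)$calls)
})

test_that("call filtering applies the documented boundary semantics", {
  # 100 individuals; site 1: 1 alt / 99 ref (MAF 0.01 < 0.02, removed);
  # site 2: missing in 80 (>= 0.75, removed);
  # site 3: MAF exactly at the 0.02 cutoff (retained: removal is strict <)
  calls <- matrix(0L, 100, 3)
  calls[1, 1] <- 1L
  calls[1:80, 2] <- NA
  calls[1:50, 3] <- NA
  calls[51, 3] <- 1L  # MAF 1/50 = 0.02, missing 0.50: both inside
  ph <- structure(list(calls = calls,
                       site_ids = data.frame(chrom = "c", pos = 1:3),
                       seed = NULL), class = "pseudo_haploid_calls")
  kept <- filter_calls(ph, maf_min = 0.02, max_missing = 0.75)
  expect_identical(kept$site_ids$pos, 3L)
  expect_warning(filter_calls(ph, maf_min = 0.6), "removed")
})

test_that("PC-corrected association recovers the causal site", {
  # imperfect penetrance and read error keep the causal site informative
  # without complete separation (which is flagged, not reported)
  pop <- simulate_population(300, 60, f_pheno = 0.39, penetrance = 0.85,
                             seed = 39)
  rc <- simulate_reads(pop, coverage = 4, error_rate = 0.02, seed = 40)
  ph <- pseudo_haploid(as_allele_counts(rc), seed = 41)
  p4 <- covariate_association(ph, pop$phenotypes, n_pcs = 4)
  expect_identical(which.min(p4), pop$causal_index)
  # n_pcs = 0 reduces to single-predictor logistic regression
  p0 <- covariate_association(ph, pop$phenotypes, n_pcs = 0)
  j <- 3
  fit <- glm(pop$phenotypes[!is.na(ph$calls[, j])] ~
               ph$calls[!is.na(ph$calls[, j]), j], family = binomial())
  expect_equal(p0[j], summary(fit)$coefficients[2, 4], tolerance = 1e-10)
})

test_that("pairwise r2 matches hand correlations and flags monomorphic sites", {
  m <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1), c = c(0, 0, 1, 1),
             d = c(1, 1, 1, 1))
  r2 <- pairwise_r2(m, focal_site = 1)
  expect_equal(unname(r2["1"]), 1)
  expect_equal(unname(r2["2"]), 0)
  expect_equal(unname(r2["3"]), 1)
  expect_true(is.na(r2["4"]))
  # independent sites at large n: r2 near zero
  set.seed(42)
  big <- cbind(rbinom(4000, 1, 0.4), rbinom(4000, 1, 0.4))
  expect_lt(pairwise_r2(big, 1)["2"], 0.005)
  # window restriction by position
  r2w <- pairwise_r2(m, 1, positions = c(0, 100, 5e6, 200), window_bp = 1e6)
  expect_identical(names(r2w), c("1", "2", "4"))
})
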