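#' Pseudo-haploid genotype calls from read counts
#'
#' For each individual and site, samples one read uniformly among the reads
#' covering that cell and assigns the allele supported by it; cells with no
#' reads are missing. This "pseudo-haploid" coding removes the depth-driven
#' heterozygote bias of low-coverage genotype calls and is the standard input
#' for PCA-based structure checks on shallow data. Expected call frequency at
#' a site equals the read-level allele frequency.
#'
#' @param counts An [allele_count_matrix()].
#' @param seed Integer seed.
#' @return Object of class `pseudo_haploid_calls`: list with `calls`
#'   (n x L matrix, 0 = ref, 1 = alt, NA = no coverage), `site_ids`, `seed`.
#' @examples
#' pop <- simulate_population(50, 10, f_pheno = 0.39, seed = 1)
#' rc <- simulate_reads(pop, coverage = 0.35, seed = 2)
#' ph <- pseudo_haploid(as_allele_counts(rc), seed = 3)
#' mean(is.na(ph$calls))  # ~ exp(-0.35)
#' @export
pseudo_haploid <- function(counts, seed = NULL) {
  stopifnot(inherits(counts, "allele_count_matrix"))
  if (!is.null(seed)) set.seed(seed)
  ref <- counts$ref_counts; alt <- counts$alt_counts
  depth <- ref + alt
  calls <- matrix(NA_integer_, nrow(ref), ncol(ref))
  cov <- depth > 0
  # the sampled read is alt with probability alt/(alt+ref)
  calls[cov] <- rbinom(sum(cov), 1L, alt[cov] / depth[cov])
  structure(list(calls = calls, site_ids = counts$site_ids, seed = seed),
            class = "pseudo_haploid_calls")
}

#' @export
print.pseudo_haploid_calls <- function(x, ...) {
  cat(sprintf("Pseudo-haploid calls: %d individuals x %d sites, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Filter pseudo-haploid calls on minor allele frequency and missingness
#'
#' Removes sites with minor allele frequency below `maf_min` (computed over
#' non-missing calls) or with a missing-call fraction of `max_missing` or
#' more. Boundary semantics: a site is removed iff `MAF < maf_min` (strict)
#' or `missing fraction >= max_missing`; sites exactly at the MAF cutoff are
#' retained. Individuals are never removed.
#'
#' @param calls A `pseudo_haploid_calls` object.
#' @param maf_min Minimum minor allele frequency (default 0.02).
#' @param max_missing Missing-fraction cutoff (default 0.75).
#' @return A filtered `pseudo_haploid_calls`; warns if no site survives.
#' @export
filter_calls <- function(calls, maf_min = 0.02, max_missing = 0.75) {
  stopifnot(inherits(calls, "pseudo_haploid_calls"))
  m <- calls$calls
  miss <- colMeans(is.na(m))
  freq <- colMeans(m, na.rm = TRUE)
  freq[is.nan(freq)] <- 0
  maf <- pmin(freq, 1 - freq)
  keep <- maf >= maf_min & miss < max_missing
  if (!any(keep)) warning("all sites removed by the MAF/missingness filter")
  structure(list(calls = m[, keep, drop = FALSE],
                 site_ids = calls$site_ids[keep, , drop = FALSE],
                 seed = calls$seed),
            class = "pseudo_haploid_calls")
}

#' Structure-corrected per-site association
#'
#' Logistic regression of the binary phenotype on each site's pseudo-haploid
#' call with the leading principal components of the call matrix as
#' covariates. The PCA is computed once on the per-site mean-imputed,
#' centered call matrix; the reported p-value is the Wald test of the call
#' coefficient. Sites where the model is degenerate (monomorphic calls,
#' complete separation) are flagged `NA` rather than given a fabricated
#' p-value.
#'
#' @param calls A `pseudo_haploid_calls` object (typically after
#'   [filter_calls()]).
#' @param phenotypes Binary 0/1 vector.
#' @param n_pcs Number of principal components to include (default 4;
#'   0 reduces to single-predictor logistic regression).
#' @return Numeric vector of per-site p-values (NA where flagged), with the
#'   PC scores in attribute `"pcs"`.
#' @export
covariate_association <- function(calls, phenotypes, n_pcs = 4L) {
  stopifnot(inherits(calls, "pseudo_haploid_calls"))
  m <- calls$calls
  phenotypes <- as.integer(phenotypes)
  if (length(phenotypes) != nrow(m))
    stop("phenotypes must have one entry per individual")
  imp <- m
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(imp))
  imp[idx] <- mu[(idx - 1L) %/% nrow(imp) + 1L]
  imp <- sweep(imp, 2, mu)
  pcs <- if (n_pcs > 0) {
    pr <- prcomp(imp, center = FALSE)
    pr$x[, seq_len(min(n_pcs, ncol(pr$x))), drop = FALSE]
  } else NULL

  p <- rep(NA_real_, ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) next
    dat <- data.frame(y = phenotypes[ok], x = x[ok])
    X <- if (is.null(pcs)) dat else cbind(dat, pcs[ok, , drop = FALSE])
    fit <- suppressWarnings(glm(y ~ ., data = X, family = binomial()))
    co <- summary(fit)$coefficients
    if (!"x" %in% rownames(co)) next
    # huge SE signals (quasi-)separation: flag rather than report
    if (!fit$converged || co["x", "Std. Error"] > 50) next
    p[j] <- co["x", "Pr(>|z|)"]
  }
  attr(p, "pcs") <- pcs
  p
}

#' Pairwise linkage disequilibrium (r-squared) around a focal site
#'
#' Composite LD: r^2 is the squared Pearson correlation of the call/dosage
#' vectors of the focal site and each partner site, over individuals
#' non-missing at both. Partner sites monomorphic among the shared
#' individuals have undefined r^2 and are returned `NA`.
#'
#' @param mat Numeric matrix of calls or dosages, individuals x sites
#'   (NA = missing), or a `pseudo_haploid_calls` object.
#' @param focal_site Column index of the focal site.
#' @param positions Optional site positions (bp); with `window_bp`, restricts
#'   partners to `abs(pos - pos[focal]) <= window_bp`.
#' @param window_bp Window half-width in bp (default 1e6).
#' @return Named numeric vector of r^2 values indexed by site column, focal
#'   site included (r^2 = 1).
#' @examples
#' m <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
#' pairwise_r2(m, 1)["2"]  # independent columns: 0
#' @export
pairwise_r2 <- function(mat, focal_site, positions = NULL, window_bp = 1e6) {
  if (inherits(mat, "pseudo_haploid_calls")) {
    positions <- if (is.null(positions)) mat$site_ids$pos else positions
    mat <- mat$calls
  }
  mat <- as.matrix(mat)
  if (focal_site < 1 || focal_site > ncol(mat)) stop("focal_site out of range")
  partners <- seq_len(ncol(mat))
  if (!is.null(positions))
    partners <- partners[abs(positions - positions[focal_site]) <= window_bp]
  x <- mat[, focal_site]
  r2 <- vapply(partners, function(j) {
    ok <- !is.na(x) & !is.na(mat[, j])
    if (sum(ok) < 2) return(NA_real_)
    xv <- x[ok]; yv <- mat[ok, j]
    if (stats::var(xv) == 0 || stats::var(yv) == 0) return(NA_real_)
    cor(xv, yv)^2
  }, numeric(1))
  names(r2) <- partners
  r2
}
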