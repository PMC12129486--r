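#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether preference differences are centered at `mu0`. Zero
#' differences are dropped before ranking (classical convention); ties in
#' the absolute values receive average ranks. The two-sided p-value is exact
#' (enumeration of the signed-rank null distribution) for n <= 25 with no
#' ties, and otherwise uses the normal approximation with continuity and
#' tie correction — the behaviour of [stats::wilcox.test()], which performs
#' the computation.
#'
#' @param x Numeric vector (length >= 1 after removing values equal to
#'   `mu0`).
#' @param mu0 Null center (default 0).
#' @return List with `W` (sum of positive signed ranks), `p`, `exact`
#'   (whether the exact distribution was used) and `degenerate` (`TRUE`,
#'   with p = 1, when every value equals `mu0`).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))$p   # exact: 2/8
#' wilcoxon_signed_rank(c(1, -2))$p     # exact: 1
#' @export
wilcoxon_signed_rank <- function(x, mu0 = 0) {
  d <- x[x != mu0]
  if (!length(d))
    return(list(W = 0, p = 1, exact = TRUE, degenerate = TRUE))
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 25 && !ties
  res <- suppressWarnings(
    wilcox.test(d, mu = mu0, exact = exact, correct = TRUE))
  list(W = unname(res$statistic), p = res$p.value, exact = exact,
       degenerate = FALSE)
}

# Fast exact two-sided signed-rank p for tie-free data, replicating the
# wilcox.test convention: double the smaller tail, capped at 1.
signrank_p_exact <- function(W, n) {
  half <- n * (n + 1) / 4
  ifelse(W > half,
         pmin(1, 2 * psignrank(W - 1, n, lower.tail = FALSE)),
         pmin(1, 2 * psignrank(W, n)))
}

#' Simulated power of the Wilcoxon test for a preference effect
#'
#' Draws `n_reps` datasets of `n` preference differences from
#' Normal(`effect`, `sd`) and reports the fraction in which a two-sided
#' Wilcoxon signed-rank test rejects at level `alpha` (strict `p < alpha`).
#' At `effect = 0` this returns the attained size of the discrete exact
#' test, slightly below `alpha` at small `n`. Draws are plain normals
#' (no truncation); [simulate_trials()] provides the truncating generator
#' when simulating bounded preference scores themselves.
#'
#' @param effect True mean preference difference.
#' @param sd Standard deviation (> 0).
#' @param n Individuals per dataset (>= 2).
#' @param alpha Test level (default 0.05).
#' @param n_reps Replicates (default 10000).
#' @param seed Integer seed.
#' @return The power (fraction of rejections).
#' @examples
#' power_simulation(0.4, sd = 0.2, n = 17, n_reps = 200, seed = 1)
#' @export
power_simulation <- function(effect, sd, n, alpha = 0.05, n_reps = 10000L,
                             seed = NULL) {
  if (sd <= 0) stop("sd must be > 0")
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(n_reps * n), nrow = n_reps)
  mean(reject_matrix(effect + sd * z, alpha))
}

# Vectorized rejection indicator per row of a tie-free normal draw matrix:
# exact signed-rank p via psignrank (identical to wilcox.test for
# continuous data), normal approximation above n = 25.
reject_matrix <- function(x, alpha) {
  n <- ncol(x)
  if (n <= 25) {
    W <- apply(x, 1, function(r) sum(rank(abs(r))[r > 0]))
    signrank_p_exact(W, n) < alpha
  } else {
    apply(x, 1, function(r) wilcoxon_signed_rank(r)$p < alpha)
  }
}

#' Power curve over a grid of preference effect sizes
#'
#' [power_simulation()] applied across an effect grid with common random
#' numbers: one set of standardized draws is shared by every grid point, so
#' the curve is smooth in the effect and pointwise comparisons across grids
#' or sample sizes with the same seed are paired.
#'
#' @param n Individuals per dataset.
#' @param sd Standard deviation of the preference difference.
#' @param grid Effect sizes (default `seq(0, 0.4, by = 0.025)`, 17 points).
#' @param alpha Test level (default 0.05).
#' @param n_reps Replicates per grid point (default 10000).
#' @param seed Integer seed.
#' @param group_label Free-text label carried into the result.
#' @return Object of class `power_curve`: data frame with columns `effect`
#'   and `power`, and attributes `n`, `sd`, `alpha`, `n_reps`, `seed`,
#'   `group_label`.
#' @examples
#' pc <- power_curve(n = 17, sd = 0.25, n_reps = 200, seed = 1)
#' head(pc)
#' @export
power_curve <- function(n, sd, grid = seq(0, 0.4, by = 0.025), alpha = 0.05,
                        n_reps = 10000L, seed = NULL, group_label = "") {
  if (!length(grid)) stop("grid must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(n_reps * n), nrow = n_reps)
  power <- vapply(grid, function(effect)
    mean(reject_matrix(effect + sd * z, alpha)), numeric(1))
  structure(data.frame(effect = grid, power = power),
            n = n, sd = sd, alpha = alpha, n_reps = n_reps, seed = seed,
            group_label = group_label,
            class = c("power_curve", "data.frame"))
}

#' @export
print.power_curve <- function(x, ...) {
  lbl <- attr(x, "group_label")
  cat(sprintf("Wilcoxon power curve%s: n = %d, sd = %.3g, alpha = %.3g, %d reps\n",
              if (nzchar(lbl)) paste0(" [", lbl, "]") else "",
              attr(x, "n"), attr(x, "sd"), attr(x, "alpha"), attr(x, "n_reps")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @param y Ignored.
#' @rdname power_curve
#' @export
plot.power_curve <- function(x, y, ...) {
  plot(x$effect, x$power, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "effect size (difference in proportion of trial time)",
       ylab = "power", ...)
  invisible(x)
}
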