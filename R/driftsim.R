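#' Piecewise-constant demographic schedule
#'
#' An ordered set of (generation-before-present, Ne) segments, the form in
#' which scaled PSMC output describes a population's history. Segment i
#' applies from its start generation (exclusive of the next segment's start)
#' down toward the present; the most recent segment runs to generation 1
#' unless recent segments have been cut with [truncate_recent()]. Effective
#' sizes are rounded to the nearest integer >= 1 when the binomial sampler
#' consumes them.
#'
#' @param generation Segment start times in generations before present,
#'   strictly decreasing (oldest first).
#' @param Ne Diploid effective sizes, one per segment, all > 0.
#' @param mutation_rate Per-site per-generation mutation rate, kept for
#'   scaling helpers (default 3.5e-9).
#' @param generation_time_years Generation time used when converting
#'   schedules from years (default 0.5).
#' @return Object of class `demography_schedule`.
#' @examples
#' sch <- demography_schedule(generation = c(5000, 2000, 500),
#'                            Ne = c(10000, 300, 10000))
#' @export
demography_schedule <- function(generation, Ne, mutation_rate = 3.5e-9,
                                generation_time_years = 0.5) {
  generation <- as.numeric(generation); Ne <- as.numeric(Ne)
  if (length(generation) != length(Ne))
    stop("generation and Ne must have equal length")
  if (any(diff(generation) >= 0))
    stop("generation must be strictly decreasing toward the present")
  if (any(Ne <= 0)) stop("Ne must be > 0")
  structure(list(generation = generation, Ne = Ne,
                 end_generation = 0,
                 mutation_rate = mutation_rate,
                 generation_time_years = generation_time_years),
            class = "demography_schedule")
}

#' @export
print.demography_schedule <- function(x, ...) {
  cat(sprintf("Demographic schedule: %d segments, %s to %s generations BP\n",
              length(x$generation), format(max(x$generation), big.mark = ","),
              format(x$end_generation, big.mark = ",")))
  cat(sprintf("  Ne range %s - %s\n", format(round(min(x$Ne)), big.mark = ","),
              format(round(max(x$Ne)), big.mark = ",")))
  invisible(x)
}

#' Read a demographic schedule from TSV
#'
#' Columns `generation_before_present` and `Ne`, one row per segment,
#' oldest first.
#'
#' @param path TSV path.
#' @param ... Passed to [demography_schedule()].
#' @return A `demography_schedule`.
#' @export
read_schedule <- function(path, ...) {
  df <- read.table(path, header = TRUE, sep = "\t")
  demography_schedule(df$generation_before_present, df$Ne, ...)
}

#' Drop the most recent segments of a schedule
#'
#' Demographic inference is unreliable in the most recent time segments, so
#' simulations conventionally exclude them; removing the `n_segments` most
#' recent segments shortens the simulated span by the generations they
#' covered (the simulation then stops that many generations before the
#' present).
#'
#' @param schedule A `demography_schedule`.
#' @param n_segments Number of most-recent segments to remove (default 4).
#' @return The truncated schedule, with its `end_generation` advanced.
#' @export
truncate_recent <- function(schedule, n_segments = 4L) {
  stopifnot(inherits(schedule, "demography_schedule"))
  if (n_segments == 0) return(schedule)
  k <- length(schedule$generation)
  if (k <= n_segments)
    stop("schedule must have more segments than are removed")
  keep <- seq_len(k - n_segments)
  schedule$end_generation <- schedule$generation[k - n_segments + 1]
  schedule$generation <- schedule$generation[keep]
  schedule$Ne <- schedule$Ne[keep]
  schedule
}

# Expand a schedule into the per-generation diploid N sequence, oldest
# generation first, stopping end_generation generations before the present.
schedule_ne_vector <- function(schedule) {
  g <- schedule$generation
  ends <- c(g[-1], schedule$end_generation)
  durations <- g - ends
  rep(pmax(1L, as.integer(round(schedule$Ne))), times = durations)
}

#' Expected allele frequency of a fully dominant trait
#'
#' Under Hardy-Weinberg equilibrium a fully dominant, fully penetrant allele
#' at frequency d produces the phenotype at frequency f = 1 - (1-d)^2, so
#' d = 1 - sqrt(1 - f). Converts observed phenotype frequencies into the
#' starting allele frequencies of the retention simulations.
#'
#' @param f_pheno Phenotype frequency in [0, 1].
#' @return Allele frequency in [0, 1].
#' @examples
#' dominant_freq(0.39)  # 0.2190
#' dominant_freq(0.24)  # 0.1282
#' @export
dominant_freq <- function(f_pheno) {
  if (any(f_pheno < 0 | f_pheno > 1)) stop("f_pheno must lie in [0, 1]")
  1 - sqrt(1 - f_pheno)
}

#' Single neutral Wright-Fisher run under a demographic schedule
#'
#' Tracks one biallelic locus from the oldest retained segment toward the
#' present: each generation in a segment of diploid size N draws the new
#' allele count Binomial(2N, p), with no recurrent mutation; the run stops
#' early once the allele fixes or is lost.
#'
#' @param schedule A `demography_schedule`.
#' @param p0 Starting allele frequency in [0, 1].
#' @param seed Integer seed.
#' @param keep_trajectory If `TRUE`, also return the frequency path.
#' @return List with `outcome` (`"lost"`, `"fixed"` or `"segregating"`),
#'   `final_freq`, `generations_run`, and optionally `trajectory`.
#' @export
wf_run <- function(schedule, p0, seed = NULL, keep_trajectory = FALSE) {
  stopifnot(inherits(schedule, "demography_schedule"))
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ne <- schedule_ne_vector(schedule)
  p <- p0
  traj <- if (keep_trajectory) numeric(length(ne)) else NULL
  gens <- 0L
  for (t in seq_along(ne)) {
    if (p <= 0 || p >= 1) break
    two_n <- 2L * ne[t]
    p <- rbinom(1L, two_n, p) / two_n
    gens <- t
    if (keep_trajectory) traj[t] <- p
  }
  outcome <- if (p <= 0) "lost" else if (p >= 1) "fixed" else "segregating"
  out <- list(outcome = outcome, final_freq = p, generations_run = gens)
  if (keep_trajectory) out$trajectory <- traj[seq_len(gens)]
  out
}

#' Probability that a neutral polymorphism is retained under drift
#'
#' Replicated neutral Wright-Fisher simulation under a demographic schedule:
#' each replicate starts at frequency `p0` and evolves by binomial sampling
#' through the schedule; the polymorphism is "retained" when both alleles
#' are still present at the final simulated generation. All replicates
#' advance in lock-step on one seeded stream (absorbed replicates drop out),
#' so results are bit-reproducible given (schedule, p0, n_reps, seed).
#'
#' @param schedule A `demography_schedule`.
#' @param p0 Starting allele frequency in (0, 1) (use [dominant_freq()] to
#'   derive it from a phenotype frequency).
#' @param n_reps Number of replicates (study convention 10000).
#' @param seed Integer seed.
#' @return Object of class `retention_result`: counts of segregating, fixed
#'   and lost replicates, `retention_prob` with binomial standard error
#'   `se`, `p0`, `n_reps`, `seed`.
#' @examples
#' sch <- demography_schedule(c(200, 50), c(50, 50))
#' retention_probability(sch, p0 = 0.3, n_reps = 500, seed = 1)
#' @export
retention_probability <- function(schedule, p0, n_reps = 10000L, seed = NULL) {
  stopifnot(inherits(schedule, "demography_schedule"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ne <- schedule_ne_vector(schedule)
  p <- rep(p0, n_reps)
  active <- p > 0 & p < 1
  for (t in seq_along(ne)) {
    if (!any(active)) break
    two_n <- 2L * ne[t]
    p[active] <- rbinom(sum(active), two_n, p[active]) / two_n
    active[active] <- p[active] > 0 & p[active] < 1
  }
  n_seg <- sum(p > 0 & p < 1)
  n_fixed <- sum(p >= 1)
  retention <- n_seg / n_reps
  structure(list(n_reps = as.integer(n_reps), n_segregating = n_seg,
                 n_fixed = n_fixed, n_lost = n_reps - n_seg - n_fixed,
                 retention_prob = retention,
                 se = sqrt(retention * (1 - retention) / n_reps),
                 p0 = p0, seed = seed),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat("Neutral Wright-Fisher retention simulation\n")
  cat(sprintf("  %d replicates from p0 = %.4f\n", x$n_reps, x$p0))
  cat(sprintf("  retained polymorphic: %.2f%% (+/- %.2f%%), fixed %.2f%%, lost %.2f%%\n",
              100 * x$retention_prob, 100 * x$se,
              100 * x$n_fixed / x$n_reps, 100 * x$n_lost / x$n_reps))
  invisible(x)
}
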