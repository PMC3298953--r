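# Stochastic supplementation demography: truncated-normal parameter draws,
# yearly age-structured bookkeeping of the supplemented ewes and their
# hybrid descendants, Leslie-matrix stable-age adjustment, the expected-
# hybrid window, and the accepted-run lamb-survival interval.

#' Age-specific demographic parameters
#'
#' Stage-structured survival and fecundity means and standard deviations
#' for bighorn ewes. Survival is the probability of the transition into
#' the listed ages; fecundity is the probability a ewe of that age
#' produces a lamb. Defaults are the study's long-term literature values.
#'
#' @param survival data.frame with columns `into_ages` (list of integer
#'   vectors), `mean`, `sd`.
#' @param fecundity data.frame with columns `ages`, `mean`, `sd`.
#' @param max_age Maximum attainable age; individuals past it die.
#' @param fecundity_mapping `"age_at_lambing"` (default: the table's age
#'   column is the ewe's age in the year she lambs) or `"shift"` (the
#'   alternative reading, shifted one class younger).
#' @return `demographic_params` list with expanded per-age vectors
#'   `s` (survival into ages 1..max_age) and `f` (fecundity at ages
#'   0..max_age), plus the stage tables.
#' @export
demographic_params <- function(
    survival = data.frame(stage = c("lamb", "yearling", "adult", "old_adult", "past_prime"),
                          from = c(1L, 2L, 3L, 8L, 14L),
                          to = c(1L, 2L, 7L, 13L, 16L),
                          mean = c(0.450, 0.825, 0.940, 0.875, 0.600),
                          sd = c(0.1500, 0.0625, 0.0200, 0.0375, 0.1000)),
    fecundity = data.frame(stage = c("lamb", "yearling", "adult", "past_prime"),
                           from = c(1L, 2L, 3L, 14L),
                           to = c(1L, 2L, 13L, 16L),
                           mean = c(0, 0.300, 0.950, 0.400),
                           sd = c(0, 0.0125, 0.00625, 0.0125)),
    max_age = 16L,
    fecundity_mapping = c("age_at_lambing", "shift")) {
  fecundity_mapping <- match.arg(fecundity_mapping)
  stopifnot(all(survival$mean >= 0), all(survival$sd >= 0),
            all(fecundity$mean >= 0), all(fecundity$sd >= 0))
  s <- s_sd <- rep(NA_real_, max_age)       # survival into age a
  s_stage <- integer(max_age)
  for (i in seq_len(nrow(survival)))
    for (a in survival$from[i]:survival$to[i]) {
      s[a] <- survival$mean[i]; s_sd[a] <- survival$sd[i]; s_stage[a] <- i
    }
  f <- f_sd <- rep(0, max_age + 1L)         # fecundity at age 0..max_age
  f_stage <- integer(max_age + 1L)
  for (i in seq_len(nrow(fecundity)))
    for (a in fecundity$from[i]:fecundity$to[i]) {
      f[a + 1L] <- fecundity$mean[i]; f_sd[a + 1L] <- fecundity$sd[i]
      f_stage[a + 1L] <- i
    }
  if (fecundity_mapping == "shift") {
    f <- c(f[-1L], f[length(f)])
    f_sd <- c(f_sd[-1L], f_sd[length(f_sd)])
    f_stage <- c(f_stage[-1L], f_stage[length(f_stage)])
  }
  if (anyNA(s)) stop("survival stages do not cover ages 1..max_age")
  structure(list(survival = survival, fecundity = fecundity,
                 max_age = as.integer(max_age), s = s, s_sd = s_sd,
                 s_stage = s_stage, f = f, f_sd = f_sd, f_stage = f_stage,
                 fecundity_mapping = fecundity_mapping),
            class = "demographic_params")
}

#' Build the Leslie projection matrix from mean parameters
#'
#' Ages 0..max_age (so `max_age + 1` classes); the subdiagonal holds the
#' mean survivals into each age, the first row the mean fecundities halved
#' (equal sex ratio at birth and equal-sex survival make the total
#' population's age structure equal that of a female-only model with
#' halved fecundity). Individuals past `max_age` die.
#'
#' @param params A [demographic_params()].
#' @return `(max_age + 1)` square matrix.
#' @export
build_leslie <- function(params = demographic_params()) {
  n <- params$max_age + 1L
  A <- matrix(0, n, n)
  A[1L, ] <- params$f / 2
  for (a in seq_len(params$max_age)) A[a + 1L, a] <- params$s[a]
  dimnames(A) <- list(paste0("age", 0:params$max_age),
                      paste0("age", 0:params$max_age))
  A
}

#' Stable age distribution by eigenanalysis
#'
#' @param A Non-negative projection matrix with a positive dominant
#'   eigenvalue.
#' @param age_cutoff If given, also return the proportion of the stable
#'   distribution at ages `0..age_cutoff`.
#' @return List: `lambda`, `proportions` (sums to 1), and
#'   `proportion_le_cutoff` when requested.
#' @export
stable_age_distribution <- function(A, age_cutoff = NULL) {
  e <- eigen(A)
  i <- which.max(abs(e$values))
  lambda <- Re(e$values[i])
  if (!(abs(Im(e$values[i])) < 1e-8) || lambda <= 0)
    stop("no positive dominant eigenvalue (defective or nilpotent matrix)")
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("dominant eigenvector is not non-negative")
  v <- pmax(v, 0); v <- v / sum(v)
  out <- list(lambda = lambda, proportions = v)
  if (!is.null(age_cutoff))
    out$proportion_le_cutoff <- sum(v[seq_len(age_cutoff + 1L)])
  out
}

#' Census size adjusted to the sampled age range
#'
#' @param census Total population size estimate.
#' @param stable_proportion Stable-age proportion at or below the cutoff.
#' @return Product (report rounded to 0 decimals when quoting).
#' @export
adjusted_population_size <- function(census, stable_proportion) {
  stopifnot(census > 0, stable_proportion > 0, stable_proportion <= 1)
  census * stable_proportion
}

#' Expected number of hybrids and acceptance window
#'
#' @param hybrid_proportion Proportion of hybrids among the sampled,
#'   at-or-below-cutoff individuals.
#' @param adjusted_size Adjusted population size.
#' @param window Half-width of the relative acceptance window (0.10 =
#'   plus or minus 10 percent).
#' @return List: `expected`, `lower`, `upper`.
#' @export
expected_hybrids <- function(hybrid_proportion, adjusted_size, window = 0.10) {
  stopifnot(hybrid_proportion >= 0, hybrid_proportion <= 1)
  e <- hybrid_proportion * adjusted_size
  list(expected = e, lower = (1 - window) * e, upper = (1 + window) * e)
}

rtruncnorm01 <- function(n, mean, sd) {
  # inverse-CDF truncated normal on [0, 1]; degenerate sd returns the
  # mean clamped into the interval
  if (sd == 0) return(rep(min(max(mean, 0), 1), n))
  lo <- pnorm((0 - mean) / sd); hi <- pnorm((1 - mean) / sd)
  qnorm(lo + runif(n) * (hi - lo)) * sd + mean
}

draw_parameters <- function(params, n_runs, forced = NULL) {
  # one truncated-normal draw per stage parameter per run
  ns <- nrow(params$survival); nf <- nrow(params$fecundity)
  sdraw <- matrix(0, n_runs, ns)
  for (i in seq_len(ns))
    sdraw[, i] <- rtruncnorm01(n_runs, params$survival$mean[i], params$survival$sd[i])
  fdraw <- matrix(0, n_runs, nf)
  for (i in seq_len(nf))
    fdraw[, i] <- rtruncnorm01(n_runs, params$fecundity$mean[i], params$fecundity$sd[i])
  if (!is.null(forced)) {
    if (!is.null(forced$survival)) sdraw[] <- forced$survival
    if (!is.null(forced$fecundity)) fdraw[] <- forced$fecundity
  }
  list(s = sdraw, f = fdraw)
}

#' Ensemble of stochastic supplementation simulations
#'
#' Each run draws one value per stage parameter from truncated-normal
#' distributions (held fixed through the run), then advances the
#' supplemented ewes and their descendants through `years` yearly cycles:
#' every individual first survives into the next age class with its
#' age-specific probability (death past the maximum age), then every
#' surviving ewe aged 1+ produces a single lamb with her age-specific
#' fecundity; lamb sex is Bernoulli(1/2), males share female survival and
#' never reproduce. Lambs born to founder ewes in the first year, when the
#' founder was old enough (2+) to have been pregnant at release, are pure
#' supplemented: they are excluded from the final count and do not
#' reproduce. The final count is the number of hybrid-lineage individuals
#' aged at or below `age_cutoff` after `years` years; founder ewes are
#' never counted.
#'
#' @param ewe_ages Integer ages of the supplemented ewes at release.
#' @param params A [demographic_params()].
#' @param n_runs Number of independent runs.
#' @param years Simulated years.
#' @param age_cutoff Count descendants at or below this age.
#' @param sex_ratio Probability a lamb is female (1 forces all-female,
#'   used by deterministic oracles).
#' @param forced Optional list `survival`/`fecundity` overriding all
#'   parameter draws with fixed values (oracle testing).
#' @param seed Optional integer seed.
#' @return data.frame of class `simulation_ensemble`: one row per run with
#'   `lamb_survival_draw`, `final_count`, `n_pure_offspring`,
#'   `n_founders_alive`.
#' @export
run_ensemble <- function(ewe_ages, params = demographic_params(),
                         n_runs = 1e5, years = 6L, age_cutoff = 6L,
                         sex_ratio = 0.5, forced = NULL, seed = NULL) {
  stopifnot(length(ewe_ages) >= 1L, all(ewe_ages >= 0L), years >= 1L, n_runs >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n_runs <- as.integer(n_runs)
  max_age <- params$max_age
  dr <- draw_parameters(params, n_runs, forced)
  s_run <- dr$s[, params$s_stage, drop = FALSE]        # n_runs x max_age
  f_stage_idx <- params$f_stage
  f_stage_idx[f_stage_idx == 0L] <- 1L
  f_run <- dr$f[, f_stage_idx, drop = FALSE]           # n_runs x (max_age+1)
  f_run[, params$f_stage == 0L] <- 0                   # ages with no fecundity stage

  nA <- max_age + 1L
  founders <- matrix(0L, n_runs, nA)   # pure supplemented ewes by age
  for (a in ewe_ages) founders[, a + 1L] <- founders[, a + 1L] + 1L
  pregnant_at_release <- ewe_ages >= 2L
  hybF <- matrix(0L, n_runs, nA)
  hybM <- matrix(0L, n_runs, nA)
  pure_off <- integer(n_runs)

  rb <- function(size_mat, prob_mat) {
    # vectorised binomial over runs x ages
    out <- size_mat
    out[] <- rbinom(length(size_mat), as.integer(size_mat), prob_mat)
    out
  }
  advance <- function(m, surv) {
    out <- matrix(0L, n_runs, nA)
    for (a in seq_len(max_age))      # into age a (from a-1); past max_age dies
      out[, a + 1L] <- rb(m[, a, drop = FALSE], surv[, a, drop = FALSE])
    out
  }

  for (y in seq_len(years)) {
    founders <- advance(founders, s_run)
    hybF <- advance(hybF, s_run)
    hybM <- advance(hybM, s_run)
    # reproduction by surviving ewes (founders and hybrid ewes)
    lambs_founder <- rb(founders, f_run)
    lambs_hybrid <- rb(hybF, f_run)
    if (y == 1L) {
      # founders old enough to have been pregnant at release throw a pure
      # (in-utero) lamb this year; ages at release >= 2 are now ages >= 3
      pure_ages <- which(0:max_age >= 3L)
      pure_born <- rowSums(lambs_founder[, pure_ages, drop = FALSE])
      pure_off <- pure_off + as.integer(pure_born)
      lambs_founder[, pure_ages] <- 0L
    }
    new_lambs <- rowSums(lambs_founder) + rowSums(lambs_hybrid)
    new_f <- rbinom(n_runs, as.integer(new_lambs), sex_ratio)
    hybF[, 1L] <- hybF[, 1L] + as.integer(new_f)
    hybM[, 1L] <- hybM[, 1L] + as.integer(new_lambs) - as.integer(new_f)
  }

  keep_ages <- seq_len(min(age_cutoff, max_age) + 1L)
  final_count <- rowSums(hybF[, keep_ages, drop = FALSE]) +
    rowSums(hybM[, keep_ages, drop = FALSE])
  out <- data.frame(run = seq_len(n_runs),
                    lamb_survival_draw = dr$s[, 1L],
                    final_count = as.integer(final_count),
                    n_pure_offspring = pure_off,
                    n_founders_alive = as.integer(rowSums(founders)))
  class(out) <- c("simulation_ensemble", "data.frame")
  out
}

#' Single supplementation simulation run
#'
#' Convenience wrapper around [run_ensemble()] with `n_runs = 1`.
#'
#' @inheritParams run_ensemble
#' @return One-row data.frame (see [run_ensemble()]).
#' @export
simulate_supplementation <- function(ewe_ages, params = demographic_params(),
                                     years = 6L, age_cutoff = 6L,
                                     sex_ratio = 0.5, forced = NULL,
                                     seed = NULL) {
  run_ensemble(ewe_ages, params, n_runs = 1L, years = years,
               age_cutoff = age_cutoff, sex_ratio = sex_ratio,
               forced = forced, seed = seed)
}

#' Lamb-survival interval from runs inside the expected-hybrid window
#'
#' Filters the ensemble to runs whose final count lies inside
#' `[lower, upper]` and returns the mean, standard deviation and
#' pseudo-95 percent interval (mean plus/minus 2 SD) of their lamb
#' survival draws.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param bounds List or numeric with `lower` and `upper` counts
#'   (see [expected_hybrids()]).
#' @return List of class `lamb_survival_interval`: `mean`, `sd`, `lower`,
#'   `upper`, `n_accepted`, `window`.
#' @export
infer_lamb_survival <- function(ensemble, bounds) {
  lo <- if (is.list(bounds)) bounds$lower else bounds[1L]
  hi <- if (is.list(bounds)) bounds$upper else bounds[2L]
  acc <- ensemble$final_count >= lo & ensemble$final_count <= hi
  if (!any(acc))
    stop("no runs in the acceptance window [", lo, ", ", hi,
         "]; increase n_runs")
  x <- ensemble$lamb_survival_draw[acc]
  m <- mean(x); s <- if (length(x) > 1L) sd(x) else 0
  structure(list(mean = m, sd = s, lower = m - 2 * s, upper = m + 2 * s,
                 n_accepted = sum(acc), window = c(lo, hi)),
            class = "lamb_survival_interval")
}

#' Compare a lamb-survival interval with observed baselines
#'
#' Baselines are lambs-per-100-ewes herd-inventory values; the
#' conservative comparison uses their maximum (divided by 100). The
#' verdict reads the interval against that bound.
#'
#' @param interval An [infer_lamb_survival()] result.
#' @param baseline_lamb_per_100_ewes Numeric baseline values in `[0, 100]`.
#' @return List: `baseline_max`, `verdict` (one of `"at or above
#'   baseline"`, `"overlaps baseline"`, `"below baseline (possible
#'   outbreeding depression signal)"`), `interval`.
#' @export
compare_to_baseline <- function(interval, baseline_lamb_per_100_ewes) {
  stopifnot(all(baseline_lamb_per_100_ewes >= 0),
            all(baseline_lamb_per_100_ewes <= 100))
  b <- max(baseline_lamb_per_100_ewes) / 100
  verdict <- if (interval$lower >= b) "at or above baseline"
             else if (interval$upper < min(baseline_lamb_per_100_ewes) / 100)
               "below baseline (possible outbreeding depression signal)"
             else "overlaps baseline"
  list(baseline_max = b, verdict = verdict, interval = interval)
}
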