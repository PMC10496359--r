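#' Simulation configuration for two-trait origin-fixation evolution
#'
#' Bundles the parameters of the forward simulation: per-trait mutational
#' variance `v_m` (default 0.01), mutational correlation `cor_m`, haploid
#' effective population size `ne` (default 1e4), mean mutations per unit
#' time (`mut_rate`, default 1), number of independent replicate lineages
#' per repetition (default 50), number of repetitions (default 200),
#' duration in time units (default 1000; long enough for lineage means to
#' reach steady state on the unit optimum scale given ~1 fixation
#' opportunity per unit and v_m = 0.01), mutational bias coefficient `bias`
#' (default 1 = none), and an optional seed.
#'
#' @param cor_m mutational correlation, |cor_m| <= 1.
#' @param v_m per-trait mutational variance, > 0.
#' @param ne effective population size, >= 2.
#' @param mut_rate Poisson mean of mutations per time unit.
#' @param n_lineages replicate lineages per repetition.
#' @param n_reps repetitions.
#' @param time_units duration of each lineage.
#' @param bias bias coefficient B > 0.
#' @param seed optional integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(cor_m, v_m = 0.01, ne = 1e4, mut_rate = 1,
                       n_lineages = 50, n_reps = 200, time_units = 1000,
                       bias = 1, seed = NULL) {
  if (v_m <= 0) stop("v_m must be positive")
  if (abs(cor_m) > 1) stop("|cor_m| must not exceed 1")
  if (ne < 2) stop("ne must be at least 2")
  if (bias <= 0) stop("bias must be positive")
  if (n_lineages < 1 || n_reps < 1 || time_units < 1 || mut_rate <= 0)
    stop("counts and rates must be positive")
  structure(list(cor_m = cor_m, v_m = v_m, ne = ne, mut_rate = mut_rate,
                 n_lineages = n_lineages, n_reps = n_reps,
                 time_units = time_units, bias = bias, seed = seed),
            class = "sim_config")
}

#' Selection regimes for the two-trait simulation
#'
#' * `none` - neutral evolution; every mutation fixes (the acceptance
#'   probability Ne * (1/Ne) equals 1).
#' * `ridge` - Gaussian fitness around the line y = `slope` * x through the
#'   origin (an optimal allometric relationship); D is the shortest
#'   distance to the line.
#' * `point` - Gaussian fitness around a single optimal phenotype
#'   `optimum`; D is the Euclidean distance to it.
#' * `random_optima` - like `point`, but each lineage receives its own
#'   optimum drawn from the standard bivariate normal distribution.
#'
#' @param kind one of `"none"`, `"ridge"`, `"point"`, `"random_optima"`.
#' @param slope ridge slope k (line y = k x), for `kind = "ridge"`.
#' @param optimum length-2 optimum, for `kind = "point"`.
#' @return list of class `selection_regime`.
#' @export
selection_regime <- function(kind = c("none", "ridge", "point",
                                      "random_optima"),
                             slope = 1, optimum = c(0, 0)) {
  kind <- match.arg(kind)
  if (kind == "ridge" && !is.finite(slope)) stop("ridge slope must be finite")
  if (kind == "point" &&
      (length(optimum) != 2L || any(!is.finite(optimum))))
    stop("point optimum must be two finite values")
  structure(list(kind = kind, slope = slope, optimum = optimum),
            class = "selection_regime")
}

#' Build the 2x2 mutational covariance matrix
#'
#' M = \[\[v_m, v_m * cor_m\], \[v_m * cor_m, v_m\]\]: equal mutational
#' variance on both traits, off-diagonal COV_M = v_m * cor_m.
#'
#' @param v_m per-trait mutational variance.
#' @param cor_m mutational correlation, |cor_m| <= 1.
#' @return symmetric positive-semidefinite 2x2 matrix.
#' @export
build_m_matrix <- function(v_m, cor_m) {
  if (abs(cor_m) > 1) stop("|cor_m| must not exceed 1")
  if (v_m <= 0) stop("v_m must be positive")
  m <- matrix(c(v_m, v_m * cor_m, v_m * cor_m, v_m), 2L, 2L,
              dimnames = list(c("trait1", "trait2"), c("trait1", "trait2")))
  m
}

#' Gaussian fitness of a phenotype under a selection regime
#'
#' f = exp(-D^2 / 2), where D is the Euclidean distance to the point
#' optimum (current optimum of the state for `random_optima`), or the
#' shortest distance |y - k x| / sqrt(1 + k^2) to the ridge y = k x.
#'
#' @param phenotype length-2 numeric.
#' @param regime a [selection_regime()]; `kind = "none"` has no fitness
#'   function and is rejected.
#' @param optimum override optimum (used for `random_optima` lineages).
#' @return fitness in (0, 1].
#' @export
fitness <- function(phenotype, regime, optimum = NULL) {
  if (regime$kind == "none")
    stop("the neutral regime has no fitness function")
  if (regime$kind == "ridge") {
    d <- abs(phenotype[2L] - regime$slope * phenotype[1L]) /
      sqrt(1 + regime$slope^2)
  } else {
    opt <- if (!is.null(optimum)) optimum else regime$optimum
    d <- sqrt(sum((phenotype - opt)^2))
  }
  exp(-d^2 / 2)
}

#' Kimura's fixation probability in a haploid population
#'
#' P_f = (1 - exp(-2 s)) / (1 - exp(-2 Ne s)), evaluated stably: the s -> 0
#' limit 1/Ne is used for |s| < 1e-12, and strongly deleterious mutations
#' underflow to 0 rather than overflowing.
#'
#' @param s selection coefficient(s).
#' @param ne effective population size, >= 2.
#' @return fixation probability(ies) in \[0, 1\].
#' @export
fixation_probability <- function(s, ne) {
  if (ne < 2) stop("ne must be at least 2")
  num <- -expm1(-2 * s)
  den <- -expm1(-2 * ne * s)
  out <- ifelse(is.infinite(den), 0, num / den)
  out[abs(s) < 1e-12] <- 1 / ne
  pmin(pmax(out, 0), 1)
}

#' Rescale a mutational effect by the bias coefficient
#'
#' Both components of the effect m = (m1, m2) are multiplied by B when
#' m1 > 0 and divided by B when m1 < 0 (m1 = 0, a probability-zero event,
#' leaves m unchanged). The sign pattern and the ratio m2/m1 are preserved
#' exactly.
#'
#' @param m length-2 effect, or an n x 2 matrix of effects.
#' @param bias B > 0.
#' @return rescaled effect(s), same shape as `m`.
#' @export
rescale_mutation <- function(m, bias) {
  if (bias <= 0) stop("bias must be positive")
  if (is.matrix(m)) {
    fac <- ifelse(m[, 1L] > 0, bias, ifelse(m[, 1L] < 0, 1 / bias, 1))
    return(m * fac)
  }
  if (m[1L] > 0) m * bias else if (m[1L] < 0) m / bias else m
}

#' Advance one lineage by one unit of time (reference implementation)
#'
#' Draws Poisson(`mut_rate`) mutation effects from the bivariate normal
#' with covariance M (rescaled by the bias coefficient if B != 1) and
#' evaluates them sequentially: for each, s = f(mean + m)/f(mean) - 1 and
#' the effect is added to the population mean with probability
#' min(1, Ne * P_f); an accepted effect moves the mean before the next
#' mutation of the same time unit is evaluated. Under the neutral regime
#' every mutation fixes. This R implementation defines the per-step
#' semantics; [simulate_regime()] runs the same scheme in compiled code.
#'
#' @param state list with `mean` (length 2), optional `optimum`, and
#'   `n_fixed`.
#' @param config a [sim_config()].
#' @param regime a [selection_regime()].
#' @return updated state.
#' @export
step_lineage <- function(state, config, regime) {
  n_mut <- rpois(1L, config$mut_rate)
  if (n_mut == 0L) return(state)
  L <- chol_2x2(config$v_m, config$cor_m)
  z <- matrix(rnorm(2L * n_mut), n_mut, 2L)
  effects <- z %*% t(L)
  if (config$bias != 1) effects <- rescale_mutation(effects, config$bias)
  opt <- if (regime$kind == "random_optima") state$optimum else NULL
  for (k in seq_len(n_mut)) {
    m <- effects[k, ]
    if (regime$kind == "none") {
      state$mean <- state$mean + m
      state$n_fixed <- state$n_fixed + 1L
      next
    }
    s <- fitness(state$mean + m, regime, optimum = opt) /
      fitness(state$mean, regime, optimum = opt) - 1
    acc <- min(1, config$ne * fixation_probability(s, config$ne))
    if (acc >= 1 || runif(1L) < acc) {
      state$mean <- state$mean + m
      state$n_fixed <- state$n_fixed + 1L
    }
  }
  state
}

# Lower Cholesky factor of the 2x2 mutational covariance matrix.
chol_2x2 <- function(v_m, cor_m) {
  s <- sqrt(v_m)
  matrix(c(s, s * cor_m, 0, s * sqrt(max(0, 1 - cor_m^2))), 2L, 2L)
}

#' Simulate a selection regime and summarize the evolutionary correlation
#'
#' Evolves `n_lineages` independent replicate lineages for `time_units`
#' units under the given regime, computes the Pearson correlation COR_E of
#' the final mean phenotypes across lineages, and repeats `n_reps` times to
#' obtain an empirical COR_E distribution. A significant difference from
#' COR_M is inferred when COR_M falls in the left or right 2.5% tail of
#' that distribution; significant runs are labeled `strengthened`,
#' `weakened` (same sign, larger/smaller |median COR_E|), or `reversed`
#' (opposite sign).
#'
#' For `random_optima`, each lineage's optimum is two independent standard
#' normal draws; one optima set is drawn per run and shared across the
#' repetitions, so the repetitions measure the mutation-and-fixation noise
#' around a fixed landscape. Optima sets whose two traits correlate at
#' |r| >= 0.3 across lineages are redrawn (with a message) so the optima
#' themselves carry essentially no correlation signal; the set used is
#' returned as `optima`.
#'
#' @param config a [sim_config()].
#' @param regime a [selection_regime()].
#' @param check_steady_state if `TRUE`, rerun at doubled `time_units` and
#'   warn when the median COR_E moves by more than 0.05.
#' @return list with `cor_e` (per-repetition values, `NA`-free; degenerate
#'   repetitions with zero variance are dropped with a message), `median`,
#'   `frac_gt_cor_m` (fraction of repetitions with COR_E > COR_M),
#'   `significant`, `verdict`, and `n_dropped`.
#' @export
simulate_regime <- function(config, regime, check_steady_state = FALSE) {
  L <- chol_2x2(config$v_m, config$cor_m)
  regime_code <- match(regime$kind,
                       c("none", "ridge", "point", "random_optima")) - 1L
  run <- function(time_units, optima) {
    vapply(seq_len(config$n_reps), function(rep) {
      finals <- cpp_evolve_lineages(
        config$n_lineages, time_units, L[1L, 1L], L[2L, 1L], L[2L, 2L],
        config$ne, config$mut_rate, regime_code,
        regime$slope, regime$optimum[1L], regime$optimum[2L],
        optima, config$bias)
      if (stats::sd(finals[, 1L]) == 0 || stats::sd(finals[, 2L]) == 0)
        return(NA_real_)
      stats::cor(finals[, 1L], finals[, 2L])
    }, numeric(1))
  }
  with_seed(config$seed, {
    optima <- matrix(0, 1L, 2L)
    if (regime$kind == "random_optima") {
      repeat {
        optima <- matrix(rnorm(2L * config$n_lineages),
                         config$n_lineages, 2L)
        if (abs(stats::cor(optima)[1L, 2L]) < 0.3) break
        message("redrawing lineage optima (|r| >= 0.3)")
      }
    }
    cor_e <- run(config$time_units, optima)
    n_dropped <- sum(is.na(cor_e))
    if (n_dropped > 0)
      message(n_dropped, " repetition(s) with degenerate phenotypes dropped")
    cor_e <- cor_e[!is.na(cor_e)]
    if (!length(cor_e)) stop("all repetitions degenerate")
    med <- median(cor_e)
    lims <- quantile(cor_e, c(0.025, 0.975), names = FALSE)
    significant <- config$cor_m < lims[1L] || config$cor_m > lims[2L]
    # "reversed" requires the COR_E distribution itself to sit on the other
    # side of zero, not just a median whose sign flips within noise.
    away_from_zero <- lims[1L] > 0 || lims[2L] < 0
    verdict <- if (!significant) "no_difference"
      else if (med * config$cor_m < 0 && away_from_zero) "reversed"
      else if (abs(med) > abs(config$cor_m)) "strengthened"
      else "weakened"
    if (check_steady_state) {
      med2 <- median(run(2L * config$time_units, optima), na.rm = TRUE)
      if (abs(med2 - med) > 0.05)
        warning("median COR_E moved by ", format(abs(med2 - med)),
                " when time_units doubled; lineages may not be at steady ",
                "state")
    }
    list(cor_e = cor_e, median = med,
         frac_gt_cor_m = mean(cor_e > config$cor_m),
         significant = significant, verdict = verdict,
         n_dropped = n_dropped, optima = if (regime_code == 3L) optima)
  })
}

#' Does bias rescaling distort the mutational correlation?
#'
#' Draws `n_mutations` effects from the bivariate normal with correlation
#' `cor_m`, rescales them by the bias coefficient, and estimates the
#' Pearson correlation of the rescaled effects; repeated `n_reps` times.
#' The quantile position of the pre-set COR_M within the estimates shows
#' whether mutational bias alone could mimic a selection signal.
#'
#' @param cor_m pre-set mutational correlation.
#' @param bias bias coefficient B.
#' @param n_mutations effects per repetition (default 5000).
#' @param n_reps repetitions (default 200).
#' @param v_m per-trait mutational variance.
#' @param seed optional seed.
#' @return list with `estimates`, their `median`, and `quantile_of_cor_m`
#'   (fraction of estimates below the pre-set COR_M).
#' @export
bias_cor_check <- function(cor_m, bias, n_mutations = 5000, n_reps = 200,
                           v_m = 0.01, seed = NULL) {
  if (n_mutations < 4) stop("need at least 4 mutations per repetition")
  L <- chol_2x2(v_m, cor_m)
  with_seed(seed, {
    estimates <- vapply(seq_len(n_reps), function(i) {
      z <- matrix(rnorm(2L * n_mutations), n_mutations, 2L)
      eff <- rescale_mutation(z %*% t(L), bias)
      stats::cor(eff[, 1L], eff[, 2L])
    }, numeric(1))
    list(estimates = estimates, median = median(estimates),
         quantile_of_cor_m = mean(estimates < cor_m))
  })
}
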