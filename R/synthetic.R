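#' Synthetic-cohort generating model
#'
#' Defines the stochastic model used to emulate a T2DM cohort when the real
#' per-patient data are unavailable. Biomarkers are drawn independently from
#' truncated normals (default mean = mid-range, sd = range/6, truncated to
#' the configured universe bounds) or uniforms over the same bounds. The
#' pocket-count outcome follows the fitted clinical line
#' `nrPP = b0 + b1 x PCRisk` plus Gaussian noise, rounded to an integer and
#' clamped to a plausible dentition range.
#'
#' Biomarker draws and outcome noise use separate seeds, so either can be
#' held fixed while the other varies.
#'
#' @param n Cohort size (>= 3). Default 37, the size implied by the
#'   reference regression's total degrees of freedom.
#' @param seed Integer seed for the biomarker stream.
#' @param distribution `"truncnorm"` (default) or `"uniform"`.
#' @param universes Biomarker bounds, as in [risk_config()].
#' @param mu,sigma Optional named lists overriding the per-biomarker
#'   truncated-normal location/scale.
#' @param b0,b1 Outcome-line intercept and slope (pockets per risk unit).
#' @param residual_sd Outcome noise sd; default `sqrt(37.533)`, the residual
#'   mean square of the reference regression.
#' @param nrpp_range Clamp range for the integer pocket count; default
#'   `c(0, 28)` (one pocket per tooth, full dentition minus third molars).
#' @param outcome_seed Seed for the outcome-noise stream; defaults to a
#'   fixed offset of `seed`.
#' @return An object of class `cohort_model`.
#' @export
cohort_model <- function(n = 37L, seed = 1L,
                         distribution = c("truncnorm", "uniform"),
                         universes = default_universes(),
                         mu = NULL, sigma = NULL,
                         b0 = 0.399, b1 = 1.881,
                         residual_sd = sqrt(37.533),
                         nrpp_range = c(0L, 28L),
                         outcome_seed = seed + 104729L) {
  distribution <- match.arg(distribution)
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("cohort size n must be >= 3", call. = FALSE)
  if (residual_sd < 0) stop("residual_sd must be >= 0", call. = FALSE)
  if (nrpp_range[1] >= nrpp_range[2]) {
    stop("nrpp_range must satisfy lo < hi", call. = FALSE)
  }
  mu_def <- lapply(universes, function(u) mean(u))
  sig_def <- lapply(universes, function(u) (u[2] - u[1]) / 6)
  for (b in names(mu)) mu_def[[b]] <- mu[[b]]
  for (b in names(sigma)) sig_def[[b]] <- sigma[[b]]
  if (any(unlist(sig_def) <= 0)) {
    stop("sigma must be > 0 for every biomarker", call. = FALSE)
  }
  structure(list(n = n, seed = as.integer(seed),
                 outcome_seed = as.integer(outcome_seed),
                 distribution = distribution,
                 universes = universes, mu = mu_def, sigma = sig_def,
                 b0 = b0, b1 = b1, residual_sd = residual_sd,
                 nrpp_range = nrpp_range),
            class = "cohort_model")
}

# inverse-CDF draw from a normal truncated to [lo, hi]
rtruncnorm <- function(n, mu, sigma, lo, hi) {
  p_lo <- stats::pnorm(lo, mu, sigma)
  p_hi <- stats::pnorm(hi, mu, sigma)
  x <- stats::qnorm(stats::runif(n, p_lo, p_hi), mu, sigma)
  pmin(pmax(x, lo), hi)  # guard fp round-off at the tails
}

# mean of the truncated normal (closed form), used as a test oracle target
truncnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  mu + sigma * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Draw synthetic biomarker records
#'
#' Generates `model$n` patient records with ids `S001`, `S002`, ... and the
#' four biomarkers drawn independently per the model. Deterministic given
#' the model's biomarker seed; every draw lies inside the configured bounds.
#'
#' @param model A [cohort_model()].
#' @return Data frame with columns `patient_id`, `bmi`, `glycemia`,
#'   `cholesterol`, `triglycerides`.
#' @export
generate_biomarkers <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  set.seed(model$seed)
  draws <- lapply(BIOMARKERS, function(b) {
    u <- model$universes[[b]]
    if (model$distribution == "uniform") {
      stats::runif(model$n, u[1], u[2])
    } else {
      rtruncnorm(model$n, model$mu[[b]], model$sigma[[b]], u[1], u[2])
    }
  })
  names(draws) <- BIOMARKERS
  cbind(data.frame(patient_id = sprintf("S%03d", seq_len(model$n)),
                   stringsAsFactors = FALSE),
        as.data.frame(draws))
}

#' Attach a simulated pocket-count outcome to scored records
#'
#' `nrpp = round(clamp(b0 + b1 x pcrisk + e))` with
#' `e ~ Normal(0, residual_sd)`, independent across records, drawn from the
#' model's outcome seed (separate from the biomarker stream). Records
#' without a `pcrisk` column are scored first with [assess_cohort()].
#'
#' @param records Data frame of biomarker records, scored or scorable.
#' @param config A [risk_config()] (used only if scoring is needed).
#' @param model A [cohort_model()].
#' @return `records` with integer column `nrpp` appended.
#' @export
attach_outcome <- function(records, config = risk_config(),
                           model = cohort_model()) {
  stopifnot(inherits(model, "cohort_model"))
  if (!"pcrisk" %in% names(records)) {
    records <- assess_cohort(records, config)
  }
  set.seed(model$outcome_seed)
  eps <- stats::rnorm(nrow(records), 0, model$residual_sd)
  y <- model$b0 + model$b1 * records$pcrisk + eps
  records$nrpp <- as.integer(round(pmin(pmax(y, model$nrpp_range[1]),
                                        model$nrpp_range[2])))
  records
}

#' Generate a complete synthetic cohort
#'
#' Biomarkers, two-level risk scores and the simulated pocket-count outcome
#' in one call; fully deterministic given the model.
#'
#' @param model A [cohort_model()].
#' @param config A [risk_config()].
#' @return Scored data frame with `nrpp`.
#' @export
generate_cohort <- function(model = cohort_model(),
                            config = risk_config()) {
  attach_outcome(assess_cohort(generate_biomarkers(model), config),
                 config, model)
}

#' Parameter-recovery simulation study
#'
#' Repeatedly generates cohorts from the model, scores them through the full
#' two-level fuzzy cascade, attaches the outcome and refits the simple
#' regression of nrPP on PCRisk; summarises bias and confidence-interval
#' coverage of the slope. Replicate r uses biomarker seed `model$seed + r`
#' (and the matching offset outcome seed), so the study is reproducible.
#'
#' @param model A [cohort_model()] (the generating truth).
#' @param config A [risk_config()].
#' @param n_reps Number of replicates (>= 10).
#' @param conf_level Nominal CI level for the slope (default 0.95).
#' @return List of class `recovery_study`: `reps` (data frame with per-rep
#'   `b0`, `b1`, `se_b1`, `ci_lo`, `ci_hi`, `p_b1`), `mean_b0`, `sd_b0`,
#'   `mean_b1`, `sd_b1`, `coverage` (fraction of CIs containing the
#'   generating slope), `rejection_rate` (fraction with slope p < 0.05),
#'   `true_b0`, `true_b1`.
#' @export
parameter_recovery_study <- function(model = cohort_model(),
                                     config = risk_config(),
                                     n_reps = 200L,
                                     conf_level = 0.95) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 10L) {
    stop("n_reps must be >= 10", call. = FALSE)
  }
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    m <- model
    m$seed <- model$seed + r
    m$outcome_seed <- m$seed + 104729L
    cohort <- generate_cohort(m, config)
    fit <- fit_simple_ols(cohort$pcrisk, cohort$nrpp)
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, fit$df_residual)
    reps[[r]] <- data.frame(
      rep = r, b0 = fit$b0, b1 = fit$b1, se_b1 = fit$se_b1,
      ci_lo = fit$b1 - tcrit * fit$se_b1,
      ci_hi = fit$b1 + tcrit * fit$se_b1,
      p_b1 = fit$p_b1)
  }
  reps <- do.call(rbind, reps)
  structure(list(
    reps = reps,
    mean_b0 = mean(reps$b0), sd_b0 = stats::sd(reps$b0),
    mean_b1 = mean(reps$b1), sd_b1 = stats::sd(reps$b1),
    coverage = mean(reps$ci_lo <= model$b1 & model$b1 <= reps$ci_hi),
    rejection_rate = mean(reps$p_b1 < 0.05),
    true_b0 = model$b0, true_b1 = model$b1,
    conf_level = conf_level, n_reps = n_reps, n = model$n),
    class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d reps of n = %d\n", x$n_reps, x$n))
  cat(sprintf("  slope: true %.3f, mean fitted %.3f (sd %.3f)\n",
              x$true_b1, x$mean_b1, x$sd_b1))
  cat(sprintf("  %.0f%% CI coverage: %.1f%%   rejection rate: %.1f%%\n",
              100 * x$conf_level, 100 * x$coverage,
              100 * x$rejection_rate))
  invisible(x)
}
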