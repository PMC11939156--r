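#' Default biomarker universes
#'
#' Observed min-max ranges of the four biomarkers in the reference T2DM
#' cohort: BMI (kg/m^2), fasting glucose (mg/dL), total cholesterol (mg/dL),
#' triglycerides (mg/dL).
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
default_universes <- function() {
  list(bmi           = c(22.03, 44.08),
       glycemia      = c(83,    237),
       cholesterol   = c(112,   290),
       triglycerides = c(63,    320))
}

BIOMARKERS <- c("bmi", "glycemia", "cholesterol", "triglycerides")

# input-variable display names per subsystem, used in rule sentences
SUBSYSTEM_VARS <- list(
  prisk1 = c("BMI", "G",      "PRisk1"),
  prisk2 = c("C",   "T",      "PRisk2"),
  pcrisk = c("PRisk1", "PRisk2", "PCRisk"))

#' System configuration for the two-level risk model
#'
#' Collects everything needed to build the three fuzzy subsystems: the four
#' biomarker universes, the shared output range (risk scale, default 1-10),
#' the defuzzification resolution, and one 5x5 rule matrix per subsystem
#' (all default to [default_rule_matrix()]).
#'
#' @param universes Named list with entries `bmi`, `glycemia`, `cholesterol`,
#'   `triglycerides`, each a `c(lo, hi)` pair.
#' @param output_lo,output_hi Risk output range.
#' @param resolution Defuzzification sample count (>= 101).
#' @param rules Named list of three 5x5 ordinal matrices
#'   (`prisk1`, `prisk2`, `pcrisk`).
#' @return An object of class `risk_config`.
#' @export
risk_config <- function(universes = default_universes(),
                        output_lo = 1, output_hi = 10,
                        resolution = 1001L,
                        rules = NULL) {
  dm <- default_rule_matrix()$matrix
  if (is.null(rules)) {
    rules <- list(prisk1 = dm, prisk2 = dm, pcrisk = dm)
  }
  cfg <- structure(list(universes = universes,
                        output_lo = output_lo, output_hi = output_hi,
                        resolution = as.integer(resolution),
                        rules = rules),
                   class = "risk_config")
  validate_config(cfg)
  cfg
}

#' Validate a risk-system configuration
#'
#' Checks universe ordering, output range, resolution and the structural
#' invariants of each rule matrix. On failure, the error message lists every
#' offending field.
#'
#' @param config A `risk_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  if (!is.list(config$universes) ||
      !all(BIOMARKERS %in% names(config$universes))) {
    problems <- c(problems, paste("universes must contain:",
                                  paste(BIOMARKERS, collapse = ", ")))
  } else {
    for (b in BIOMARKERS) {
      u <- config$universes[[b]]
      if (!is.numeric(u) || length(u) != 2 || !all(is.finite(u)) ||
          u[1] >= u[2]) {
        problems <- c(problems,
                      sprintf("universes$%s: need finite lo < hi", b))
      }
    }
  }
  if (!is.numeric(config$output_lo) || !is.numeric(config$output_hi) ||
      config$output_lo >= config$output_hi) {
    problems <- c(problems, "output range: need output_lo < output_hi")
  }
  if (is.na(config$resolution) || config$resolution < 101L) {
    problems <- c(problems, "resolution: need integer >= 101")
  }
  for (id in names(SUBSYSTEM_VARS)) {
    ok <- tryCatch({
      rule_base(config$rules[[id]])
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      problems <- c(problems, sprintf("rules$%s: %s", id, ok))
    }
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(config)
}

#' @export
print.risk_config <- function(x, ...) {
  cat("Two-level periodontitis risk configuration\n")
  for (b in BIOMARKERS) {
    cat(sprintf("  %-13s [%g, %g]\n", b, x$universes[[b]][1],
                x$universes[[b]][2]))
  }
  cat(sprintf("  risk scale    [%g, %g], resolution %d\n",
              x$output_lo, x$output_hi, x$resolution))
  invisible(x)
}

#' Build the three fuzzy subsystems from a configuration
#'
#' Wires the cascade: PRisk1 scores BMI + glycemia, PRisk2 scores
#' cholesterol + triglycerides, and the cumulative PCRisk subsystem takes
#' the two first-level outputs as inputs, so its input universes equal the
#' risk output range.
#'
#' @param config A [risk_config()].
#' @return Named list of three [fuzzy_subsystem()] objects
#'   (`prisk1`, `prisk2`, `pcrisk`).
#' @export
build_system <- function(config = risk_config()) {
  validate_config(config)
  u <- config$universes
  out_rng <- c(config$output_lo, config$output_hi)
  mk_out <- function(name) linguistic_variable(name, out_rng[1], out_rng[2])
  mk_rb <- function(id) {
    v <- SUBSYSTEM_VARS[[id]]
    rule_base(config$rules[[id]], input1 = v[1], input2 = v[2],
              output = v[3])
  }
  res <- config$resolution
  list(
    prisk1 = fuzzy_subsystem(
      linguistic_variable("BMI", u$bmi[1], u$bmi[2]),
      linguistic_variable("G", u$glycemia[1], u$glycemia[2]),
      mk_out("PRisk1"), mk_rb("prisk1"), res),
    prisk2 = fuzzy_subsystem(
      linguistic_variable("C", u$cholesterol[1], u$cholesterol[2]),
      linguistic_variable("T", u$triglycerides[1], u$triglycerides[2]),
      mk_out("PRisk2"), mk_rb("prisk2"), res),
    pcrisk = fuzzy_subsystem(
      mk_out("PRisk1"), mk_out("PRisk2"),
      mk_out("PCRisk"), mk_rb("pcrisk"), res))
}

check_record <- function(bmi, glycemia, cholesterol, triglycerides) {
  v <- c(bmi = bmi, glycemia = glycemia, cholesterol = cholesterol,
         triglycerides = triglycerides)
  bad <- names(v)[!is.finite(v) | v <= 0]
  if (length(bad)) {
    return(paste("non-finite or non-positive biomarker(s):",
                 paste(bad, collapse = ", ")))
  }
  NULL
}

#' Score one patient record
#'
#' Runs the two-level cascade: PRisk1 from BMI and glucose, PRisk2 from
#' cholesterol and triglycerides, then PCRisk from the two intermediate
#' risks. Biomarkers outside the configured universes are clamped to the
#' nearest bound before fuzzification.
#'
#' @param record Named list or one-row data frame with `bmi`, `glycemia`,
#'   `cholesterol`, `triglycerides` and optionally `patient_id`.
#' @param config A [risk_config()], or a prebuilt system from
#'   [build_system()] (cheaper when scoring repeatedly).
#' @return List of class `risk_result` with `prisk1`, `prisk2`, `pcrisk`,
#'   all inside the risk output range.
#' @examples
#' assess_patient(list(bmi = 33.055, glycemia = 160, cholesterol = 201,
#'                     triglycerides = 191.5))
#' @export
assess_patient <- function(record, config = risk_config()) {
  sys <- if (is.list(config) && inherits(config$prisk1, "fuzzy_subsystem")) {
    config
  } else {
    build_system(config)
  }
  id <- if (!is.null(record$patient_id)) record$patient_id else "<unnamed>"
  err <- check_record(as.numeric(record$bmi), as.numeric(record$glycemia),
                      as.numeric(record$cholesterol),
                      as.numeric(record$triglycerides))
  if (!is.null(err)) {
    stop(sprintf("record '%s': %s", id, err), call. = FALSE)
  }
  p1 <- evaluate_fis(sys$prisk1, as.numeric(record$bmi),
                     as.numeric(record$glycemia))
  p2 <- evaluate_fis(sys$prisk2, as.numeric(record$cholesterol),
                     as.numeric(record$triglycerides))
  pc <- evaluate_fis(sys$pcrisk, p1, p2)
  structure(list(prisk1 = p1, prisk2 = p2, pcrisk = pc),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("PRisk1 = %.4f  PRisk2 = %.4f  PCRisk = %.4f\n",
              x$prisk1, x$prisk2, x$pcrisk))
  invisible(x)
}

#' Score a cohort of patient records
#'
#' Vectorised batch scoring. Invalid records (missing/non-finite biomarkers)
#' are collected rather than aborting the run: valid records are still
#' scored, order is preserved, and failed records carry `NA` risk columns.
#' A run log (counts, clamped-input ids, failures) is attached as the
#' `"run_log"` attribute.
#'
#' @param records Data frame with columns `bmi`, `glycemia`, `cholesterol`,
#'   `triglycerides`, optionally `patient_id` and `nrpp`.
#' @param config A [risk_config()].
#' @return `records` with appended numeric columns `prisk1`, `prisk2`,
#'   `pcrisk`; attribute `run_log` (list: `n_read`, `n_scored`, `n_failed`,
#'   `n_clamped`, `clamped_ids`, `failures` data frame).
#' @export
assess_cohort <- function(records, config = risk_config()) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("empty cohort: need at least one record", call. = FALSE)
  }
  missing_cols <- setdiff(BIOMARKERS, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sys <- build_system(config)
  ids <- if ("patient_id" %in% names(records)) {
    as.character(records$patient_id)
  } else {
    sprintf("row%d", seq_len(nrow(records)))
  }
  vals <- lapply(BIOMARKERS, function(b) {
    suppressWarnings(as.numeric(records[[b]]))
  })
  names(vals) <- BIOMARKERS
  reasons <- vapply(seq_len(nrow(records)), function(r) {
    e <- check_record(vals$bmi[r], vals$glycemia[r], vals$cholesterol[r],
                      vals$triglycerides[r])
    if (is.null(e)) NA_character_ else e
  }, character(1))
  ok <- is.na(reasons)
  clamped <- rep(FALSE, nrow(records))
  for (b in BIOMARKERS) {
    u <- config$universes[[b]]
    clamped <- clamped | (ok & (vals[[b]] < u[1] | vals[[b]] > u[2]))
  }
  records$prisk1 <- NA_real_
  records$prisk2 <- NA_real_
  records$pcrisk <- NA_real_
  if (any(ok)) {
    p1 <- evaluate_fis(sys$prisk1, vals$bmi[ok], vals$glycemia[ok])
    p2 <- evaluate_fis(sys$prisk2, vals$cholesterol[ok],
                       vals$triglycerides[ok])
    records$prisk1[ok] <- p1
    records$prisk2[ok] <- p2
    records$pcrisk[ok] <- evaluate_fis(sys$pcrisk, p1, p2)
  }
  attr(records, "run_log") <- list(
    n_read = nrow(records),
    n_scored = sum(ok),
    n_failed = sum(!ok),
    n_clamped = sum(clamped),
    clamped_ids = ids[clamped],
    failures = data.frame(patient_id = ids[!ok],
                          reason = reasons[!ok],
                          stringsAsFactors = FALSE))
  records
}

#' Evaluate a subsystem's response surface on a regular grid
#'
#' An n-by-n evenly spaced evaluation over the two input universes,
#' returned row-major (input 1 varies slowest). Suitable for re-plotting the
#' characteristic risk surfaces.
#'
#' @param subsystem_id One of `"prisk1"`, `"prisk2"`, `"pcrisk"`.
#' @param n Grid points per axis (>= 2).
#' @param config A [risk_config()].
#' @return Data frame with columns `x1`, `x2`, `value` (n^2 rows).
#' @export
surface_grid <- function(subsystem_id, n = 101L, config = risk_config()) {
  if (!subsystem_id %in% names(SUBSYSTEM_VARS)) {
    stop("unknown subsystem '", subsystem_id,
         "'; expected prisk1, prisk2 or pcrisk", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    stop("grid size n must be an integer >= 2", call. = FALSE)
  }
  sys <- build_system(config)[[subsystem_id]]
  g1 <- seq(sys$input1$lo, sys$input1$hi, length.out = n)
  g2 <- seq(sys$input2$lo, sys$input2$hi, length.out = n)
  x1 <- rep(g1, each = n)
  x2 <- rep(g2, times = n)
  data.frame(x1 = x1, x2 = x2,
             value = evaluate_fis(sys, x1, x2))
}
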