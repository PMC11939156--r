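#' Read a risk-system configuration from YAML
#'
#' Strict schema: the file may contain `universes` (per-biomarker `lo`/`hi`),
#' `output` (`lo`/`hi`), `resolution` and `rules` (per-subsystem 5x5 matrix
#' of term labels Vs/s/Md/B/VB). Unknown keys at any level are rejected;
#' omitted keys fall back to the defaults of [risk_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated [risk_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- c("universes", "output", "resolution", "rules")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  universes <- default_universes()
  if (!is.null(raw$universes)) {
    unknown <- setdiff(names(raw$universes), BIOMARKERS)
    if (length(unknown)) {
      stop("unknown biomarker(s) in universes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (b in names(raw$universes)) {
      u <- raw$universes[[b]]
      unknown <- setdiff(names(u), c("lo", "hi"))
      if (length(unknown) || is.null(u$lo) || is.null(u$hi)) {
        stop("universes$", b, " must have exactly the keys lo and hi",
             call. = FALSE)
      }
      universes[[b]] <- c(u$lo, u$hi)
    }
  }
  out_lo <- 1
  out_hi <- 10
  if (!is.null(raw$output)) {
    unknown <- setdiff(names(raw$output), c("lo", "hi"))
    if (length(unknown)) {
      stop("output must have only the keys lo and hi", call. = FALSE)
    }
    if (!is.null(raw$output$lo)) out_lo <- raw$output$lo
    if (!is.null(raw$output$hi)) out_hi <- raw$output$hi
  }
  resolution <- if (!is.null(raw$resolution)) raw$resolution else 1001L
  rules <- NULL
  if (!is.null(raw$rules)) {
    unknown <- setdiff(names(raw$rules), names(SUBSYSTEM_VARS))
    if (length(unknown)) {
      stop("unknown subsystem(s) in rules: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    dm <- default_rule_matrix()$matrix
    rules <- list(prisk1 = dm, prisk2 = dm, pcrisk = dm)
    for (id in names(raw$rules)) {
      rows <- raw$rules[[id]]
      if (length(rows) != 5 ||
          !all(vapply(rows, length, integer(1)) == 5)) {
        stop("rules$", id, " must be 5 rows of 5 term labels",
             call. = FALSE)
      }
      labels <- unlist(rows)
      ord <- match(labels, TERM_LABELS)
      if (any(is.na(ord))) {
        stop("rules$", id, ": unknown term label(s): ",
             paste(unique(labels[is.na(ord)]), collapse = ", "),
             call. = FALSE)
      }
      rules[[id]] <- matrix(ord, 5, 5, byrow = TRUE)
    }
  }
  risk_config(universes = universes, output_lo = out_lo,
              output_hi = out_hi, resolution = resolution, rules = rules)
}

#' Write a risk-system configuration to YAML
#'
#' Inverse of [read_config()]: the written file reads back to an identical
#' configuration. Rule matrices are written as rows of term labels.
#'
#' @param config A [risk_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  as_label_rows <- function(m) {
    lapply(1:5, function(i) as.list(TERM_LABELS[m[i, ]]))
  }
  doc <- list(
    universes = lapply(config$universes,
                       function(u) list(lo = u[1], hi = u[2])),
    output = list(lo = config$output_lo, hi = config$output_hi),
    resolution = config$resolution,
    rules = lapply(config$rules, as_label_rows))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Comma-separated, dot decimal, UTF-8, header required. Expected columns:
#' `patient_id`, `bmi`, `glycemia`, `cholesterol`, `triglycerides`, and
#' optionally `nrpp` plus previously computed risk columns. Biomarker fields
#' that fail numeric parsing become `NA` (reported downstream by
#' [assess_cohort()]), but structurally missing columns are a hard error.
#'
#' @param path CSV path.
#' @param require_nrpp Require the periodontal pocket count column.
#' @return Data frame.
#' @export
read_cohort <- function(path, require_nrpp = FALSE) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("patient_id", BIOMARKERS)
  if (require_nrpp) required <- c(required, "nrpp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (b in c(BIOMARKERS, intersect("nrpp", names(df)))) {
    df[[b]] <- suppressWarnings(as.numeric(df[[b]]))
  }
  df
}

#' Write a cohort CSV
#'
#' Same dialect as [read_cohort()]. Risk columns (`prisk1`, `prisk2`,
#' `pcrisk`), when present, are rounded to 4 decimals on write.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  for (col in intersect(c("prisk1", "prisk2", "pcrisk"), names(df))) {
    df[[col]] <- round(df[[col]], 4)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
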