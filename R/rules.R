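#' Fuzzy rule base as a 5x5 consequent matrix
#'
#' Encodes the 25 if-then rules of a two-input subsystem: entry `[i, j]` is
#' the ordinal (1-5) of the output term fired when input 1 is in term `i` and
#' input 2 is in term `j`. Clinically motivated structural invariants are
#' enforced: the matrix is symmetric (the two risk factors are
#' interchangeable), non-decreasing along every row and column (worse
#' biomarkers never lower the risk) and has identity diagonal (concordant
#' inputs map to the same grade).
#'
#' @param matrix Integer 5x5 matrix with entries in 1..5.
#' @param input1,input2,output Variable names, used when rendering the rules
#'   as sentences.
#' @return An object of class `rule_base`.
#' @export
rule_base <- function(matrix, input1 = "input1", input2 = "input2",
                      output = "output") {
  m <- base::matrix(as.integer(matrix), 5, 5)
  if (any(is.na(m)) || any(m < 1L | m > 5L)) {
    stop("rule matrix entries must be ordinals in 1..5", call. = FALSE)
  }
  if (!identical(m, t(m))) {
    stop("rule matrix must be symmetric", call. = FALSE)
  }
  if (any(apply(m, 1, function(r) any(diff(r) < 0)))) {
    stop("rule matrix must be non-decreasing along each row and column",
         call. = FALSE)
  }
  if (!identical(diag(m), 1:5)) {
    stop("rule matrix diagonal must map each grade to itself", call. = FALSE)
  }
  dimnames(m) <- list(TERM_LABELS, TERM_LABELS)
  structure(list(matrix = m, input1 = input1, input2 = input2,
                 output = output),
            class = "rule_base")
}

#' Default periodontitis-risk rule matrix
#'
#' The completed 25-rule consequent matrix shared by all three subsystems
#' (BMI+glycemia, cholesterol+triglycerides, and the cumulative level). Rows
#' index the first input's grade Vs..VB, columns the second input's. The
#' matrix is the unique symmetric, row/column-monotone completion of the
#' published rule set with identity diagonal.
#'
#' @param input1,input2,output Variable names for rendered rule sentences.
#' @return A [rule_base()].
#' @examples
#' rb <- default_rule_matrix("BMI", "G", "PRisk1")
#' rb$matrix["Vs", "Md"]  # 2: very small BMI + medium glucose -> small risk
#' @export
default_rule_matrix <- function(input1 = "input1", input2 = "input2",
                                output = "output") {
  m <- rbind(c(1L, 1L, 2L, 2L, 3L),
             c(1L, 2L, 3L, 3L, 4L),
             c(2L, 3L, 3L, 4L, 4L),
             c(2L, 3L, 4L, 4L, 5L),
             c(3L, 4L, 4L, 5L, 5L))
  rule_base(m, input1 = input1, input2 = input2, output = output)
}

#' Render a rule base as its 25 if-then sentences
#'
#' Row-major order (input 1 grade outermost), matching the numbering used in
#' clinical rule listings: sentence `5 (i - 1) + j` covers input grades
#' `(i, j)`.
#'
#' @param rules A [rule_base()].
#' @return Character vector of 25 sentences.
#' @examples
#' rule_sentences(default_rule_matrix("BMI", "G", "PRisk1"))[3]
#' @export
rule_sentences <- function(rules) {
  stopifnot(inherits(rules, "rule_base"))
  out <- character(25)
  for (i in 1:5) {
    for (j in 1:5) {
      out[5 * (i - 1) + j] <- sprintf(
        "If (%s is %s) and (%s is %s), then (%s is %s)",
        rules$input1, TERM_LABELS[i],
        rules$input2, TERM_LABELS[j],
        rules$output, TERM_LABELS[rules$matrix[i, j]])
    }
  }
  out
}

#' @export
print.rule_base <- function(x, ...) {
  cat(sprintf("Rule base: %s x %s -> %s\n", x$input1, x$input2, x$output))
  print(base::matrix(TERM_LABELS[x$matrix], 5, 5,
                     dimnames = dimnames(x$matrix)))
  invisible(x)
}
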