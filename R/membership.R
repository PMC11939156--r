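#' Triangular membership function
#'
#' Constructs a triangular membership function with left foot `a`, peak `b`
#' and right foot `c` (all in the units of the variable it describes). The
#' degenerate cases `a == b` and `b == c` give left/right shoulders, used for
#' the outermost terms of a partition so that the universe endpoints carry
#' full membership in the extreme terms.
#'
#' @param a Left foot.
#' @param b Peak (degree 1).
#' @param c Right foot.
#' @return An object of class `tri_mf`.
#' @examples
#' mf <- tri_mf(1, 3.25, 5.5)
#' mf_degree(mf, c(1, 2.125, 3.25, 5.5))
#' @export
tri_mf <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1, length(b) == 1, length(c) == 1,
            is.finite(a), is.finite(b), is.finite(c))
  if (!(a <= b && b <= c)) {
    stop("triangular membership function requires a <= b <= c", call. = FALSE)
  }
  if (!(a < c)) {
    stop("degenerate support: a must be strictly less than c", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, kind = "triangular"), class = "tri_mf")
}

#' Membership degree of a triangular function
#'
#' Piecewise-linear degree: 0 outside `[a, c]`, rising linearly on `[a, b]`,
#' falling linearly on `[b, c]`, 1 at the peak. Total function of x
#' (vectorised); never errors.
#'
#' @param mf A [tri_mf()] object.
#' @param x Numeric vector of crisp values.
#' @return Numeric vector of degrees in `[0, 1]`.
#' @export
mf_degree <- function(mf, x) {
  stopifnot(inherits(mf, "tri_mf"))
  d <- numeric(length(x))
  if (mf$b > mf$a) {
    i <- x >= mf$a & x <= mf$b
    d[i] <- (x[i] - mf$a) / (mf$b - mf$a)
  }
  if (mf$c > mf$b) {
    j <- x > mf$b & x <= mf$c
    d[j] <- (mf$c - x[j]) / (mf$c - mf$b)
  }
  d[x == mf$b] <- 1
  d
}

#' Uniform five-term Ruspini partition of an interval
#'
#' Places the five linguistic-term peaks evenly from `lo` to `hi`
#' (at `lo + k (hi - lo) / 4`, k = 0..4) with each triangle's feet at the
#' adjacent peaks. The two end terms have a degenerate outer limb (shoulder),
#' so degrees sum to exactly 1 at every point of `[lo, hi]` (a Ruspini
#' partition).
#'
#' @param lo,hi Universe bounds, `lo < hi`.
#' @return List of 5 [tri_mf()] objects, ordered Vs to VB.
#' @export
uniform_partition <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1, length(hi) == 1,
            is.finite(lo), is.finite(hi))
  if (!(lo < hi)) {
    stop("invalid universe: lo must be strictly less than hi", call. = FALSE)
  }
  p <- lo + (0:4) * (hi - lo) / 4
  lapply(1:5, function(k) {
    tri_mf(if (k == 1) p[1] else p[k - 1],
           p[k],
           if (k == 5) p[5] else p[k + 1])
  })
}

#' Linguistic term labels used throughout the system
#'
#' Very small, small, medium, big, very big; ordinals 1 to 5.
#' @export
TERM_LABELS <- c("Vs", "s", "Md", "B", "VB")

#' Linguistic variable with a five-term partition
#'
#' A named variable with universe `[lo, hi]` and an ordered five-term
#' partition labelled Vs, s, Md, B, VB (ordinals 1-5). By default the terms
#' form the uniform Ruspini partition of [uniform_partition()].
#'
#' @param name Variable name (used in rule sentences and error messages).
#' @param lo,hi Universe bounds, `lo < hi`.
#' @param mfs Optional list of 5 `tri_mf` objects with strictly increasing
#'   peaks spanning `lo` to `hi`; defaults to the uniform partition.
#' @return An object of class `lingvar`.
#' @export
linguistic_variable <- function(name, lo, hi, mfs = uniform_partition(lo, hi)) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(lo < hi)) {
    stop("invalid universe for '", name, "': lo must be < hi", call. = FALSE)
  }
  stopifnot(length(mfs) == 5, all(vapply(mfs, inherits, TRUE, "tri_mf")))
  peaks <- vapply(mfs, function(m) m$b, numeric(1))
  if (any(diff(peaks) <= 0)) {
    stop("term peaks must be strictly increasing across the universe",
         call. = FALSE)
  }
  structure(list(name = name, lo = lo, hi = hi,
                 labels = TERM_LABELS, mfs = mfs),
            class = "lingvar")
}

#' @export
print.lingvar <- function(x, ...) {
  cat(sprintf("Linguistic variable '%s' on [%g, %g]\n", x$name, x$lo, x$hi))
  for (k in 1:5) {
    m <- x$mfs[[k]]
    cat(sprintf("  %-2s (%d): tri(%g, %g, %g)\n",
                x$labels[k], k, m$a, m$b, m$c))
  }
  invisible(x)
}

#' Fuzzify crisp values against a linguistic variable
#'
#' Clamps each value to the variable's universe, then evaluates the degree of
#' every term. For Ruspini partitions the five degrees sum to 1 at every
#' point, so clamped out-of-range values behave exactly like the nearest
#' universe bound.
#'
#' @param var A [linguistic_variable()].
#' @param x Numeric vector of crisp values (any finite real; clamped).
#' @return Numeric matrix, `length(x)` rows by 5 columns (Vs..VB).
#' @export
fuzzify <- function(var, x) {
  stopifnot(inherits(var, "lingvar"), is.numeric(x))
  xc <- pmin(pmax(x, var$lo), var$hi)
  deg <- vapply(var$mfs, mf_degree, numeric(length(x)), x = xc)
  matrix(deg, nrow = length(x), ncol = 5,
         dimnames = list(NULL, var$labels))
}
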