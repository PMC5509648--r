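# Homogeneous-motif significance bound.
#
# A discovered DOM could in principle be a "homogeneous" motif that
# matches every subject, case or control, with the same unknown
# probability p, and landed on a of |A| cases and 0 of |B| controls by
# chance. The probability of that event,
#   choose(|A|, a) p^a (1-p)^(|A|-a) * (1-p)^|B|,
# is maximized over p at p = w = a/(|A|+|B|), giving the closed form
#   ML(a,|A|,|B|) = choose(|A|, a) (1-w)^(a(1/w-1)) w^a,
# where the exponent a(1/w - 1) equals the integer |A|+|B|-a and is
# computed exactly as such. Over a search that scored C motifs, the
# expected number of spurious homogeneous DOMs with a or more case
# matches is bounded by Mev = C * sum_{i=a}^{|A|} ML(i,|A|,|B|).
#
# The fast path works in log space (lchoose + log1p); an independent
# factored-product evaluation (.ml_factored) pairs each binomial factor
# with a power of w so every partial product stays in double range, and
# serves as the in-package cross-check of the log-space path.

.check_ml_args <- function(a, size_a, size_b) {
  if (any(a < 1L)) stop("a must be >= 1: w = 0 is outside the bound's domain")
  if (any(a > size_a)) stop("a cannot exceed |A|")
  if (size_a < 1L || size_b < 0L) stop("need |A| >= 1 and |B| >= 0")
}

#' Homogeneous-motif probability bound ML
#'
#' Upper bound on the probability that a motif matching every subject
#' with one common (unknown) probability matches exactly `a` of the
#' `size_a` category-A subjects and none of the `size_b` category-B
#' subjects: `ML(a,|A|,|B|) = choose(|A|,a) (1-w)^(a(1/w-1)) w^a` with
#' `w = a/(|A|+|B|)`. Vectorized over `a`.
#'
#' @param a Integer vector of category-A match counts, `1 <= a <= size_a`.
#' @param size_a,size_b Category sizes `|A| >= 1`, `|B| >= 0`.
#' @param log If `TRUE`, return the natural log of the bound.
#' @return Numeric vector of probabilities in `(0, 1]` (or their logs).
#' @export
#' @examples
#' ml_bound(30, 51, 46)
ml_bound <- function(a, size_a, size_b, log = FALSE) {
  a <- as.integer(a)
  .check_ml_args(a, size_a, size_b)
  n <- size_a + size_b
  w <- a / n
  e <- n - a                       # a(1/w - 1) is exactly this integer
  log_ml <- lchoose(size_a, a) + ifelse(e == 0L, 0, e * log1p(-w)) +
    a * log(w)
  if (log) log_ml else exp(log_ml)
}

# Independent verification path: direct factored product, no logs.
# choose(A,a) w^a = prod_{i=1..a} ((A-a+i)/i * w); each factor is O(A),
# and the trailing (1-w)^(n-a) is applied stepwise.
ml_factored <- function(a, size_a, size_b) {
  a <- as.integer(a)
  .check_ml_args(a, size_a, size_b)
  vapply(a, function(ai) {
    n <- size_a + size_b
    w <- ai / n
    acc <- 1
    for (i in seq_len(ai)) acc <- acc * ((size_a - ai + i) / i) * w
    e <- n - ai
    if (e > 0L) for (i in seq_len(e)) acc <- acc * (1 - w)
    acc
  }, numeric(1))
}

#' Maximum Expected Value of spurious homogeneous DOMs
#'
#' `Mev = C * sum_{i=a}^{|A|} ML(i,|A|,|B|)`: an upper bound on the
#' expected number of homogeneous motifs that reach `a` or more
#' category-A matches with zero category-B matches anywhere among the
#' `C` motifs a search traversed. `Mev` well below one means the
#' discovered DOM is unlikely to be a chance artifact.
#'
#' @param c_motifs Number of motifs traversed by the search, `C >= 0`.
#' @inheritParams ml_bound
#' @return A single non-negative number, exactly linear in `c_motifs`.
#' @export
#' @examples
#' mev(2743571, 30, 51, 46)
mev <- function(c_motifs, a, size_a, size_b) {
  stopifnot(length(a) == 1L, c_motifs >= 0)
  .check_ml_args(as.integer(a), size_a, size_b)
  c_motifs * sum(ml_bound(seq.int(a, size_a), size_a, size_b))
}

#' The -ln(Mev) significance curve
#'
#' Evaluates `Mev` (and its negative log) for every possible DOM match
#' count `a = 1..|A|` at a fixed traversal size `C`. The sign change of
#' `-ln(Mev)` locates the match count above which a DOM cannot plausibly
#' be a traversal artifact.
#'
#' @inheritParams mev
#' @return A data.frame with columns `a`, `mev`, `neg_ln_mev`.
#' @export
#' @examples
#' head(mev_curve(2743571, 51, 46))
mev_curve <- function(c_motifs, size_a, size_b) {
  a <- seq_len(size_a)
  m <- vapply(a, function(ai) mev(c_motifs, ai, size_a, size_b), numeric(1))
  data.frame(a = a, mev = m, neg_ln_mev = -log(m))
}

#' Significance report for a discovered DOM
#'
#' Bundles the homogeneous-motif bound for one DOM discovered by a run
#' that traversed `c_motifs` motifs.
#'
#' @inheritParams mev
#' @return A `haystack_significance` with fields `a`, `size_a`,
#'   `size_b`, `c_motifs`, `w`, `ml_value`, `mev`, `neg_ln_mev`.
#' @export
#' @examples
#' significance_report(30, 51, 46, 2743571)
significance_report <- function(a, size_a, size_b, c_motifs) {
  a <- as.integer(a)
  .check_ml_args(a, size_a, size_b)
  m <- mev(c_motifs, a, size_a, size_b)
  structure(list(
    a = a, size_a = size_a, size_b = size_b, c_motifs = c_motifs,
    w = a / (size_a + size_b),
    ml_value = ml_bound(a, size_a, size_b),
    mev = m,
    neg_ln_mev = -log(m)
  ), class = "haystack_significance")
}

#' @export
print.haystack_significance <- function(x, ...) {
  cat("<significance> a = ", x$a, " of |A| = ", x$size_a, ", |B| = ",
      x$size_b, ", C = ", format(x$c_motifs, big.mark = ","),
      "\n  ML = ", signif(x$ml_value, 4), "  Mev = ", signif(x$mev, 4),
      "  -ln(Mev) = ", signif(x$neg_ln_mev, 4), "\n", sep = "")
  invisible(x)
}
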