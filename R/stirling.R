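# Exact unsigned Stirling numbers of the first kind (arbitrary-precision
# integers) and Fu's Fs via the Ewens sampling formula.
#
# |s(79, j)| reaches ~10^115, far beyond double precision, so the numbers
# are carried as exact base-1e7 little-endian limb vectors (each limb an
# integer-valued double; limb * 78 + carry stays well below 2^53).

.bn_base <- 1e7

bn <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  if (x == 0) return(0)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% .bn_base)
    x <- x %/% .bn_base
  }
  limbs
}

bn_norm <- function(x) {
  while (any(x >= .bn_base)) {
    carry <- x %/% .bn_base
    x <- x %% .bn_base
    x <- x + c(0, carry)[seq_along(x)]
    if (utils::tail(carry, 1) > 0) x <- c(x, utils::tail(carry, 1))
  }
  while (length(x) > 1 && utils::tail(x, 1) == 0) x <- x[-length(x)]
  x
}

bn_add <- function(a, b) {
  n <- max(length(a), length(b))
  bn_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# multiply by a small non-negative integer scalar (< 1e7)
bn_smul <- function(a, s) {
  stopifnot(s >= 0, s < .bn_base)
  if (s == 0) return(0)
  bn_norm(a * s)
}

bn_is_zero <- function(a) length(a) == 1 && a[1] == 0

# natural log; the top three limbs (21 digits) give full double accuracy
bn_log <- function(a) {
  if (bn_is_zero(a)) return(-Inf)
  k <- length(a)
  top <- a[max(1, k - 2):k]
  mant <- sum(top * .bn_base^(seq_along(top) - 1))
  log(mant) + (max(1, k - 2) - 1) * log(.bn_base)
}

bn_format <- function(a) {
  if (bn_is_zero(a)) return("0")
  digits <- sprintf("%07.0f", rev(a))
  digits[1] <- sub("^0+", "", digits[1])
  paste(digits, collapse = "")
}

#' Exact unsigned Stirling numbers of the first kind
#'
#' Computes the full row |s(n, j)| for j = 0..n by the recurrence
#' |s(n, j)| = |s(n-1, j-1)| + (n-1) |s(n-1, j)| in exact arbitrary-precision
#' integer arithmetic. These count permutations of n elements with j cycles
#' and drive the Ewens sampling formula: sum_j |s(n,j)| theta^j equals the
#' rising factorial theta(theta+1)...(theta+n-1).
#'
#' @param n Sample size (>= 1).
#' @return A `stirling_table`: list of exact integers (internal limb
#'   representation), element j+1 holding |s(n, j)|. Use [as.character()] for
#'   decimal strings and [stirling_log()] for natural logs.
#' @export
#' @examples
#' as.character(unsigned_stirling_first(5))
unsigned_stirling_first <- function(n) {
  stopifnot(n >= 1, n == floor(n))
  row <- list(bn(1))  # n = 0: s(0,0) = 1
  for (m in seq_len(n)) {
    new <- vector("list", m + 1)
    new[[1]] <- 0  # s(m, 0) = 0 for m >= 1
    for (j in seq_len(m)) {
      lower <- if (j <= m - 1) bn_smul(row[[j + 1]], m - 1) else 0
      new[[j + 1]] <- bn_add(row[[j]], lower)
    }
    row <- new
  }
  structure(row, class = "stirling_table", n = n)
}

#' @export
as.character.stirling_table <- function(x, ...) {
  vapply(unclass(x), bn_format, "")
}

#' @rdname unsigned_stirling_first
#' @param x A `stirling_table`.
#' @return `stirling_log()`: numeric vector of log |s(n, j)|, j = 0..n
#'   (`-Inf` for zero entries).
#' @export
stirling_log <- function(x) {
  stopifnot(inherits(x, "stirling_table"))
  vapply(unclass(x), bn_log, numeric(1))
}

#' @export
print.stirling_table <- function(x, ...) {
  n <- attr(x, "n")
  s <- as.character(x)
  cat("<stirling_table> |s(", n, ", j)| for j = 0..", n, "\n", sep = "")
  utils::str(s, vec.len = 3)
  invisible(x)
}

# pure floating route: log |s(n, j)| by the same recurrence in log space
stirling_log_float <- function(n) {
  row <- 0  # log s(0,0)
  for (m in seq_len(n)) {
    prev <- c(row, -Inf)
    new <- rep(-Inf, m + 1)
    for (j in seq_len(m)) {
      a <- prev[j]                     # log s(m-1, j-1)
      b <- log(m - 1) + prev[j + 1]    # log((m-1) s(m-1, j))
      hi <- pmax(a, b)
      new[j + 1] <- if (is.infinite(hi)) hi else hi + log1p(exp(min(a, b) - hi))
    }
    row <- new
  }
  row
}

.stirling_cache <- new.env(parent = emptyenv())

cached_stirling_logs <- function(n, method) {
  key <- paste0(method, n)
  if (is.null(.stirling_cache[[key]])) {
    .stirling_cache[[key]] <- if (method == "exact") {
      stirling_log(unsigned_stirling_first(n))
    } else {
      stirling_log_float(n)
    }
  }
  .stirling_cache[[key]]
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0 || all(is.infinite(x) & x < 0)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fu's Fs
#'
#' Fu's Fs compares the observed number of haplotypes h against the number
#' expected under neutrality given the observed mean pairwise differences k.
#' With theta = k, the Ewens sampling formula gives
#' S' = P(K >= h) = sum_{j=h}^{n} |s(n, j)| theta^j / (theta)_n, where
#' (theta)_n is the rising factorial, and Fs = ln(S' / (1 - S')). Strongly
#' negative values indicate an excess of rare haplotypes (population
#' expansion); positive values a deficit (bottleneck). The odds are evaluated
#' as the ratio of the two tail sums, so the rising factorial cancels and no
#' overflow occurs even at n = 79 and beyond.
#'
#' @param n Sample size (>= 2).
#' @param h Observed number of haplotypes (1 <= h <= n).
#' @param k Mean pairwise differences of the same sample, used as the theta
#'   estimate (> 0).
#' @param method `"exact"` (big-integer Stirling numbers, default) or
#'   `"log"` (floating log-space recurrence); the two agree to < 1e-6.
#' @return Fs. `+Inf` when h = 1 (S' = 1, the statistic is undefined);
#'   `NA` when k <= 0.
#' @export
#' @examples
#' fus_fs(3, 2, 1)   # log(2)
fus_fs <- function(n, h, k, method = c("exact", "log")) {
  method <- match.arg(method)
  stopifnot(n >= 2, h >= 1, h <= n)
  if (is.na(k) || k <= 0) {
    warning("Fu's Fs is undefined for k <= 0", call. = FALSE)
    return(NA_real_)
  }
  if (h == 1) return(Inf)
  ls <- cached_stirling_logs(n, method)
  terms <- ls[2:(n + 1)] + seq_len(n) * log(k)  # j = 1..n
  logsumexp(terms[h:n]) - logsumexp(terms[seq_len(h - 1)])
}

#' Tail probability of the haplotype count under the Ewens sampling formula
#'
#' P(K >= h) for a neutral sample of size n at scaled mutation rate theta,
#' using exact Stirling numbers.
#'
#' @inheritParams fus_fs
#' @param theta Scaled mutation rate (> 0).
#' @return Probability in [0, 1].
#' @export
ewens_haplotype_tail <- function(n, h, theta) {
  stopifnot(n >= 1, h >= 1, h <= n, theta > 0)
  ls <- cached_stirling_logs(n, "exact")
  terms <- ls[2:(n + 1)] + seq_len(n) * log(theta)
  lrising <- sum(log(theta + 0:(n - 1)))
  exp(logsumexp(terms[h:n]) - lrising)
}
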