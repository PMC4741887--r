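# Expression normalization and replicate-free differential expression.
#
# With one sample per (patient, stage) there are no biological replicates,
# so differential expression between two samples is assessed with the
# Audic-Claverie exact count test: conditional on observing x tags out of
# N1 in one library, the count y out of N2 in the other has point
# probability
#
#   p(y | x) = r^y * (x+y)! / (x! y! (1+r)^(x+y+1)),   r = N2/N1,
#
# which is the negative binomial with size x+1 and success probability
# N1/(N1+N2). Tails are therefore computed with pnbinom(), which is stable
# in log space for counts up to at least 1e7.

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `1e9 * C / (N * L)` for count C, library size N and transcript length L
#' in bp. Requires feature lengths on the count matrix.
#'
#' @param cm a [count_matrix()] with `feature_lengths`.
#' @return An `expression_matrix`: list with `values` (features x samples)
#'   and `unit = "RPKM"`.
#' @export
compute_rpkm <- function(cm) {
  if (is.null(cm$feature_lengths))
    stop("RPKM requires feature lengths; none present")
  v <- 1e9 * sweep(cm$counts, 2, cm$library_sizes, "/") / cm$feature_lengths
  structure(list(values = v, unit = "RPKM"), class = "expression_matrix")
}

#' Tags-per-million normalization (for features without lengths, e.g. miRNA)
#'
#' `1e6 * C / N`.
#' @param cm a [count_matrix()].
#' @return An `expression_matrix` with `unit = "per_million"`.
#' @export
compute_per_million <- function(cm) {
  v <- 1e6 * sweep(cm$counts, 2, cm$library_sizes, "/")
  structure(list(values = v, unit = "per_million"), class = "expression_matrix")
}

#' Normalize a count matrix (RPKM when lengths are present, else per-million)
#' @export
normalize_counts <- function(cm) {
  if (is.null(cm$feature_lengths)) compute_per_million(cm) else compute_rpkm(cm)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", x$unit, "): ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Pseudocounted log2 fold change
#'
#' `log2((a + pseudo) / (b + pseudo))`; 0/0 is a fold change of 0 by
#' construction. Vectorized.
#'
#' @param a,b non-negative expression values (numerator a, denominator b).
#' @param pseudo positive pseudocount, default 0.5.
#' @export
log2_ratio <- function(a, b, pseudo = 0.5) {
  stopifnot(pseudo > 0)
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  log2((a + pseudo) / (b + pseudo))
}

#' Point probability of the replicate-free exact count test
#'
#' P(Y = y | x) under the Audic-Claverie model for libraries of sizes
#' N1 (where x was seen) and N2 (where y was seen). Vectorized.
#' @export
ac_point_prob <- function(x, y, N1, N2) {
  check_pair(x, y, N1, N2)
  stats::dnbinom(y, size = x + 1, prob = N1 / (N1 + N2))
}

check_pair <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0) || any(x != round(x)) || any(y != round(y)))
    stop("counts must be non-negative integers")
  if (any(N1 < 1) || any(N2 < 1)) stop("library sizes must be >= 1")
  if (any(x > N1) || any(y > N2)) stop("count exceeds its library size")
  invisible(TRUE)
}

#' Replicate-free exact test for a pair of counts
#'
#' Compares one count per condition given the two library sizes. The
#' two-sided p-value is the doubled smaller tail, capped at 1:
#' `min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`. One-sided alternatives
#' return the corresponding single tail ("greater" tests for y larger than
#' expected under the null). Vectorized over x, y (and the library sizes).
#'
#' @param x,y observed counts in condition 1 and 2.
#' @param N1,N2 library sizes of condition 1 and 2.
#' @param alternative "two_sided" (default), "greater" or "less".
#' @return p-value(s) in (0, 1].
#' @export
ac_exact_test <- function(x, y, N1, N2,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_pair(x, y, N1, N2)
  prob <- N1 / (N1 + N2)
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  upper <- stats::pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE)
  switch(alternative,
         two_sided = pmin(1, 2 * pmin(lower, upper)),
         greater   = upper,
         less      = lower)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values in the input order (via [stats::p.adjust()]).
#' @param p p-values in \[0, 1\].
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression thresholds
#'
#' @param min_abs_log2fc minimum absolute log2 fold change for a call
#'   (default 1, i.e. the two-fold cutoff).
#' @param max_q maximum FDR-adjusted q-value (default 0.05).
#' @param pseudo pseudocount for fold changes (default 0.5).
#' @param fc_on compute fold changes on "normalized" expression (default) or
#'   raw "counts".
#' @export
de_thresholds <- function(min_abs_log2fc = 1, max_q = 0.05, pseudo = 0.5,
                          fc_on = c("normalized", "counts")) {
  fc_on <- match.arg(fc_on)
  stopifnot(min_abs_log2fc >= 0, max_q >= 0, max_q <= 1, pseudo > 0)
  list(min_abs_log2fc = min_abs_log2fc, max_q = max_q, pseudo = pseudo,
       fc_on = fc_on)
}

#' Differential-expression call for one feature between two samples
#'
#' Condition 2 versus condition 1: `log2fc > 0` means higher in condition 2.
#' Direction is `"up"`/`"down"` only when both the fold-change and q-value
#' thresholds pass, else `"none"`. When no multiplicity-adjusted q is
#' supplied (single-feature use) q equals p.
#'
#' @param x,y counts in conditions 1 and 2.
#' @param N1,N2 library sizes.
#' @param thresholds a [de_thresholds()] list.
#' @param q optional FDR-adjusted q-value computed over the full feature set.
#' @return data.frame row: log2fc, p, q, direction.
#' @export
de_call <- function(x, y, N1, N2, thresholds = de_thresholds(), q = NULL) {
  p <- ac_exact_test(x, y, N1, N2)
  if (is.null(q)) q <- p
  if (thresholds$fc_on == "normalized") {
    a <- 1e6 * y / N2
    b <- 1e6 * x / N1
  } else {
    a <- y
    b <- x
  }
  lfc <- log2_ratio(a, b, thresholds$pseudo)
  dir <- rep("none", length(lfc))
  pass <- abs(lfc) >= thresholds$min_abs_log2fc & q <= thresholds$max_q
  dir[pass & lfc > 0] <- "up"
  dir[pass & lfc < 0] <- "down"
  data.frame(log2fc = lfc, p = p, q = q, direction = dir,
             stringsAsFactors = FALSE)
}

#' Per-feature differential-expression table between two samples
#'
#' Runs the exact test for every feature of a count matrix between two of
#' its samples, adjusts across features with Benjamini-Hochberg, and calls
#' direction. Fold changes are condition `sample_b` versus `sample_a`.
#'
#' @param cm a [count_matrix()].
#' @param sample_a,sample_b sample ids (condition 1 and 2).
#' @param thresholds a [de_thresholds()] list.
#' @return data.frame: feature_id, count_a, count_b, log2fc, p, q, direction.
#' @export
de_table <- function(cm, sample_a, sample_b, thresholds = de_thresholds()) {
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(cm$counts)) stop("unknown sample: ", s)
  x <- cm$counts[, sample_a]
  y <- cm$counts[, sample_b]
  N1 <- cm$library_sizes[[sample_a]]
  N2 <- cm$library_sizes[[sample_b]]
  p <- ac_exact_test(x, y, N1, N2)
  q <- bh_fdr(p)
  call <- de_call(x, y, N1, N2, thresholds, q = q)
  data.frame(feature_id = rownames(cm$counts), count_a = x, count_b = y,
             call, row.names = NULL, stringsAsFactors = FALSE)
}
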