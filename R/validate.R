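# Validation-side computations: qPCR relative quantification (2^-ddCt),
# weighted immunohistochemistry scoring (c = a x b), Spearman rank
# correlation and the Mann-Whitney U test (exact by enumeration for small
# samples, normal approximation with tie correction otherwise).

#' Read a qPCR Ct table
#'
#' TSV with columns sample_id, group ("case"/"control"), ct_target,
#' ct_reference (the endogenous control, e.g. U6 or GAPDH).
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "ct_target", "ct_reference")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("Ct table missing column(s): ",
                         paste(miss, collapse = ", "))
  ct <- c(df$ct_target, df$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct >= 50))
    stop("Ct values must lie in (0, 50)")
  df
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per record, dCt = Ct(target) - Ct(reference). The calibrator is the mean
#' dCt over the control records; each case record's fold change is
#' 2^-(dCt_case - dCt_calibrator).
#'
#' @param case data.frame (or list) with `ct_target` and `ct_reference` for
#'   the case/treated group.
#' @param control same for the control/calibrator group; multiple records
#'   are averaged on the dCt scale.
#' @return Numeric vector of fold changes, one per case record.
#' @export
ddct_fold <- function(case, control) {
  dct_case <- case$ct_target - case$ct_reference
  dct_ctrl <- mean(control$ct_target - control$ct_reference)
  2^(-(dct_case - dct_ctrl))
}

#' Bin percent-positive cells into the IHC proportion grade
#'
#' Grades: (0) < 5\%, (1) 5-25\%, (2) 25-50\%, (3) 50-75\%, (4) > 75\%.
#' The printed bin boundaries overlap; they are resolved as half-open,
#' lower-inclusive intervals (25\% falls in grade 2).
#' @param percent percent positive tumor cells, in \[0, 100\]. Vectorized.
#' @export
ihc_bin_percent <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100))
    stop("percent positive must lie in [0, 100]")
  findInterval(percent, c(5, 25, 50, 75))
}

#' Weighted IHC evaluation score
#'
#' `c = a * b` for proportion grade a in 0..4 and staining intensity b in
#' 0..3 (0 none, 1 weak, 2 moderate, 3 intense). Vectorized.
#' @export
ihc_score <- function(a, b) {
  if (any(!a %in% 0:4)) stop("proportion grade a must be in 0..4")
  if (any(!b %in% 0:3)) stop("intensity b must be in 0..3")
  as.integer(a * b)
}

#' Read an IHC table
#'
#' TSV with columns sample_id, group, percent_positive, intensity; returns
#' the table with grades `a` and weighted scores `score` appended.
#' @export
read_ihc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "percent_positive", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("IHC table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$a <- ihc_bin_percent(df$percent_positive)
  df$score <- ihc_score(df$a, df$intensity)
  df
}

#' Spearman rank correlation with large-sample p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks under ties);
#' the p-value uses the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom, which is the
#' standard large-sample treatment (and degenerates to p = 0 at rho = +-1).
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return list(rho, n, p).
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 paired observations")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("rank variance is zero; Spearman correlation undefined")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, n = n, p = p)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with mid-ranks for ties:
#' U = R1 - n1(n1+1)/2 where R1 is the rank sum of `x`. The two-sided
#' p-value is exact by enumeration of all choose(n1+n2, n1) group labelings
#' (probability of a U at least as far from n1*n2/2 as observed) when
#' n1 + n2 <= `exact_threshold`; otherwise the normal approximation with
#' tie-corrected variance is used, without continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_threshold enumerate exactly when n1 + n2 is at most this
#'   (default 12).
#' @return list(U, p, method).
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 12) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  if (n <= exact_threshold) {
    idx <- utils::combn(n, n1)
    r1 <- colSums(matrix(r[idx], nrow = n1))
    u_all <- r1 - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(U = U, p = min(1, p), method = method)
}

#' Validation statistics over Ct and IHC tables
#'
#' Computes per-case 2^-ddCt fold changes with a Mann-Whitney comparison of
#' the case and control dCt values, per-sample weighted IHC scores with a
#' case-vs-control Mann-Whitney test, and (when two IHC marker tables are
#' supplied) the Spearman correlation between their per-sample scores.
#'
#' @param ct Ct data.frame (see [read_ct_table()]); NULL to skip.
#' @param ihc IHC data.frame (see [read_ihc_table()]); NULL to skip.
#' @param ihc2 optional second-marker IHC data.frame; samples are paired by
#'   sample_id.
#' @return list with elements `qpcr`, `ihc`, `marker_correlation` (NULL when
#'   not computable).
#' @export
validation_stats <- function(ct = NULL, ihc = NULL, ihc2 = NULL) {
  out <- list(qpcr = NULL, ihc = NULL, marker_correlation = NULL)
  if (!is.null(ct)) {
    case <- ct[ct$group == "case", , drop = FALSE]
    ctrl <- ct[ct$group == "control", , drop = FALSE]
    if (!nrow(case) || !nrow(ctrl))
      stop("Ct table needs both 'case' and 'control' groups")
    folds <- ddct_fold(case, ctrl)
    mw <- mann_whitney_u(case$ct_target - case$ct_reference,
                         ctrl$ct_target - ctrl$ct_reference)
    out$qpcr <- list(folds = stats::setNames(folds, case$sample_id),
                     mean_fold = mean(folds), mw = mw)
  }
  if (!is.null(ihc)) {
    if (is.null(ihc$score)) {
      ihc$a <- ihc_bin_percent(ihc$percent_positive)
      ihc$score <- ihc_score(ihc$a, ihc$intensity)
    }
    case <- ihc[ihc$group == "case", , drop = FALSE]
    ctrl <- ihc[ihc$group == "control", , drop = FALSE]
    mw <- if (nrow(case) && nrow(ctrl))
      mann_whitney_u(case$score, ctrl$score) else NULL
    out$ihc <- list(scores = ihc, mw = mw)
  }
  if (!is.null(ihc) && !is.null(ihc2)) {
    if (is.null(ihc2$score)) {
      ihc2$a <- ihc_bin_percent(ihc2$percent_positive)
      ihc2$score <- ihc_score(ihc2$a, ihc2$intensity)
    }
    common <- intersect(ihc$sample_id, ihc2$sample_id)
    if (length(common) >= 3) {
      s1 <- ihc$score[match(common, ihc$sample_id)]
      s2 <- ihc2$score[match(common, ihc2$sample_id)]
      out$marker_correlation <- tryCatch(spearman_rho(s1, s2),
                                         error = function(e) NULL)
    }
  }
  out
}
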