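# Independent oracles: brute-force / closed-form implementations that the
# package routines are checked against. They deliberately share no code
# path with the package.

# Point probability of the replicate-free exact test by direct log-gamma
# evaluation of the series term (no distribution functions).
oracle_ac_point <- function(x, y, N1, N2) {
  r <- N2 / N1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

# Two-sided p by summing the series over y' until the upper tail is
# negligible.
oracle_ac_two_sided <- function(x, y, N1, N2, tail_tol = 1e-12) {
  ymax <- y
  repeat {
    ymax <- ymax + 50
    probs <- oracle_ac_point(x, 0:ymax, N1, N2)
    if (1 - sum(probs) < tail_tol) break
    if (ymax > 1e6) stop("oracle series did not converge")
  }
  lower <- sum(probs[seq_len(y + 1)])
  upper <- 1 - sum(probs[seq_len(y)])  # P(Y >= y); empty sum when y = 0
  min(1, 2 * min(lower, upper))
}

# Benjamini-Hochberg by the literal step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    q[ord[i]] <- running
  }
  q
}

# Exhaustive seed-site scanner: slide over every position, compare
# substrings for every class, then apply the same containment-collapse
# rule by nested loops.
oracle_scan <- function(utr_seq, mirna_seq) {
  seq <- chartr("U", "T", toupper(utr_seq))
  s <- chartr("U", "T", toupper(mirna_seq))
  rc <- function(z) paste(rev(strsplit(chartr("ACGT", "TGCA", z), "")[[1]]),
                          collapse = "")
  pats <- list("6mer" = rc(substr(s, 2, 7)),
               "7mer-A1" = paste0(rc(substr(s, 2, 7)), "A"),
               "7mer-m8" = rc(substr(s, 2, 8)),
               "8mer" = paste0(rc(substr(s, 2, 8)), "A"))
  rank <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  cand <- list()
  L <- nchar(seq)
  for (cl in names(pats)) {
    k <- nchar(pats[[cl]])
    if (L < k) next
    for (st in 1:(L - k + 1)) {
      if (substr(seq, st, st + k - 1) == pats[[cl]])
        cand[[length(cand) + 1]] <- data.frame(
          start = st, end = st + k - 1L, site_class = cl,
          matched_seq = pats[[cl]], stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(data.frame(start = integer(), end = integer(),
                                       site_class = character(),
                                       matched_seq = character(),
                                       stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  drop <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) for (j in seq_len(nrow(cand))) {
    if (i == j) next
    if (!drop[j] && rank[cand$site_class[j]] > rank[cand$site_class[i]] &&
        cand$start[j] <= cand$start[i] && cand$end[j] >= cand$end[i])
      drop[i] <- TRUE
  }
  out <- cand[!drop, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact Mann-Whitney by enumerating group labelings of the pooled values
# and counting x>y / tied pairs directly (pair-count definition of U,
# an independent route from the rank-sum formula).
oracle_mwu_exact <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  n <- length(pool)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, function(idx) u_of(pool[idx], pool[-idx]))
  list(U = u_obs,
       p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Mid-rank Spearman by explicit rank construction and the Pearson formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(a) sum(v < a) + (1 + sum(v == a)) / 2)
  }
  rx <- midrank(x)
  ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
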