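# Independent oracles, deliberately naive: enumeration and closed forms
# that share no code with the implementation paths they check.

# Exhaustive Gini-minimizing stump: try every midpoint between distinct
# sorted feature values, score with the textbook weighted impurity.
brute_stump <- function(x, y) {
  n <- length(x)
  npos <- sum(y == 1)
  gini <- function(v) {
    if (length(v) == 0L) return(0)
    p <- mean(v == 1)
    1 - p^2 - (1 - p)^2
  }
  leaf <- function(v) {
    pos <- sum(v == 1)
    neg <- length(v) - pos
    list(cls = if (pos > neg) 1 else -1, prob = max(pos, neg) / length(v))
  }
  sx <- sort(unique(x))
  if (npos == 0L || npos == n || length(sx) < 2L) {
    cls <- if (2L * npos > n) 1 else -1
    pr <- max(npos, n - npos) / n
    return(list(threshold = -Inf, class_low = cls, class_high = cls,
                prob_low = pr, prob_high = pr, impurity = gini(y)))
  }
  thrs <- (sx[-length(sx)] + sx[-1L]) / 2
  # exact rational impurity comparison: weighted impurity at threshold t
  # equals [(nL^2 - pL^2 - qL^2) * nR + (nR^2 - pR^2 - qR^2) * nL] /
  # (n * nL * nR); numerators/denominators stay integer-exact in doubles
  frac <- lapply(thrs, function(t) {
    L <- y[x <= t]
    R <- y[x > t]
    nL <- length(L); nR <- length(R)
    pL <- sum(L == 1); qL <- nL - pL
    pR <- sum(R == 1); qR <- nR - pR
    list(num = (nL^2 - pL^2 - qL^2) * nR + (nR^2 - pR^2 - qR^2) * nL,
         den = nL * nR)
  })
  lt <- function(a, b) a$num * b$den < b$num * a$den
  eq <- function(a, b) a$num * b$den == b$num * a$den
  bi <- 1L
  for (j in seq_along(frac)[-1L]) if (lt(frac[[j]], frac[[bi]])) bi <- j
  ties <- thrs[vapply(frac, eq, logical(1L), b = frac[[bi]])]
  imps <- vapply(thrs, function(t) {
    L <- y[x <= t]
    R <- y[x > t]
    length(L) / n * gini(L) + length(R) / n * gini(R)
  }, numeric(1L))
  best <- imps[match(ties[1L], thrs)]
  t0 <- ties[1L]                       # smallest threshold on ties
  lo <- leaf(y[x <= t0])
  hi <- leaf(y[x > t0])
  list(threshold = t0, class_low = lo$cls, class_high = hi$cls,
       prob_low = lo$prob, prob_high = hi$prob, impurity = best,
       tie_set = ties, impurity_at = function(t) {
         L <- y[x <= t]; R <- y[x > t]
         length(L) / n * gini(L) + length(R) / n * gini(R)
       })
}

# Direct Eq.-3 arithmetic with the zero-denominator convention.
brute_mcc <- function(TP, TN, FP, FN) {
  den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den2 == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den2)
}

# Closed-form simple OLS.
brute_ols <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  yhat <- b0 + b1 * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = b0, slope = b1, r_squared = r2)
}

# Shorthand: a scale from a plain 20-vector in canonical residue order.
toy_scale <- function(vals, name = "toy") {
  aa_scale(name, structure(vals, names = aa_residues()))
}

# Indicator scale: 1 for one residue, 0 elsewhere.
indicator_scale <- function(residue) {
  v <- numeric(20L)
  v[match(residue, aa_residues())] <- 1
  toy_scale(v, name = paste0("count_", residue))
}
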