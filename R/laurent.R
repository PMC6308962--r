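# Minimal Laurent-polynomial algebra over the shift operator S, where
# (S^m u)_k = u_{k+m} on a circular index set. A Laurent polynomial is
# list(coef, low): coef[j] multiplies S^(low + j - 1). Used only to factor
# wavelet polyphase matrices into lifting steps.

lp <- function(coef, low = 0L) {
  keep <- which(coef != 0)
  if (length(keep) == 0) return(structure(list(coef = 0, low = 0L),
                                          class = "laurent"))
  structure(list(coef = coef[min(keep):max(keep)],
                 low = as.integer(low + min(keep) - 1L)),
            class = "laurent")
}

lp_zero <- function() lp(0)

lp_is_zero <- function(p, tol = 0) all(abs(p$coef) <= tol)

lp_degree <- function(p) if (lp_is_zero(p)) -Inf else length(p$coef) - 1L

lp_add <- function(a, b) {
  low <- min(a$low, b$low)
  high <- max(a$low + length(a$coef), b$low + length(b$coef)) - 1L
  coef <- numeric(high - low + 1L)
  ia <- a$low - low + seq_along(a$coef)
  ib <- b$low - low + seq_along(b$coef)
  coef[ia] <- coef[ia] + a$coef
  coef[ib] <- coef[ib] + b$coef
  lp(coef, low)
}

lp_neg <- function(a) lp(-a$coef, a$low)

lp_sub <- function(a, b) lp_add(a, lp_neg(b))

lp_mul <- function(a, b) {
  if (lp_is_zero(a) || lp_is_zero(b)) return(lp_zero())
  coef <- numeric(length(a$coef) + length(b$coef) - 1L)
  for (i in seq_along(a$coef)) {
    idx <- i:(i + length(b$coef) - 1L)
    coef[idx] <- coef[idx] + a$coef[i] * b$coef
  }
  lp(coef, a$low + b$low)
}

# Division with remainder: a = q*b + r with deg(r) < deg(b). The Laurent
# offset is carried through, so this is ordinary polynomial long division
# on the coefficient vectors (quotient eliminates leading terms).
lp_divmod <- function(a, b) {
  stopifnot(!lp_is_zero(b))
  if (lp_degree(a) < lp_degree(b))
    return(list(q = lp_zero(), r = a))
  ac <- a$coef
  bc <- b$coef
  nq <- length(ac) - length(bc) + 1L
  q <- numeric(nq)
  for (j in nq:1) {
    q[j] <- ac[j + length(bc) - 1L] / bc[length(bc)]
    idx <- j:(j + length(bc) - 1L)
    ac[idx] <- ac[idx] - q[j] * bc
    ac[j + length(bc) - 1L] <- 0   # cancel exactly
  }
  list(q = lp(q, a$low - b$low),
       r = lp(ac, a$low))
}

# reverse a Laurent polynomial: p(S) -> p(1/S)
lp_reverse <- function(p) lp(rev(p$coef), -(p$low + length(p$coef) - 1L))

# division eliminating the *lowest*-order terms instead of the highest
lp_divmod_low <- function(a, b) {
  dm <- lp_divmod(lp_reverse(a), lp_reverse(b))
  list(q = lp_reverse(dm$q), r = lp_reverse(dm$r))
}

# Division zeroing t coefficients at the top of the remainder and the
# rest at the bottom (t = nq reproduces lp_divmod, t = 0 lp_divmod_low);
# solved as an nq x nq linear system in the quotient coefficients.
lp_divmod_split <- function(a, b, t) {
  ac <- a$coef; bc <- b$coef
  na <- length(ac); nb <- length(bc)
  nq <- na - nb + 1L
  zero_pos <- c(seq_len(nq - t), if (t > 0) (na - t + 1L):na)
  M <- matrix(0, nrow = nq, ncol = nq)
  for (r in seq_along(zero_pos)) {
    p <- zero_pos[r]
    for (j in seq_len(nq)) {
      k <- p - j + 1L
      if (k >= 1L && k <= nb) M[r, j] <- bc[k]
    }
  }
  q <- solve(M, ac[zero_pos])
  rc <- ac
  for (j in seq_len(nq)) {
    idx <- j:(j + nb - 1L)
    rc[idx] <- rc[idx] - q[j] * bc
  }
  rc[zero_pos] <- 0
  list(q = lp(q, a$low - b$low), r = lp(rc, a$low))
}

# Laurent division is not unique: any nq coefficients split between the
# two ends of the remainder can be eliminated. Pick the split giving the
# smallest quotient — essential for numerical stability of the Euclidean
# factorization (boundary coefficients of intermediate remainders can be
# nearly zero).
lp_divmod_stable <- function(a, b) {
  if (lp_degree(a) < lp_degree(b)) return(list(q = lp_zero(), r = a))
  nq <- lp_degree(a) - lp_degree(b) + 1L
  best <- NULL
  for (t in 0:nq) {
    cand <- tryCatch(lp_divmod_split(a, b, t), error = function(e) NULL)
    if (is.null(cand)) next
    if (is.null(best) || max(abs(cand$q$coef)) < max(abs(best$q$coef)))
      best <- cand
  }
  if (is.null(best)) stop("Laurent division failed")
  best
}

# prune coefficients that are numerically zero relative to `scale`
lp_chop <- function(p, scale, tol = 1e-11) {
  coef <- p$coef
  coef[abs(coef) <= tol * scale] <- 0
  lp(coef, p$low)
}

# apply p(S) to a vector circularly: sum_j p_j * (u shifted left by m_j)
lp_apply <- function(p, u) {
  n <- length(u)
  out <- numeric(n)
  for (j in seq_along(p$coef)) {
    cj <- p$coef[j]
    if (cj == 0) next
    m <- (p$low + j - 1L) %% n
    out <- out + cj * u[((seq_len(n) - 1L + m) %% n) + 1L]
  }
  out
}
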