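# Lifting realization of the supported wavelets.
#
# The analysis step a = sum_i dec_lo[i] x[2k + L/2 - i] splits x into even
# samples e_k = x[2k] and odd samples o_k = x[2k+1], giving the polyphase
# form [a; d] = P(S) [e; o] with Laurent-polynomial entries in the shift
# operator S. P is factored by the Euclidean algorithm on its lowpass row
# into elementary lifting steps (each step updates one of the two channels
# in place from the other), plus a final channel scaling/shift. Applying
# the steps circularly reproduces the periodized filter-bank transform to
# machine precision; the factorization is computed once per wavelet and
# cached.

polyphase_rows <- function(w) {
  L <- length(w$dec_lo)
  he <- lp_zero(); ho <- lp_zero(); ge <- lp_zero(); go <- lp_zero()
  for (i in 0:(L - 1L)) {
    off <- L %/% 2L - i
    if (off %% 2L == 0L) {
      m <- off %/% 2L
      he <- lp_add(he, lp(w$dec_lo[i + 1L], m))
      ge <- lp_add(ge, lp(w$dec_hi[i + 1L], m))
    } else {
      m <- (off - 1L) %/% 2L
      ho <- lp_add(ho, lp(w$dec_lo[i + 1L], m))
      go <- lp_add(go, lp(w$dec_hi[i + 1L], m))
    }
  }
  list(he = he, ho = ho, ge = ge, go = go)
}

# Factor the analysis polyphase matrix into lifting steps.
# Returns list(quotients = list of Laurent q_i, K = list(coef, shift) for
# the lowpass monomial, C = Laurent lifting into the highpass channel,
# D = monomial scaling of the highpass channel).
lift_factorize <- function(w) {
  pp <- polyphase_rows(w)
  scale <- max(abs(c(pp$he$coef, pp$ho$coef)))
  a <- pp$he; b <- pp$ho
  qs <- list()
  while (!lp_is_zero(b, tol = 1e-12 * scale)) {
    dm <- lp_divmod_stable(a, b)
    qs[[length(qs) + 1L]] <- dm$q
    a <- b
    b <- lp_chop(dm$r, scale)
  }
  if (lp_degree(a) != 0L)
    stop("polyphase gcd is not a monomial for wavelet ", w$name)
  gcd <- a   # K * S^alpha
  # M = A_n ... A_1 with A_i = [[q_i, 1], [1, 0]]; row1 = [gcd, 0] %*% M.
  # Recover row2 factor [C, D] = [ge, go] %*% M^{-1},
  # M^{-1} = A_1^{-1} ... A_n^{-1}, A^{-1} = [[0, 1], [1, -q]].
  C <- pp$ge; D <- pp$go
  for (q in qs) {
    # [C, D] <- [C, D] %*% [[0, 1], [1, -q]]
    newC <- D
    newD <- lp_sub(C, lp_mul(D, q))
    C <- newC
    # chop relative to the step's own scale: large quotients amplify the
    # cancellation residue far above the original filter scale
    D <- lp_chop(newD, max(abs(newD$coef)), tol = 1e-9)
  }
  if (lp_degree(D) != 0L)
    stop("highpass factor is not a monomial for wavelet ", w$name)
  list(quotients = qs, K = gcd, C = C, D = D)
}

lift_cache <- new.env(parent = emptyenv())

lift_scheme <- function(w) {
  key <- w$name
  if (is.null(lift_cache[[key]])) lift_cache[[key]] <- lift_factorize(w)
  lift_cache[[key]]
}

# circular shift: (S^m u)_k = u_{k+m}
circ_shift <- function(u, m) {
  n <- length(u)
  m <- ((m %% n) + n) %% n
  if (m == 0) u else c(u[(m + 1):n], u[1:m])
}

# One analysis step via lifting: returns list(ca, cd), identical to
# dwt_step(x, w) up to round-off.
lift_step <- function(x, w) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  sc <- lift_scheme(w)
  u <- x[seq(1, n, by = 2)]   # even samples x[2k]
  v <- x[seq(2, n, by = 2)]   # odd samples  x[2k+1]
  # apply A_i = [[q_i, 1], [1, 0]] for i = 1..n: (u, v) <- (q_i u + v, u)
  for (q in sc$quotients) {
    t <- lp_apply(q, u) + v
    v <- u
    u <- t
  }
  # final triangular factor [[K, 0], [C, D]]
  ca <- sc$K$coef * circ_shift(u, sc$K$low)
  cd <- lp_apply(sc$C, u) + sc$D$coef * circ_shift(v, sc$D$low)
  list(ca = ca, cd = cd)
}

# inverse of lift_step
inv_lift_step <- function(ca, cd, w) {
  stopifnot(length(ca) == length(cd))
  sc <- lift_scheme(w)
  u <- circ_shift(ca / sc$K$coef, -sc$K$low)
  v <- circ_shift((cd - lp_apply(sc$C, u)) / sc$D$coef, -sc$D$low)
  # undo A_i in reverse: (u, v) -> (v, u - q_i v)
  for (q in rev(sc$quotients)) {
    t <- v
    v <- u - lp_apply(q, v)
    u <- t
  }
  n <- 2L * length(ca)
  x <- numeric(n)
  x[seq(1, n, by = 2)] <- u
  x[seq(2, n, by = 2)] <- v
  x
}
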