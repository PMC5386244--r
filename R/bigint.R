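# Exact integer and rational arithmetic.
#
# The moment matrix is a Hankel matrix and, on [0, 1], the Hilbert matrix;
# both are notoriously ill-conditioned, so floating-point solves degrade
# rapidly with the polynomial degree. This file provides the small exact
# arithmetic core behind the explicit integer Hilbert inverse and the
# rational fallback solver: signed big integers as base-1e6 limb vectors
# (little-endian) and reduced rationals on top of them. Only the operations
# the solvers need are implemented.

BI_BASE <- 1e6

bi_norm <- function(d, s = 1L) {
  # propagate carries/borrows so all limbs lie in [0, BI_BASE)
  repeat {
    carry <- floor(d / BI_BASE)
    if (all(carry == 0)) break
    d <- d - carry * BI_BASE
    d <- c(d, 0) + c(0, carry)
  }
  while (length(d) && d[length(d)] == 0) d <- d[-length(d)]
  if (!length(d)) s <- 0L
  structure(list(s = s, d = d), class = "bigint")
}

bi_zero <- function() bi_norm(numeric(0))
bi_one <- function() bi_norm(1)
bi_is_zero <- function(a) a$s == 0L

# exact conversion from an integer-valued double (any magnitude)
bi <- function(x) {
  if (length(x) != 1L || !is.finite(x) || x != round(x))
    stop("bigint source must be a single integer-valued number", call. = FALSE)
  s <- if (x < 0) -1L else if (x > 0) 1L else 0L
  x <- abs(x)
  p2 <- 0L
  while (x >= 2^53) { x <- x / 2; p2 <- p2 + 1L }  # exact: trailing bits are zero
  d <- numeric(0)
  while (x > 0) { d <- c(d, x %% BI_BASE); x <- floor(x / BI_BASE) }
  out <- bi_norm(d, s)
  if (p2 > 0L) out <- bi_mul(out, bi_pow2(p2))
  out
}

bi_pow2 <- function(k) {
  out <- bi_one()
  while (k >= 20L) { out <- bi_mul_small(out, 2^20); k <- k - 20L }
  if (k > 0L) out <- bi_mul_small(out, 2^k)
  out
}

bi_neg <- function(a) { a$s <- -a$s; a }
bi_abs <- function(a) { a$s <- abs(a$s); a }

bi_cmp_abs <- function(a, b) {
  la <- length(a$d); lb <- length(b$d)
  if (la != lb) return(sign(la - lb))
  for (i in rev(seq_len(la))) {
    if (a$d[i] != b$d[i]) return(sign(a$d[i] - b$d[i]))
  }
  0L
}

bi_eq <- function(a, b) a$s == b$s && bi_cmp_abs(a, b) == 0L

bi_add_abs <- function(a, b, s = 1L) {
  n <- max(length(a$d), length(b$d))
  d <- c(a$d, numeric(n - length(a$d))) + c(b$d, numeric(n - length(b$d)))
  bi_norm(d, s)
}

bi_sub_abs <- function(a, b, s = 1L) {
  # |a| >= |b| assumed
  n <- length(a$d)
  d <- a$d - c(b$d, numeric(n - length(b$d)))
  # borrow propagation
  for (i in seq_len(n)) {
    if (d[i] < 0) { d[i] <- d[i] + BI_BASE; d[i + 1L] <- d[i + 1L] - 1 }
  }
  bi_norm(d, s)
}

bi_add <- function(a, b) {
  if (bi_is_zero(a)) return(b)
  if (bi_is_zero(b)) return(a)
  if (a$s == b$s) return(bi_add_abs(a, b, a$s))
  cmp <- bi_cmp_abs(a, b)
  if (cmp == 0L) return(bi_zero())
  if (cmp > 0L) bi_sub_abs(a, b, a$s) else bi_sub_abs(b, a, b$s)
}

bi_sub <- function(a, b) bi_add(a, bi_neg(b))

bi_mul_small <- function(a, k) {
  # k a nonnegative integer below ~2^40 / BI_BASE
  if (bi_is_zero(a) || k == 0) return(bi_zero())
  bi_norm(a$d * k, a$s)
}

bi_mul <- function(a, b) {
  if (bi_is_zero(a) || bi_is_zero(b)) return(bi_zero())
  la <- length(a$d); lb <- length(b$d)
  d <- numeric(la + lb)
  for (i in seq_len(la)) {
    idx <- i:(i + lb - 1L)
    d[idx] <- d[idx] + a$d[i] * b$d
    if (i %% 8L == 0L) {  # keep partial sums well below 2^53
      carry <- floor(d / BI_BASE)
      d <- d - carry * BI_BASE
      d <- d + c(0, carry[-length(carry)])
      if (carry[length(carry)] != 0) d <- c(d, carry[length(carry)])
    }
  }
  bi_norm(d, a$s * b$s)
}

bi_to_double <- function(a) {
  if (bi_is_zero(a)) return(0)
  n <- length(a$d)
  top <- min(n, 9L)
  m <- 0
  for (i in n:(n - top + 1L)) m <- m * BI_BASE + a$d[i]
  a$s * m * BI_BASE^(n - top)
}

bi_div_small <- function(a, k) {
  # divide |a| by small positive integer k; returns list(q = bigint, r = double)
  n <- length(a$d)
  q <- numeric(n); r <- 0
  for (i in rev(seq_len(n))) {
    cur <- r * BI_BASE + a$d[i]
    q[i] <- cur %/% k
    r <- cur %% k
  }
  list(q = bi_norm(q, a$s), r = r)
}

bi_divmod <- function(a, b) {
  # truncated division of magnitudes with sign of a*b on q; |r| < |b|, sign(a)
  if (bi_is_zero(b)) stop("bigint division by zero", call. = FALSE)
  if (bi_cmp_abs(a, b) < 0L) return(list(q = bi_zero(), r = a))
  if (length(b$d) == 1L) {
    dm <- bi_div_small(bi_abs(a), b$d[1L])
    q <- dm$q; q$s <- if (bi_is_zero(q)) 0L else a$s * b$s
    r <- if (dm$r == 0) bi_zero() else bi_norm(dm$r, a$s)
    return(list(q = q, r = r))
  }
  babs <- bi_abs(b)
  bd <- bi_to_double(babs)
  r <- bi_zero()
  n <- length(a$d)
  qd <- numeric(n)
  for (i in rev(seq_len(n))) {
    r <- bi_norm(c(a$d[i], r$d), if (length(r$d) || a$d[i] != 0) 1L else 0L)
    if (bi_cmp_abs(r, babs) >= 0L) {
      qh <- floor(bi_to_double(r) / bd)
      if (qh > BI_BASE - 1) qh <- BI_BASE - 1
      t <- bi_mul_small(babs, qh)
      while (bi_cmp_abs(t, r) > 0L) { qh <- qh - 1; t <- bi_sub_abs(t, babs) }
      repeat {
        t2 <- bi_add_abs(t, babs)
        if (bi_cmp_abs(t2, r) > 0L) break
        qh <- qh + 1; t <- t2
      }
      r <- bi_sub_abs(r, t)
      qd[i] <- qh
    }
  }
  q <- bi_norm(qd, a$s * b$s)
  r$s <- if (bi_is_zero(r)) 0L else a$s
  list(q = q, r = r)
}

bi_gcd <- function(a, b) {
  a <- bi_abs(a); b <- bi_abs(b)
  while (!bi_is_zero(b)) {
    r <- bi_divmod(a, b)$r
    a <- b; b <- bi_abs(r)
  }
  if (bi_is_zero(a)) bi_one() else a
}

bi_even <- function(a) bi_is_zero(a) || a$d[1L] %% 2 == 0

# ---- reduced rationals ------------------------------------------------------

qq <- function(n, d = bi_one(), reduce = TRUE) {
  if (bi_is_zero(d)) stop("rational with zero denominator", call. = FALSE)
  if (d$s < 0L) { d <- bi_neg(d); n <- bi_neg(n) }
  if (bi_is_zero(n)) return(structure(list(n = bi_zero(), d = bi_one()), class = "bigq"))
  if (reduce) {
    g <- bi_gcd(n, d)
    if (!(length(g$d) == 1L && g$d[1L] == 1)) {
      n <- bi_divmod(n, g)$q
      d <- bi_divmod(d, g)$q
      if (d$s < 0L) { d <- bi_neg(d); n <- bi_neg(n) }
    }
  }
  structure(list(n = n, d = d), class = "bigq")
}

q_zero <- function() qq(bi_zero())
q_is_zero <- function(x) bi_is_zero(x$n)

q_from_double <- function(x) {
  if (!is.finite(x)) stop("cannot represent non-finite value as rational", call. = FALSE)
  if (x == 0) return(q_zero())
  fr <- x; k <- 0L
  while (fr != round(fr)) { fr <- fr * 2; k <- k + 1L }
  n <- bi(fr)
  while (k > 0L && bi_even(n)) { n <- bi_div_small(n, 2)$q; k <- k - 1L }
  qq(n, bi_pow2(k), reduce = FALSE)
}

q_add <- function(a, b) qq(bi_add(bi_mul(a$n, b$d), bi_mul(b$n, a$d)), bi_mul(a$d, b$d))
q_sub <- function(a, b) qq(bi_sub(bi_mul(a$n, b$d), bi_mul(b$n, a$d)), bi_mul(a$d, b$d))
q_mul <- function(a, b) qq(bi_mul(a$n, b$n), bi_mul(a$d, b$d))
q_div <- function(a, b) {
  if (q_is_zero(b)) stop("rational division by zero", call. = FALSE)
  qq(bi_mul(a$n, b$d), bi_mul(a$d, b$n))
}
q_neg <- function(a) { a$n <- bi_neg(a$n); a }

q_to_double <- function(a) {
  if (q_is_zero(a)) return(0)
  ln <- length(a$n$d); ld <- length(a$d$d)
  drop <- max(0L, min(ln, ld) - 9L)  # cancel common scale to avoid overflow
  nn <- a$n; dd <- a$d
  if (drop > 0L) {
    nn$d <- nn$d[-seq_len(drop)]
    dd$d <- dd$d[-seq_len(drop)]
  }
  bi_to_double(nn) / bi_to_double(dd)
}

# exact Gaussian elimination with partial (nonzero, max-magnitude) pivoting
q_solve <- function(A, b) {
  n <- length(b)
  for (col in seq_len(n)) {
    mags <- vapply(col:n, function(r) abs(q_to_double(A[[r]][[col]])), numeric(1))
    if (all(mags == 0)) stop("exact solve: matrix is singular", call. = FALSE)
    piv <- (col:n)[which.max(mags)]
    if (piv != col) {
      tmp <- A[[col]]; A[[col]] <- A[[piv]]; A[[piv]] <- tmp
      tmp <- b[[col]]; b[[col]] <- b[[piv]]; b[[piv]] <- tmp
    }
    for (r in seq_len(n)[-seq_len(col)]) {
      if (q_is_zero(A[[r]][[col]])) next
      fac <- q_div(A[[r]][[col]], A[[col]][[col]])
      for (c2 in col:n)
        A[[r]][[c2]] <- q_sub(A[[r]][[c2]], q_mul(fac, A[[col]][[c2]]))
      b[[r]] <- q_sub(b[[r]], q_mul(fac, b[[col]]))
    }
  }
  x <- vector("list", n)
  for (r in rev(seq_len(n))) {
    acc <- b[[r]]
    for (c2 in seq_len(n)[-seq_len(r)])
      acc <- q_sub(acc, q_mul(A[[r]][[c2]], x[[c2]]))
    x[[r]] <- q_div(acc, A[[r]][[r]])
  }
  x
}
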