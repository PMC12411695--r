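# internal numerical helpers

# Truncated standard-deviation-1 normal draws via inverse CDF.
# y = 1 truncates to (0, Inf), y = 0 to (-Inf, 0].  Vectorized; clamps the
# uniform deviates away from 0/1 so extreme means cannot produce infinities.
.rtruncProbit <- function(mean, y) {
  p0 <- pnorm(-mean)                       # P(latent <= 0)
  lo <- p0 * y                             # y = 1: (p0, 1); y = 0: (0, p0)
  u <- lo + runif(length(mean)) * (p0 + (1 - p0) * y - lo)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  z <- mean + qnorm(u)
  # guard pathological cancellation far in the tails
  bad <- which(!is.finite(z))
  if (length(bad)) z[bad] <- pmax(mean[bad], 0) * y[bad] + pmin(mean[bad], 0) * (1 - y[bad])
  z
}

# Draw x_i ~ N(P_i^{-1} b_i, P_i^{-1}) for a batch of m small precision
# matrices.  Parray is m x d^2 (row i = vec of P_i), Bmat is m x d, Eps is a
# m x d matrix of standard normals supplied by the caller (so RNG consumption
# is independent of the code path taken).
.drawMVNBatch <- function(Parray, Bmat, Eps) {
  d <- ncol(Bmat)
  m <- nrow(Bmat)
  out <- matrix(0, m, d)
  if (d == 1L) {
    P <- Parray[, 1L]
    return(matrix(Bmat[, 1L] / P + Eps[, 1L] / sqrt(P), m, 1L))
  }
  if (d == 2L) {
    p11 <- Parray[, 1L]; p12 <- Parray[, 2L]; p22 <- Parray[, 4L]
    det <- p11 * p22 - p12 * p12
    m1 <- (p22 * Bmat[, 1L] - p12 * Bmat[, 2L]) / det
    m2 <- (p11 * Bmat[, 2L] - p12 * Bmat[, 1L]) / det
    # upper Cholesky of P: [[s1, p12/s1], [0, s2]]
    s1 <- sqrt(p11)
    s2 <- sqrt(p22 - p12 * p12 / p11)
    x2 <- Eps[, 2L] / s2
    x1 <- (Eps[, 1L] - (p12 / s1) * x2) / s1
    out[, 1L] <- m1 + x1
    out[, 2L] <- m2 + x2
    return(out)
  }
  for (i in seq_len(m)) {
    P <- matrix(Parray[i, ], d, d)
    U <- chol(P)
    mu <- backsolve(U, forwardsolve(t(U), Bmat[i, ]))
    out[i, ] <- mu + backsolve(U, Eps[i, ])
  }
  out
}

# per-column crossprod with a mask: returns d^2 x p matrix whose column c is
# vec(t(M[obs_c, ]) %*% M[obs_c, ]) computed without subsetting copies
.maskedCrossprodArray <- function(M, mask) {
  d <- ncol(M)
  prods <- matrix(0, nrow(M), d * d)
  k <- 0L
  for (b in seq_len(d)) for (a in seq_len(d)) {
    k <- k + 1L
    prods[, k] <- M[, a] * M[, b]
  }
  crossprod(prods, mask)                   # d^2 x p
}

# full-precision numeric table IO: %.17g survives a write/read round trip
# bit-exactly for doubles
.writeNumericCSV <- function(mat, file) {
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  df <- as.data.frame(mat, check.names = FALSE)
  fmt <- vapply(df, is.numeric, logical(1))
  df[fmt] <- lapply(df[fmt], function(x) sprintf("%.17g", x))
  utils::write.csv(cbind(row = rownames(mat), df), file, row.names = FALSE, quote = TRUE)
}

.readNumericCSV <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  rn <- df$row
  df$row <- NULL
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

.stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
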