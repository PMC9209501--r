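# Independent brute-force reference for the field calculus: explicit loops,
# explicit stencils, and an explicit characteristic-polynomial eigensolve.
# Deliberately shares no code with the package implementation.

oracleGradient <- function(u, mask, h) {
  d <- dim(mask)
  g <- array(0, dim = c(d, 3L, 3L))
  degenerate <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    for (ax in 1:3) {
      if (d[ax] == 1L) next
      ip <- c(i, j, k); ip[ax] <- ip[ax] + 1L
      im <- c(i, j, k); im[ax] <- im[ax] - 1L
      hasP <- ip[ax] <= d[ax] && mask[ip[1], ip[2], ip[3]]
      hasM <- im[ax] >= 1L && mask[im[1], im[2], im[3]]
      if (!hasP && !hasM) {
        degenerate[i, j, k] <- TRUE
        next
      }
      for (comp in 1:3) {
        uc <- u[i, j, k, comp]
        g[i, j, k, comp, ax] <-
          if (hasP && hasM)
            (u[ip[1], ip[2], ip[3], comp] - u[im[1], im[2], im[3], comp]) /
              (2 * h)
          else if (hasP) (u[ip[1], ip[2], ip[3], comp] - uc) / h
          else (uc - u[im[1], im[2], im[3], comp]) / h
      }
    }
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (degenerate[i, j, k]) g[i, j, k, , ] <- 0
  list(g = g, degenerate = degenerate)
}

# middle eigenvalue of a symmetric 3x3 matrix through its characteristic
# polynomial  -l^3 + tr l^2 - m2 l + det = 0, solved with polyroot()
oracleMiddleEig <- function(S) {
  tr <- S[1, 1] + S[2, 2] + S[3, 3]
  m2 <- (S[1, 1] * S[2, 2] - S[1, 2]^2) +
    (S[1, 1] * S[3, 3] - S[1, 3]^2) +
    (S[2, 2] * S[3, 3] - S[2, 3]^2)
  dt <- det(S)
  if (max(abs(S)) == 0) return(0)
  roots <- Re(polyroot(c(dt, -m2, tr, -1)))
  sort(roots, decreasing = TRUE)[2L]
}

oracleDensities <- function(u, mask, h) {
  d <- dim(mask)
  og <- oracleGradient(u, mask, h)
  out <- list(helicity = array(0, d), abs_helicity = array(0, d),
              enstrophy = array(0, d), q = array(0, d),
              lambda2 = array(0, d), vort_mag = array(0, d))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    G <- matrix(og$g[i, j, k, , ], 3, 3)
    om <- c(G[3, 2] - G[2, 3], G[1, 3] - G[3, 1], G[2, 1] - G[1, 2])
    uu <- u[i, j, k, ]
    D <- (G + t(G)) / 2
    A <- (G - t(G)) / 2
    out$helicity[i, j, k] <- sum(uu * om)
    out$abs_helicity[i, j, k] <- abs(sum(uu * om))
    out$enstrophy[i, j, k] <- sum(om^2) / 2
    out$vort_mag[i, j, k] <- sqrt(sum(om^2))
    out$q[i, j, k] <- (sum(A^2) - sum(D^2)) / 2
    out$lambda2[i, j, k] <- oracleMiddleEig(D %*% D + A %*% A)
  }
  out
}
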