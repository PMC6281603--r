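# Generic convex-programming oracle for the biclustering objective:
# ADMM with exact Sylvester U-updates and group soft-thresholding on the
# column- and row-difference splitting variables. Coded independently of
# the package solver; run long enough to act as a high-accuracy optimum.
admm_cobra <- function(X, weights, gamma, rho = 2, iters = 3000) {
  m <- nrow(X)
  n <- ncol(X)
  ce <- weights$col_edges
  re <- weights$row_edges
  lap <- function(edges, d) {
    L <- matrix(0, d, d)
    for (r in seq_len(nrow(edges))) {
      i <- edges$i[r]
      j <- edges$j[r]
      L[i, i] <- L[i, i] + 1
      L[j, j] <- L[j, j] + 1
      L[i, j] <- L[i, j] - 1
      L[j, i] <- L[j, i] - 1
    }
    L
  }
  er <- eigen(rho * lap(re, m), symmetric = TRUE)
  ec <- eigen(rho * lap(ce, n), symmetric = TRUE)
  denom <- 1 + outer(er$values, ec$values, "+")
  V <- matrix(0, m, nrow(ce))
  A <- matrix(0, m, nrow(ce))
  W <- matrix(0, nrow(re), n)
  B <- matrix(0, nrow(re), n)
  U <- X
  soft <- function(v, t) {
    nv <- sqrt(sum(v^2))
    if (nv <= t) v * 0 else v * (1 - t / nv)
  }
  for (it in seq_len(iters)) {
    Mc <- matrix(0, m, n)
    for (r in seq_len(nrow(ce))) {
      vv <- V[, r] - A[, r]
      Mc[, ce$i[r]] <- Mc[, ce$i[r]] + vv
      Mc[, ce$j[r]] <- Mc[, ce$j[r]] - vv
    }
    Mr <- matrix(0, m, n)
    for (r in seq_len(nrow(re))) {
      ww <- W[r, ] - B[r, ]
      Mr[re$i[r], ] <- Mr[re$i[r], ] + ww
      Mr[re$j[r], ] <- Mr[re$j[r], ] - ww
    }
    RHS <- X + rho * (Mc + Mr)
    U <- er$vectors %*%
      (crossprod(er$vectors, RHS %*% ec$vectors) / denom) %*%
      t(ec$vectors)
    for (r in seq_len(nrow(ce))) {
      d <- U[, ce$i[r]] - U[, ce$j[r]]
      V[, r] <- soft(d + A[, r], gamma * ce$w[r] / rho)
      A[, r] <- A[, r] + d - V[, r]
    }
    for (r in seq_len(nrow(re))) {
      d <- U[re$i[r], ] - U[re$j[r], ]
      W[r, ] <- soft(d + B[r, ], gamma * re$w[r] / rho)
      B[r, ] <- B[r, ] + d - W[r, ]
    }
  }
  U
}

cobra_objective_of <- function(X, U, weights, gamma) {
  multimorbid:::cobra_objective(X, U, weights, gamma)
}
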