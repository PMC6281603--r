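# Convex biclustering of phenotype sharing matrices.
#
# The fitted object minimises
#   F_gamma(U) = 1/2 ||X - U||_F^2
#              + gamma * [ sum_(i,j) w_ij ||U_.i - U_.j||_2
#                        + sum_(k,l) wt_kl ||U_k. - U_l.||_2 ]
# over all real matrices U, where the column weights w and row weights wt
# come from a Gaussian kernel truncated to k nearest neighbours. The solver
# is majorisation-minimisation on an epsilon-smoothed objective: each norm
# ||v|| is replaced by sqrt(||v||^2 + delta^2) and majorised by a quadratic,
# giving per-step weighted-Laplacian quadratics solved exactly as a Sylvester
# equation via eigendecomposition. The objective sequence is monotone
# non-increasing (up to the delta smoothing slack).

#' Gaussian-kernel k-nearest-neighbour fusion weights
#'
#' Column weights are \eqn{w_{ij} = \exp(-(\phi/m) \|X_{.i} - X_{.j}\|^2)}
#' (m the number of rows), kept only if j is among i's k nearest columns
#' (symmetrised by union); row weights are built analogously from the rows
#' of `X` with exponent scaled by the number of columns. Following the
#' convention of reference convex-biclustering implementations, the kept
#' column weights are then normalised to sum to \eqn{1/\sqrt{n}} and the
#' row weights to \eqn{1/\sqrt{m}}, which balances the two fusion penalties
#' and puts the informative range of the penalty gamma on a common scale
#' across problem sizes (`normalize = FALSE` keeps the raw kernel values).
#' Each graph must be connected for the fully fused limit to be unique; if
#' truncation disconnects a graph, k is escalated with a warning until it
#' connects.
#'
#' @param X Numeric matrix with finite entries.
#' @param k Number of nearest neighbours kept per node (default 5).
#' @param phi Gaussian kernel bandwidth (default 0.5).
#' @param normalize Apply the reference weight normalisation
#'   (default `TRUE`).
#' @return A list of class `cobra_weights`: tibbles `col_edges` and
#'   `row_edges` (columns `i`, `j`, `w`; `i < j`), the dimensions of `X`,
#'   and the `k` finally used per graph.
#' @export
build_weights <- function(X, k = 5, phi = 0.5, normalize = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  if (min(dim(X)) < 2) stop("X needs at least two rows and columns",
                            call. = FALSE)
  col_edges <- knn_kernel_edges(t(X), k, phi / nrow(X), "column")
  row_edges <- knn_kernel_edges(X, k, phi / ncol(X), "row")
  if (normalize) {
    col_edges$edges$w <- col_edges$edges$w / sum(col_edges$edges$w) /
      sqrt(ncol(X))
    row_edges$edges$w <- row_edges$edges$w / sum(row_edges$edges$w) /
      sqrt(nrow(X))
  }
  structure(
    list(col_edges = col_edges$edges, row_edges = row_edges$edges,
         nrow = nrow(X), ncol = ncol(X), k = k, phi = phi,
         normalize = normalize,
         k_col = col_edges$k, k_row = row_edges$k),
    class = "cobra_weights"
  )
}

# Build union-kNN Gaussian edges between the rows of `pts` with kernel
# exp(-phi * d^2); escalate k until the graph is connected.
knn_kernel_edges <- function(pts, k, phi, what) {
  m <- nrow(pts)
  if (k >= m) k <- m - 1
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  d2 <- as.matrix(stats::dist(pts))^2
  k0 <- k
  repeat {
    keep <- matrix(FALSE, m, m)
    for (i in seq_len(m)) {
      ord <- order(d2[i, ])
      ord <- ord[ord != i]
      keep[i, ord[seq_len(k)]] <- TRUE
    }
    keep <- keep | t(keep)  # union symmetrisation
    if (connected_graph(keep) || k >= m - 1) break
    k <- k + 1
  }
  if (!connected_graph(keep)) {
    stop("could not build a connected ", what, " graph", call. = FALSE)
  }
  if (k > k0) {
    warning("k escalated from ", k0, " to ", k, " to connect the ", what,
            " graph", call. = FALSE)
  }
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- tibble::tibble(
    i = as.integer(idx[, 1]),
    j = as.integer(idx[, 2]),
    w = exp(-phi * d2[idx])
  )
  list(edges = edges, k = k)
}

# Breadth-first connectivity of a logical adjacency matrix.
connected_graph <- function(adj) {
  m <- nrow(adj)
  seen <- logical(m)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Regularisation grid for the biclustering solution path
#'
#' `n` values of the fusion penalty gamma spaced uniformly on the log10
#' scale between `low` and `high` (endpoints exact); `log = FALSE` gives
#' linear spacing.
#'
#' @param n Number of grid points (default 100).
#' @param low,high Grid endpoints (defaults 1 and 1000).
#' @param log Log10 spacing (default `TRUE`).
#' @return Numeric vector of length `n`.
#' @export
gamma_grid <- function(n = 100, low = 1, high = 1000, log = TRUE) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (!(is.finite(low) && is.finite(high) && low > 0 && low < high)) {
    stop("need 0 < low < high", call. = FALSE)
  }
  if (log) 10^seq(log10(low), log10(high), length.out = n)
  else seq(low, high, length.out = n)
}

# Weighted graph Laplacian from an edge tibble.
edge_laplacian <- function(edges, m, weights) {
  L <- matrix(0, m, m)
  if (nrow(edges) > 0) {
    ij <- cbind(edges$i, edges$j)
    L[ij] <- L[ij] - weights
    L[ij[, 2:1, drop = FALSE]] <- L[ij[, 2:1, drop = FALSE]] - weights
    diag(L) <- -rowSums(L)
  }
  L
}

# Evaluate the exact (unsmoothed) biclustering objective.
cobra_objective <- function(X, U, weights, gamma) {
  col_pen <- if (nrow(weights$col_edges) > 0) {
    d <- U[, weights$col_edges$i, drop = FALSE] -
      U[, weights$col_edges$j, drop = FALSE]
    sum(weights$col_edges$w * sqrt(colSums(d^2)))
  } else 0
  row_pen <- if (nrow(weights$row_edges) > 0) {
    d <- U[weights$row_edges$i, , drop = FALSE] -
      U[weights$row_edges$j, , drop = FALSE]
    sum(weights$row_edges$w * sqrt(rowSums(d^2)))
  } else 0
  0.5 * sum((X - U)^2) + gamma * (col_pen + row_pen)
}

#' Solve the convex biclustering problem at one penalty value
#'
#' Minimises the squared-error-plus-fusion objective (see [build_weights()])
#' by majorisation-minimisation on an epsilon-smoothed objective, with each
#' quadratic step solved exactly as a Sylvester equation. At `gamma = 0` the
#' input is returned unchanged; as gamma grows every entry fuses towards the
#' grand mean of `X`.
#'
#' @param X Numeric data matrix.
#' @param weights `cobra_weights` for `X` (built with defaults when `NULL`).
#' @param gamma Fusion penalty (scalar, >= 0).
#' @param tol Relative objective-change convergence tolerance
#'   (default 1e-6).
#' @param max_iter Iteration cap; reaching it returns the current iterate
#'   with a warning (default 500).
#' @return The smoothed matrix `U` with attributes `objective` (the monotone
#'   per-iteration objective trace), `iterations` and `converged`.
#' @export
cobra_solve <- function(X, weights = NULL, gamma, tol = 1e-6,
                        max_iter = 500) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- build_weights(X)
  stopifnot(inherits(weights, "cobra_weights"),
            weights$nrow == nrow(X), weights$ncol == ncol(X),
            length(gamma) == 1, gamma >= 0)
  if (gamma == 0 || cobra_objective(X, X, weights, gamma) == 0) {
    # gamma = 0, or X already has zero fusion penalty (e.g. constant input):
    # X minimises both terms exactly
    return(structure(X, objective = cobra_objective(X, X, weights, gamma),
                     iterations = 0L, converged = TRUE))
  }
  delta <- 1e-8 * (stats::sd(X) + 1e-12)
  c_cap <- 1e8  # conditioning guard for the weighted-Laplacian eigensolves
  U <- X
  obj <- cobra_objective(X, U, weights, gamma)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # IRLS weights: gamma * w_e / sqrt(||diff||^2 + delta^2)
    cw <- {
      d <- U[, weights$col_edges$i, drop = FALSE] -
        U[, weights$col_edges$j, drop = FALSE]
      pmin(gamma * weights$col_edges$w / sqrt(colSums(d^2) + delta^2), c_cap)
    }
    rw <- {
      d <- U[weights$row_edges$i, , drop = FALSE] -
        U[weights$row_edges$j, , drop = FALSE]
      pmin(gamma * weights$row_edges$w / sqrt(rowSums(d^2) + delta^2), c_cap)
    }
    Lc <- edge_laplacian(weights$col_edges, ncol(X), cw)
    Lr <- edge_laplacian(weights$row_edges, nrow(X), rw)
    # Quadratic majoriser minimised by U solving  U + Lr U + U Lc = X
    er <- eigen(Lr, symmetric = TRUE)
    ec <- eigen(Lc, symmetric = TRUE)
    Xt <- crossprod(er$vectors, X %*% ec$vectors)
    denom <- 1 + outer(er$values, ec$values, "+")
    U <- er$vectors %*% (Xt / denom) %*% t(ec$vectors)
    new_obj <- cobra_objective(X, U, weights, gamma)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) <= tol * (abs(obj) + 1e-12)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged) {
    warning("cobra_solve reached max_iter = ", max_iter,
            " before meeting tol; returning current iterate", call. = FALSE)
  }
  structure(U, objective = trace, iterations = iter, converged = converged)
}

#' Solution path with hold-out validation
#'
#' A random subset of matrix entries is held out and replaced by the mean of
#' the observed entries; the biclustering problem is solved at every grid
#' value of gamma on the completed matrix, and the validation error of each
#' model is the mean squared difference between its smoothed values and the
#' true held-out entries. The final smoothed matrix is re-solved on the full
#' data at the gamma minimising validation error.
#'
#' @param X Numeric data matrix (e.g. a [share_matrix()]).
#' @param grid Gamma grid from [gamma_grid()].
#' @param weights Optional `cobra_weights`; built from the completed matrix
#'   when `NULL`.
#' @param holdout_fraction Fraction of entries held out, in (0, 0.5]
#'   (default 0.1).
#' @param seed Optional integer seed for the hold-out draw; global RNG state
#'   is untouched.
#' @param tol,max_iter Passed to [cobra_solve()].
#' @param tol_cluster Fusion tolerance for cluster extraction, as a fraction
#'   of `sd(U*)` (default 0.05).
#' @param keep_path Keep the smoothed matrix at every grid point
#'   (default `TRUE`).
#' @return An object of class `cobra_result`: `gamma` (grid), `error`
#'   (validation errors), `gamma_star`, `U_star`, `row_clusters`,
#'   `col_clusters`, the holdout index set, and optionally `U_path`.
#' @export
validate_path <- function(X, grid = gamma_grid(), weights = NULL,
                          holdout_fraction = 0.1, seed = NULL,
                          tol = 1e-6, max_iter = 500, tol_cluster = 0.05,
                          keep_path = TRUE) {
  X <- as.matrix(X)
  if (!(holdout_fraction > 0 && holdout_fraction <= 0.5)) {
    stop("holdout_fraction must lie in (0, 0.5]", call. = FALSE)
  }
  n_hold <- max(1L, floor(holdout_fraction * length(X)))
  held <- with_local_seed(seed, sample.int(length(X), n_hold))
  X_train <- X
  X_train[held] <- mean(X[-held])
  if (is.null(weights)) weights <- build_weights(X_train)
  fits <- purrr::map(grid, function(g) {
    cobra_solve(X_train, weights, g, tol = tol, max_iter = max_iter)
  })
  errs <- purrr::map_dbl(fits, function(U) mean((U[held] - X[held])^2))
  star <- which.min(errs)
  full_weights <- build_weights(X, k = weights$k, phi = weights$phi,
                                normalize = isTRUE(weights$normalize))
  U_star <- cobra_solve(X, full_weights, grid[star], tol = tol,
                        max_iter = max_iter)
  clusters <- extract_clusters(U_star, tol_cluster = tol_cluster)
  structure(
    list(
      X = X,
      gamma = grid,
      error = errs,
      gamma_star = grid[star],
      gamma_star_index = star,
      U_star = U_star,
      row_clusters = clusters$row_clusters,
      col_clusters = clusters$col_clusters,
      holdout = held,
      holdout_fraction = holdout_fraction,
      tol_cluster = tol_cluster,
      U_path = if (keep_path) fits else NULL,
      weights = full_weights
    ),
    class = "cobra_result"
  )
}

#' Extract row and column clusters from a smoothed matrix
#'
#' Two columns share a cluster when they are connected through column pairs
#' whose smoothed profiles differ by at most `tol_cluster * sd(U)` in
#' Euclidean norm (connected components); rows analogously. Labels are
#' numbered by first appearance.
#'
#' @param U Smoothed matrix (e.g. `U_star` from [validate_path()]).
#' @param tol_cluster Fusion tolerance as a fraction of `scale`
#'   (default 0.05).
#' @param scale Reference scale for the fusion tolerance; defaults to
#'   `sd(U)`. When comparing cluster counts across a solution path, pass the
#'   scale of the unsmoothed data so the threshold is the same at every
#'   gamma.
#' @return A list with integer vectors `row_clusters` and `col_clusters`.
#' @export
extract_clusters <- function(U, tol_cluster = 0.05, scale = NULL) {
  U <- as.matrix(U)
  if (is.null(scale)) scale <- stats::sd(U)
  thr <- tol_cluster * (if (is.na(scale) || scale == 0) 1 else scale)
  part <- function(pts) {
    d <- as.matrix(stats::dist(pts))
    adj <- d <= thr
    labels <- integer(nrow(d))
    nxt <- 0L
    for (s in seq_len(nrow(d))) {
      if (labels[s] > 0) next
      nxt <- nxt + 1L
      frontier <- s
      labels[s] <- nxt
      while (length(frontier) > 0) {
        nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & labels == 0)
        labels[nb] <- nxt
        frontier <- nb
      }
    }
    labels
  }
  list(row_clusters = part(U), col_clusters = part(t(U)))
}

#' Bicluster a phenotype sharing matrix
#'
#' Convenience wrapper: builds Gaussian-kernel kNN weights, runs the gamma
#' solution path with hold-out validation and extracts biclusters at the
#' minimum-validation-error model.
#'
#' @param x A `share_matrix` (or any numeric matrix).
#' @param k,phi Weight parameters, see [build_weights()].
#' @param ... Passed to [validate_path()].
#' @return A `cobra_result`; column clusters carry phenotype names when the
#'   input has dimnames.
#' @export
bicluster_phenotypes <- function(x, k = 5, phi = 0.5, ...) {
  X <- as.matrix(unclass(x))
  res <- validate_path(X, weights = build_weights(X, k = k, phi = phi), ...)
  if (!is.null(colnames(X))) {
    names(res$col_clusters) <- colnames(X)
    names(res$row_clusters) <- rownames(X)
  }
  res
}

#' @export
print.cobra_result <- function(x, ...) {
  cat("Convex biclustering path\n")
  cat(sprintf("  gamma grid: %d points in [%.4g, %.4g]\n",
              length(x$gamma), min(x$gamma), max(x$gamma)))
  cat(sprintf("  gamma* = %.4g (validation MSE %.4g)\n",
              x$gamma_star, min(x$error)))
  cat(sprintf("  clusters at gamma*: %d row, %d column\n",
              max(x$row_clusters), max(x$col_clusters)))
  invisible(x)
}

#' Validation-error curve of a biclustering path
#'
#' @param x A `cobra_result`.
#' @param ... Unused.
#' @return A tibble with `gamma`, `error` and, when the path was kept,
#'   `n_col_clusters` per grid point.
#' @export
tidy.cobra_result <- function(x, ...) {
  out <- tibble::tibble(gamma = x$gamma, error = x$error)
  if (!is.null(x$U_path)) {
    # fixed threshold (data scale) so counts are comparable along the path
    s <- stats::sd(x$X)
    out$n_col_clusters <- purrr::map_int(x$U_path, function(U) {
      max(extract_clusters(U, tol_cluster = x$tol_cluster,
                           scale = s)$col_clusters)
    })
  }
  out
}

#' One-row summary of a biclustering path
#'
#' @param x A `cobra_result`.
#' @param ... Unused.
#' @return A one-row tibble: `gamma_star`, minimum validation error, cluster
#'   counts and holdout size.
#' @export
glance.cobra_result <- function(x, ...) {
  tibble::tibble(
    gamma_star = x$gamma_star,
    min_error = min(x$error),
    n_row_clusters = max(x$row_clusters),
    n_col_clusters = max(x$col_clusters),
    n_holdout = length(x$holdout)
  )
}

#' Plot the validation-error curve
#'
#' @param object A `cobra_result`.
#' @param ... Unused.
#' @return A ggplot of validation error against gamma (log10 axis) with the
#'   selected gamma* marked.
#' @export
autoplot.cobra_result <- function(object, ...) {
  df <- tibble::tibble(gamma = object$gamma, error = object$error)
  ggplot2::ggplot(df, ggplot2::aes(.data$gamma, .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$gamma_star, linetype = 2,
                        colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(gamma), y = "validation MSE",
                  title = sprintf("gamma* = %.3g", object$gamma_star)) +
    ggplot2::theme_minimal()
}
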