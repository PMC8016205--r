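# Shared iterative machinery: DIIS extrapolation and a real non-symmetric
# Davidson eigensolver.

#' Create a DIIS accelerator state
#'
#' @param max_size maximum subspace (ring buffer) size
#' @return a `diis_state`
#' @export
diis_new <- function(max_size = 8) {
  structure(list(params = list(), errors = list(), max_size = max_size,
                 last_coef = numeric(0)),
            class = "diis_state")
}

#' One DIIS extrapolation step
#'
#' Stores the new (parameter, error) pair and returns the least-squares
#' extrapolated parameter; the extrapolation coefficients sum to one.  On a
#' singular system the oldest pair is dropped and the solve retried; if that
#' fails the plain parameter is returned.
#'
#' @param state a `diis_state`
#' @param new_param parameter vector
#' @param new_error error vector of the same length convention each call
#' @return list with `param` (extrapolated vector) and `state`
#' @export
diis_step <- function(state, new_param, new_error) {
  state$params[[length(state$params) + 1L]] <- new_param
  state$errors[[length(state$errors) + 1L]] <- new_error
  if (length(state$params) > state$max_size) {
    state$params <- state$params[-1]
    state$errors <- state$errors[-1]
  }
  repeat {
    m <- length(state$params)
    if (m == 1L) {
      state$last_coef <- 1
      return(list(param = new_param, state = state))
    }
    B <- matrix(0, m + 1, m + 1)
    for (i in seq_len(m)) for (j in seq_len(m))
      B[i, j] <- sum(state$errors[[i]] * state$errors[[j]])
    B[m + 1, seq_len(m)] <- -1
    B[seq_len(m), m + 1] <- -1
    rhs <- c(rep(0, m), -1)
    coef <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
    if (!is.null(coef) && all(is.finite(coef))) {
      state$last_coef <- coef
      p <- coef[1] * state$params[[1]]
      if (m > 1) for (i in 2:m) p <- p + coef[i] * state$params[[i]]
      return(list(param = p, state = state))
    }
    # singular normal equations: drop oldest and retry
    state$params <- state$params[-1]
    state$errors <- state$errors[-1]
  }
}

# modified Gram-Schmidt against the columns of V, twice for stability;
# returns NULL if the remainder is negligible
.mgs_append <- function(V, w, tol = 1e-10) {
  for (pass in 1:2) if (!is.null(V) && ncol(V) > 0)
    w <- w - V %*% crossprod(V, w)
  nw <- sqrt(sum(w^2))
  if (nw < tol) return(NULL)
  w / nw
}

#' Non-symmetric Davidson eigensolver (right eigenpairs, lowest real parts)
#'
#' @param apply_A function mapping a vector to `A %*% v` (matrix-free)
#' @param diag_A diagonal estimate of A, used for preconditioning
#' @param n_roots number of requested eigenpairs
#' @param n_dim problem dimension
#' @param tol per-root residual threshold
#' @param seed RNG seed for the (deterministic) start-vector perturbation
#' @param start_vectors optional matrix of start vectors
#' @param max_iter maximum outer iterations
#' @param max_subspace subspace cap before a restart (collapse to Ritz
#'   vectors)
#' @return list with `values` (length `n_roots`), `vectors`
#'   (`n_dim x n_roots`), `residuals`, `iterations`
#' @export
davidson_nonsym <- function(apply_A, diag_A, n_roots, n_dim, tol = 1e-6,
                            seed = 1L, start_vectors = NULL,
                            max_iter = 200L, max_subspace = NULL) {
  if (n_roots > n_dim) stop("n_roots exceeds the problem dimension")
  if (is.null(max_subspace)) max_subspace <- min(n_dim, max(20L * n_roots, 40L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  V <- NULL
  if (is.null(start_vectors)) {
    ord <- order(diag_A)
    nstart <- min(n_dim, max(2L * n_roots, n_roots + 2L))
    start_vectors <- matrix(0, n_dim, nstart)
    for (k in seq_len(nstart)) {
      start_vectors[ord[k], k] <- 1
      start_vectors[, k] <- start_vectors[, k] +
        1e-3 * rnorm(n_dim) / sqrt(n_dim)
    }
  }
  for (k in seq_len(ncol(start_vectors))) {
    w <- .mgs_append(V, start_vectors[, k])
    if (!is.null(w)) V <- cbind(V, w)
  }
  AV <- apply(V, 2, apply_A)
  if (n_dim == 1) AV <- matrix(AV, 1)
  for (iter in seq_len(max_iter)) {
    H <- crossprod(V, AV)
    eh <- eigen(H)
    # complex Ritz pairs may appear transiently in the subspace; work with
    # real parts and only reject complex values once converged
    ord <- order(Re(eh$values))
    sel <- ord[seq_len(n_roots)]
    theta <- Re(eh$values[sel])
    Y <- Re(eh$vectors[, sel, drop = FALSE])
    ynorm <- sqrt(colSums(Y^2))
    ynorm[ynorm < 1e-12] <- 1
    Y <- sweep(Y, 2, ynorm, "/")
    Xr <- V %*% Y
    AXr <- AV %*% Y
    res <- AXr - Xr %*% diag(theta, n_roots)
    rnorms <- sqrt(colSums(res^2))
    if (all(rnorms <= tol)) {
      if (any(abs(Im(eh$values[sel])) > 1e-8 * (1 + abs(theta))))
        stop("complex Ritz pair encountered for state ",
             which(abs(Im(eh$values[sel])) > 1e-8)[1],
             "; the requested roots are not real")
      nf <- sqrt(colSums(Xr^2))
      return(list(values = theta, vectors = sweep(Xr, 2, nf, "/"),
                  residuals = rnorms, iterations = iter))
    }
    if (ncol(V) + sum(rnorms > tol) > max_subspace) {
      # restart: collapse to current Ritz vectors (plus a spare)
      V <- NULL
      for (k in seq_len(n_roots)) {
        w <- .mgs_append(V, Xr[, k])
        if (!is.null(w)) V <- cbind(V, w)
      }
      AV <- apply(V, 2, apply_A)
      if (n_dim == 1) AV <- matrix(AV, 1)
      next
    }
    added <- FALSE
    for (k in which(rnorms > tol)) {
      denom <- diag_A - theta[k]
      denom[abs(denom) < 1e-6] <- sign(denom[abs(denom) < 1e-6] + 1e-12) * 1e-6
      w <- .mgs_append(V, res[, k] / denom)
      if (!is.null(w)) {
        V <- cbind(V, w)
        AV <- cbind(AV, apply_A(w))
        added <- TRUE
      }
    }
    if (!added) {
      # stagnation: inject a deterministic random direction
      w <- .mgs_append(V, rnorm(n_dim))
      if (is.null(w)) stop("Davidson subspace exhausted before convergence")
      V <- cbind(V, w)
      AV <- cbind(AV, apply_A(w))
    }
  }
  stop("Davidson failed to converge in ", max_iter, " iterations (residuals ",
       paste(format(rnorms, digits = 3), collapse = ", "), ")")
}
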