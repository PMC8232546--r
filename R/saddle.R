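#' Saddle-point solver policy
#'
#' Controls how the per-subdomain velocity-pressure blocks of the tangent
#' are (approximately) inverted inside the Schur-complement block
#' preconditioner, and the outer flexible-GMRES settings.
#'
#' @param type local-inverse policy: `"exact"` (sparse LU), `"simple"`
#'   (one SIMPLE sweep, the default), or `"gmres"` (inner GMRES with
#'   tolerance `inner_tol`).
#' @param inner_tol inner GMRES relative tolerance (used by
#'   `type = "gmres"`).
#' @param n_reuse number of consecutive preconditioner applications that
#'   reuse the same Schur complement before it is refreshed.
#' @param outer_tol outer FGMRES relative tolerance.
#' @param restart outer FGMRES restart length.
#' @param maxit maximum outer iterations.
#' @return object of class `rbe_saddle_policy`.
#' @export
saddle_policy <- function(type = c("simple", "exact", "gmres"),
                          inner_tol = 1e-2, n_reuse = 20L,
                          outer_tol = 1e-8, restart = 100L, maxit = 500L) {
  type <- match.arg(type)
  structure(list(type = type, inner_tol = inner_tol, n_reuse = n_reuse,
                 outer_tol = outer_tol, restart = restart, maxit = maxit,
                 state = new.env(parent = emptyenv())),
            class = "rbe_saddle_policy")
}

#' One-sweep SIMPLE approximate inverse of a local saddle block
#'
#' For a block `[[F, G], [Dv, 0]]` the sweep is: predictor
#' `u* = F^{-1} f`, pressure `p = Shat^{-1} (g - Dv u*)` with
#' `Shat = -Dv diag(F)^{-1} G`, corrector `u = u* - diag(F)^{-1} G p`.
#' Exact whenever `F` is diagonal.
#'
#' @param Ablk sparse local saddle matrix of size `(nf+np) x (nf+np)`.
#' @param nf number of velocity rows (the top-left `F` block).
#' @return function mapping a right-hand side to the approximate solution.
#' @export
simple_local_inverse <- function(Ablk, nf) {
  n <- nrow(Ablk)
  np <- n - nf
  Fm <- Ablk[seq_len(nf), seq_len(nf), drop = FALSE]
  dF <- Matrix::diag(Fm)
  if (any(dF == 0)) stop("zero diagonal entry in the momentum block")
  luF <- Matrix::lu(methods::as(Fm, "CsparseMatrix"))
  if (np == 0L) {
    return(function(rhs) as.numeric(Matrix::solve(luF, rhs)))
  }
  G <- Ablk[seq_len(nf), nf + seq_len(np), drop = FALSE]
  Dv <- Ablk[nf + seq_len(np), seq_len(nf), drop = FALSE]
  Shat <- -Dv %*% (G / dF)
  luS <- Matrix::lu(methods::as(Shat, "CsparseMatrix"))
  function(rhs) {
    f <- rhs[seq_len(nf)]; g <- rhs[nf + seq_len(np)]
    ustar <- as.numeric(Matrix::solve(luF, f))
    p <- as.numeric(Matrix::solve(luS, g - as.numeric(Dv %*% ustar)))
    u <- ustar - as.numeric(G %*% p) / dF
    c(u, p)
  }
}

# Build the per-subdomain local (approximate) inverse callbacks for the
# given global tangent J and policy.
local_inverses <- function(sys, J, policy) {
  lapply(seq_along(sys$sub), function(j) {
    idx <- sys_w_idx(sys, j)
    Ablk <- J[idx, idx, drop = FALSE]
    switch(policy$type,
      exact = {
        lu <- Matrix::lu(methods::as(Ablk, "CsparseMatrix"))
        function(v) as.numeric(Matrix::solve(lu, v))
      },
      simple = simple_local_inverse(Ablk, sys$sub[[j]]$nf),
      gmres = {
        dA <- Matrix::diag(Ablk)
        dA[dA == 0] <- 1
        function(v) gmres_solve(function(x) as.numeric(Ablk %*% x), v,
                                precond = function(x) x / dA,
                                tol = policy$inner_tol, restart = 200L,
                                maxit = 400L)$x
      })
  })
}

#' Assemble the multiplier Schur complement
#'
#' `S = -B Atilde^{-1} B^T`, built column by column by applying the
#' per-subdomain (approximate) local inverses to the columns of `B^T`;
#' the block-diagonality of `Atilde` makes every column a sum of local
#' solves.
#'
#' @param sys an `rbe_system`.
#' @param J global tangent matrix (saddle structure over `(W, Lambda)`).
#' @param locals list of local inverse callbacks (see [saddle_policy()]),
#'   or a policy from which they are built.
#' @return dense `nL x nL` matrix.
#' @export
assemble_schur <- function(sys, J, locals) {
  if (inherits(locals, "rbe_saddle_policy")) locals <- local_inverses(sys, J, locals)
  widx <- seq_len(sys$nW)
  lidx <- sys$nW + seq_len(sys$nL)
  Bg <- J[lidx, widx, drop = FALSE]
  Bt <- J[widx, lidx, drop = FALSE]
  S <- matrix(0, sys$nL, sys$nL)
  for (l in seq_len(sys$nL)) {
    col <- as.numeric(Bt[, l])
    z <- numeric(sys$nW)
    for (j in seq_along(sys$sub)) {
      idx <- sys_w_idx(sys, j)
      if (any(col[idx] != 0)) z[idx] <- locals[[j]](col[idx])
    }
    S[, l] <- -as.numeric(Bg %*% z)
  }
  S
}

#' Build the block Schur-complement preconditioner
#'
#' @param sys an `rbe_system`.
#' @param J global tangent.
#' @param policy an `rbe_saddle_policy`. The Schur complement stored in the
#'   policy state is reused for up to `n_reuse` applications.
#' @param refresh_schur force recomputation of the Schur complement.
#' @return object of class `rbe_precond` with an `apply(rhs)` function.
#' @export
build_block_preconditioner <- function(sys, J, policy, refresh_schur = FALSE) {
  locals <- local_inverses(sys, J, policy)
  st <- policy$state
  if (refresh_schur || is.null(st$S) || is.null(st$uses) ||
      st$uses >= policy$n_reuse || !identical(dim(st$S), c(sys$nL, sys$nL))) {
    st$S <- assemble_schur(sys, J, locals)
    st$qrS <- if (sys$nL) qr(st$S) else NULL
    st$uses <- 0L
  }
  widx <- seq_len(sys$nW)
  lidx <- sys$nW + seq_len(sys$nL)
  Bg <- J[lidx, widx, drop = FALSE]
  Bt <- J[widx, lidx, drop = FALSE]
  apply_local <- function(v) {
    z <- numeric(sys$nW)
    for (j in seq_along(sys$sub)) {
      idx <- sys_w_idx(sys, j)
      z[idx] <- locals[[j]](v[idx])
    }
    z
  }
  app <- function(rhs) {
    bw <- rhs[widx]
    bl <- if (sys$nL) rhs[lidx] else numeric(0)
    zw <- apply_local(bw)
    if (sys$nL) {
      st$uses <- st$uses + 1L
      xl <- solve(st$qrS, bl - as.numeric(Bg %*% zw))
      xw <- zw - apply_local(as.numeric(Bt %*% xl))
      c(xw, xl)
    } else {
      zw
    }
  }
  structure(list(sys = sys, policy = policy, apply = app,
                 schur = st$S), class = "rbe_precond")
}

#' Apply a block preconditioner
#'
#' Executes the two-solve procedure `Z_w = Atilde^{-1} B_w`,
#' `X_lambda = S^{-1}(B_lambda - B Z_w)`,
#' `X_w = Z_w - Atilde^{-1} B^T X_lambda`. With exact local solves this is
#' the exact solution of the saddle system.
#'
#' @param precond an `rbe_precond`.
#' @param rhs right-hand side over `(W, Lambda)`.
#' @return solution vector.
#' @export
apply_preconditioner <- function(precond, rhs) {
  precond$apply(rhs)
}

#' Flexible GMRES
#'
#' Right-preconditioned GMRES that stores the preconditioned directions,
#' hence supports preconditioners that change between iterations (inner
#' iterative solves).
#'
#' @param amul function `x -> A x`.
#' @param b right-hand side.
#' @param precond function `x -> M(x)` (default identity).
#' @param tol relative residual tolerance.
#' @param restart restart length.
#' @param maxit maximum total iterations.
#' @param x0 initial guess.
#' @return list with `x`, `iterations`, `resvec` (relative residual
#'   history), `converged`.
#' @export
gmres_solve <- function(amul, b, precond = NULL, tol = 1e-10,
                        restart = 100L, maxit = 500L, x0 = NULL) {
  n <- length(b)
  if (is.null(precond)) precond <- function(x) x
  x <- if (is.null(x0)) numeric(n) else x0
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = numeric(n), iterations = 0L,
                              resvec = numeric(0), converged = TRUE))
  resvec <- numeric(0)
  total <- 0L
  repeat {
    r <- b - amul(x)
    beta <- sqrt(sum(r^2))
    if (beta / bnorm < tol)
      return(list(x = x, iterations = total, resvec = resvec, converged = TRUE))
    m <- min(restart, maxit - total)
    if (m <= 0L)
      return(list(x = x, iterations = total, resvec = resvec, converged = FALSE))
    V <- matrix(0, n, m + 1L)
    Z <- matrix(0, n, m)
    Hm <- matrix(0, m + 1L, m)
    cs <- numeric(m); sn <- numeric(m)
    g <- numeric(m + 1L); g[1L] <- beta
    V[, 1L] <- r / beta
    k <- 0L
    for (i in seq_len(m)) {
      Z[, i] <- precond(V[, i])
      w <- amul(Z[, i])
      for (j in seq_len(i)) {
        Hm[j, i] <- sum(w * V[, j])
        w <- w - Hm[j, i] * V[, j]
      }
      Hm[i + 1L, i] <- sqrt(sum(w^2))
      if (Hm[i + 1L, i] > 0) V[, i + 1L] <- w / Hm[i + 1L, i]
      # apply accumulated Givens rotations
      for (j in seq_len(i - 1L)) {
        tmp <- cs[j] * Hm[j, i] + sn[j] * Hm[j + 1L, i]
        Hm[j + 1L, i] <- -sn[j] * Hm[j, i] + cs[j] * Hm[j + 1L, i]
        Hm[j, i] <- tmp
      }
      dn <- sqrt(Hm[i, i]^2 + Hm[i + 1L, i]^2)
      cs[i] <- Hm[i, i] / dn; sn[i] <- Hm[i + 1L, i] / dn
      Hm[i, i] <- dn; Hm[i + 1L, i] <- 0
      g[i + 1L] <- -sn[i] * g[i]
      g[i] <- cs[i] * g[i]
      k <- i
      total <- total + 1L
      resvec <- c(resvec, abs(g[i + 1L]) / bnorm)
      if (abs(g[i + 1L]) / bnorm < tol) break
    }
    y <- backsolve(Hm[seq_len(k), seq_len(k), drop = FALSE], g[seq_len(k)])
    x <- x + Z[, seq_len(k), drop = FALSE] %*% y
    x <- as.numeric(x)
    if (utils::tail(resvec, 1L) < tol)
      return(list(x = x, iterations = total, resvec = resvec, converged = TRUE))
    if (total >= maxit)
      return(list(x = x, iterations = total, resvec = resvec, converged = FALSE))
  }
}

#' Solve the global saddle system with the block preconditioner
#'
#' Outer flexible GMRES on the global tangent, preconditioned by the
#' Schur-complement block preconditioner under the given policy.
#'
#' @param sys an `rbe_system`.
#' @param J global tangent matrix.
#' @param b right-hand side.
#' @param policy an `rbe_saddle_policy`.
#' @return list with `x`, `iterations`, `resvec`, `converged`.
#' @export
saddle_krylov_solve <- function(sys, J, b, policy) {
  pc <- build_block_preconditioner(sys, J, policy)
  out <- gmres_solve(function(x) as.numeric(J %*% x), b,
                     precond = pc$apply, tol = policy$outer_tol,
                     restart = policy$restart, maxit = policy$maxit)
  if (!out$converged) stop("FGMRES failed to reach tolerance ", policy$outer_tol)
  out
}
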