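#' Chebyshev polynomial of the second kind
#'
#' Evaluated by the recurrence `U_0 = 1`, `U_1 = 2x`,
#' `U_{n+1} = 2 x U_n - U_{n-1}`.
#'
#' @param n degree (non-negative integer).
#' @param x numeric vector of evaluation points.
#' @return numeric vector `U_n(x)`.
#' @export
chebyshev_U <- function(n, x) {
  stopifnot(n >= 0)
  if (n == 0L) return(rep(1, length(x)))
  um1 <- rep(1, length(x))
  u <- 2 * x
  if (n == 1L) return(u)
  for (k in 2:n) {
    up1 <- 2 * x * u - um1
    um1 <- u
    u <- up1
  }
  u
}

#' Ridge polynomial on the reference interface
#'
#' On the unit disk (`d = 3` interfaces): `P_k^n(x, y) = U_n(x cos w + y
#' sin w)` with `w = k pi / (n + 1)`. This family is orthonormal with
#' respect to the weight `W = 1/pi` on the disk. On the reference interval
#' `[-1, 1]` (`d = 2` interfaces) the scalar modes are simply `U_n(x)`,
#' orthonormal under the weight `(2/pi) sqrt(1 - x^2)`; `k` must then be 0.
#'
#' @param n degree.
#' @param k ridge index, `0 <= k <= n` (ignored on the interval).
#' @param pts evaluation points: `m x 2` matrix (disk) or numeric vector
#'   (interval).
#' @return numeric vector of values.
#' @export
ridge_polynomial <- function(n, k, pts) {
  if (k < 0 || k > n) stop("ridge index k out of range [0, n]")
  if (is.matrix(pts) && ncol(pts) == 2L) {
    w <- k * pi / (n + 1)
    chebyshev_U(n, pts[, 1L] * cos(w) + pts[, 2L] * sin(w))
  } else {
    chebyshev_U(n, as.numeric(pts))
  }
}

#' Spectral Lagrange-multiplier basis on the reference interface
#'
#' Builds the vector-valued set: every scalar mode of degree up to `n`
#' multiplied by each of the `d` canonic vectors (component-major ordering:
#' all scalar modes times `e_1`, then times `e_2`, ...). Scalar modes are
#' ordered degree-major, within a degree by ridge index `k`. The counts are
#' `N_lambda = d (n+1)(n+2)/2` for `d = 3` and `N_lambda = d (n+1)` for
#' `d = 2`.
#'
#' @param d ambient dimension (2 or 3).
#' @param n maximum polynomial degree (`n >= 0`).
#' @return an object of class `rbe_interface_basis` with fields `d`, `n`,
#'   `n_lambda`, `n_scalar`, `modes` (data.frame of `(degree, k, comp)`),
#'   `eval_scalar(i, pts)`, quadrature `quad` (points `x`, weights `w`,
#'   measure weights including the orthonormality weight in `w_weighted`).
#' @export
build_basis_set <- function(d, n) {
  if (!d %in% c(2L, 3L)) stop("unsupported ambient dimension d = ", d)
  stopifnot(n >= 0)
  if (d == 3L) {
    scal <- do.call(rbind, lapply(0:n, function(nn)
      data.frame(degree = nn, k = 0:nn)))
  } else {
    scal <- data.frame(degree = 0:n, k = 0L)
  }
  nsc <- nrow(scal)
  modes <- do.call(rbind, lapply(seq_len(d), function(comp)
    cbind(scal, comp = comp)))
  quad <- reference_interface_quadrature(d, n)
  obj <- structure(list(d = d, n = n, n_lambda = d * nsc, n_scalar = nsc,
                        scalar_modes = scal, modes = modes, quad = quad),
                   class = "rbe_interface_basis")
  obj$eval_scalar <- function(i, pts) {
    ridge_polynomial(scal$degree[i], scal$k[i], pts)
  }
  obj
}

#' @export
print.rbe_interface_basis <- function(x, ...) {
  cat(sprintf("<rbe_interface_basis> d = %d, degree n = %d, N_lambda = %d\n",
              x$d, x$n, x$n_lambda))
  invisible(x)
}

# Quadrature on the reference interface, exact (up to roundoff) for
# products of two scalar modes times the orthonormality weight.
# d = 3: tensorized Gauss-Legendre in radius (mapped to [0,1], including
# the polar factor r) and angle; d = 2: Gauss-Jacobi-like rule obtained
# from Gauss-Legendre of sufficient order on [-1,1].
reference_interface_quadrature <- function(d, n, order = NULL) {
  if (is.null(order)) order <- 2L * n + 4L
  if (d == 3L) {
    gr <- pracma::gaussLegendre(max(order %/% 2L + 2L, 4L), 0, 1)
    na <- max(2L * order, 8L)
    th <- 2 * pi * (seq_len(na) - 0.5) / na
    wth <- rep(2 * pi / na, na)
    r <- rep(gr$x, times = na)
    t2 <- rep(th, each = length(gr$x))
    x <- cbind(r * cos(t2), r * sin(t2))
    w <- rep(gr$w, times = na) * rep(wth, each = length(gr$x)) * r
    list(x = x, w = w, w_weighted = w / pi)
  } else {
    # Gauss-Chebyshev (second kind) rule: exact for the sqrt(1 - x^2)
    # weight that makes the U_n family orthonormal on [-1, 1]
    N <- max(order, 8L)
    th <- seq_len(N) * pi / (N + 1)
    x <- cos(th)
    wU <- pi / (N + 1) * sin(th)^2          # weights for weight sqrt(1-x^2)
    list(x = x, w = wU / sqrt(1 - x^2), w_weighted = wU * 2 / pi)
  }
}

#' Gram matrix of the scalar interface modes under the orthonormality weight
#'
#' Used to certify orthonormality; equals the identity up to quadrature
#' error.
#'
#' @param basis an `rbe_interface_basis`.
#' @return `n_scalar x n_scalar` numeric matrix.
#' @export
interface_basis_gram <- function(basis) {
  q <- basis$quad
  V <- vapply(seq_len(basis$n_scalar), function(i) basis$eval_scalar(i, q$x),
              numeric(length(q$w)))
  crossprod(V, V * q$w_weighted)
}

#' Map the reference interface basis onto a physical interface
#'
#' The map `Theta` sends the reference disk/interval onto the physical
#' interface by a rigid motion plus isotropic scaling by the interface
#' radius. In 2D the reference coordinate `s` in `[-1, 1]` is mapped to
#' `centre + s * radius * tangent` with the tangent fixed deterministically
#' (rotate the outward normal by -90 degrees). The vector components of the
#' basis stay expressed in the global Cartesian frame; `sign` is the
#' orientation factor `c = +/-1` of the side.
#'
#' @param basis an `rbe_interface_basis` with `d = 2`.
#' @param interface an interface descriptor (fields `centre`, `normal`,
#'   `radius`).
#' @param sign orientation sign, `+1` or `-1`.
#' @return a list with `eval(i, X)` returning the `n x 2` values of mapped
#'   vector mode `i` at physical points `X`, `theta_inv(X)` the reference
#'   coordinates, and the interface metadata.
#' @export
map_to_interface <- function(basis, interface, sign = 1) {
  stopifnot(sign %in% c(-1, 1))
  if (interface$radius <= 0) stop("degenerate interface: zero radius")
  ctr <- interface$centre
  tang <- c(interface$normal[2L], -interface$normal[1L])
  radius <- interface$radius
  theta_inv <- function(X) {
    (sweep(X, 2L, ctr) %*% tang) / radius
  }
  evalf <- function(i, X) {
    md <- basis$modes[i, ]
    s <- theta_inv(X)
    v <- sign * ridge_polynomial(md$degree, md$k, as.numeric(s))
    out <- matrix(0, nrow(X), 2L)
    out[, md$comp] <- v
    out
  }
  list(basis = basis, interface = interface, sign = sign,
       centre = ctr, tangent = tang, radius = radius,
       theta = function(s) sweep(outer(as.numeric(s), tang * radius), 2L, ctr, `+`),
       theta_inv = theta_inv, eval = evalf)
}
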