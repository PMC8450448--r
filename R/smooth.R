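# Solve A Z + Z B = C for symmetric A, B by simultaneous diagonalization:
# with A = U a U', B = V b V', Z = U ( (U' C V) / (a_i + b_j) ) V'.
solveSylvesterSym <- function(A, B, C, tol = 1e-12) {
  eA <- eigen(A, symmetric = TRUE)
  eB <- eigen(B, symmetric = TRUE)
  denom <- outer(eA$values, eB$values, "+")
  if (min(abs(denom)) < tol * max(1, max(abs(denom))))
    stop("singular Sylvester system (an eigenvalue pair sums to zero); ",
      "use beta > 0 to regularize")
  Ct <- crossprod(eA$vectors, C %*% eB$vectors)
  eA$vectors %*% (Ct / denom) %*% t(eB$vectors)
}

#' Update the smooth representation Z of one view
#'
#' Solves the graph-regularized self-expression block update for one omics
#' view inside the joint objective: given the current fused graph S and the
#' view's Laplacian L, find the Z minimizing
#' \deqn{\lVert X - XZ\rVert_F^2 + \alpha\,tr(Z L Z^T) +
#'   \beta\epsilon^v \lVert S - Z\rVert_F^2.}
#' The stationarity condition is the Sylvester equation
#' \deqn{(X^T X + \beta\epsilon^v I)\,Z + \alpha Z L = X^T X +
#'   \beta\epsilon^v S.}
#'
#' Two solution modes are provided and the distinction matters:
#' \describe{
#'   \item{\code{"as_printed"}}{the one-shot closed form
#'     \eqn{Z = (X^T X + \beta\epsilon^v I + \alpha L)^{-1}(X^T X +
#'     \beta\epsilon^v S)}. This moves the \eqn{\alpha L} term from the right
#'     of Z to the left, i.e. it is exact only when Z and L commute (always
#'     when \eqn{\alpha = 0}). It is the update the original algorithm states,
#'     and the default.}
#'   \item{\code{"sylvester"}}{an exact dense solve of the Sylvester equation
#'     above (both coefficient matrices are symmetric, so simultaneous
#'     eigendecomposition applies), i.e. the true minimizer of the block
#'     objective.}
#' }
#' In both modes negative entries are then clipped to zero
#' (\code{clip = TRUE}), matching the algorithm's projection step; clipping
#' voids exact optimality, so analyses of the descent property disable it.
#'
#' @param x an [OmicsView-class] or features-by-samples matrix.
#' @param S current fused graph ([FusedGraph-class] or n x n matrix).
#' @param L the view's [GraphLaplacian-class] (or matrix).
#' @param epsV this view's positive fusion weight \eqn{\epsilon^v}.
#' @param alpha smoothness weight, \eqn{\ge 0}.
#' @param beta fusion weight, \eqn{\ge 0} (must be > 0 for the system to be
#'   guaranteed nonsingular when \eqn{X^T X} is rank deficient).
#' @param mode \code{"as_printed"} (default) or \code{"sylvester"}.
#' @param clip clip negative entries to zero afterwards (default TRUE).
#' @param gram optional precomputed \eqn{X^T X} (n x n), to avoid re-forming
#'   the Gram matrix every iteration.
#' @return A [SmoothRepresentation-class].
#' @export
updateZ <- function(x, S, L, epsV, alpha, beta,
    mode = c("as_printed", "sylvester"), clip = TRUE, gram = NULL) {
  mode <- match.arg(mode)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be nonnegative")
  if (epsV <= 0) stop("epsV must be positive")
  Sm <- asSquareMatrix(S)
  Lm <- asSquareMatrix(L)
  nm <- if (is(x, "OmicsView")) viewName(x) else "view"
  A <- if (is.null(gram)) {
    Xm <- asViewMatrix(x)
    if (ncol(Xm) != nrow(Sm)) stop("X and S disagree on the number of samples")
    crossprod(Xm)
  } else as.matrix(gram)
  n <- nrow(A)
  be <- beta * epsV
  rhs <- A + be * Sm
  Z <- if (mode == "as_printed") {
    lhs <- A + diag(be, n) + alpha * Lm
    res <- tryCatch(solve(lhs, rhs), error = function(e) e)
    if (inherits(res, "error"))
      stop("singular system in the Z update (rank-deficient X^T X with ",
        "alpha = beta = 0?); use beta > 0")
    res
  } else {
    solveSylvesterSym(A + diag(be, n), alpha * Lm, rhs)
  }
  if (clip) Z <- pmax(Z, 0)
  dimnames(Z) <- dimnames(Sm)
  new("SmoothRepresentation", Z = Z, viewName = nm)
}

#' Clip negative entries to zero
#'
#' The projection step applied to Z after each linear solve; idempotent.
#'
#' @param Z a [SmoothRepresentation-class] or numeric matrix.
#' @return object of the same kind with entries \eqn{\max(z_{ij}, 0)}.
#' @export
clipNonneg <- function(Z) {
  if (is(Z, "SmoothRepresentation"))
    new("SmoothRepresentation", Z = pmax(Z@Z, 0), viewName = Z@viewName)
  else pmax(as.matrix(Z), 0)
}

#' Graph-smoothness penalty tr(Z L Z^T)
#'
#' Equals \eqn{\frac12 \sum_{ij} w_{ij}\lVert z_i - z_j\rVert^2}: columns of Z
#' belonging to samples joined by strong edges are pulled together, which is
#' the grouping effect the smooth representation is named for.
#'
#' @param Z [SmoothRepresentation-class] or n x n matrix.
#' @param L [GraphLaplacian-class] or n x n matrix.
#' @return nonnegative scalar (up to numerical tolerance).
#' @export
smoothnessPenalty <- function(Z, L) {
  Zm <- asSquareMatrix(Z)
  Lm <- asSquareMatrix(L)
  if (ncol(Zm) != nrow(Lm))
    stop("Z and L have incompatible dimensions")
  sum((Zm %*% Lm) * Zm)
}

#' Self-expression reconstruction error
#'
#' Squared Frobenius norm \eqn{\lVert X - XZ\rVert_F^2} of the residual of
#' representing every sample as a combination of the others.
#'
#' @param x [OmicsView-class] or features-by-samples matrix.
#' @param Z [SmoothRepresentation-class] or n x n matrix.
#' @return nonnegative scalar.
#' @export
reconstructionError <- function(x, Z) {
  Xm <- asViewMatrix(x)
  Zm <- asSquareMatrix(Z)
  if (ncol(Xm) != nrow(Zm))
    stop("X and Z have incompatible dimensions")
  sum((Xm - Xm %*% Zm)^2)
}
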