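#' Joint objective of the fused multi-view model
#'
#' \deqn{\sum_v\left(\lVert X^v - X^v Z^v\rVert_F^2 +
#'   \alpha\,tr(Z^v L^v (Z^v)^T) +
#'   \beta\epsilon^v\lVert S - Z^v\rVert_F^2\right) +
#'   \lambda\,tr(F^T L_S F)}
#' with \eqn{L_S} built from the symmetrized S. This is the quantity each
#' block update of [mrfmsc()] descends (exactly so in \code{sylvester} mode
#' with clipping disabled and weights frozen).
#'
#' @param Xlist list of [OmicsView-class] or matrices (features x samples).
#' @param Zlist list of [SmoothRepresentation-class] or n x n matrices.
#' @param S [FusedGraph-class] or n x n matrix.
#' @param F [SpectralEmbedding-class] or n x k matrix.
#' @param eps [ViewWeights-class] or positive numeric vector.
#' @param Llist list of per-view [GraphLaplacian-class] or matrices.
#' @param alpha,beta,lam hyperparameters of the three regularizers.
#' @return finite scalar.
#' @export
mrfmscObjective <- function(Xlist, Zlist, S, F, eps, Llist, alpha, beta, lam) {
  t <- length(Xlist)
  if (length(Zlist) != t || length(Llist) != t)
    stop("Xlist, Zlist and Llist must have one entry per view")
  e <- if (is(eps, "ViewWeights")) eps@eps else as.numeric(eps)
  Sm <- asSquareMatrix(S)
  obj <- 0
  for (v in seq_len(t)) {
    Zm <- asSquareMatrix(Zlist[[v]])
    obj <- obj + reconstructionError(Xlist[[v]], Zm) +
      alpha * smoothnessPenalty(Zm, Llist[[v]]) +
      beta * e[v] * sum((Sm - Zm)^2)
  }
  Fm <- asEmbeddingMatrix(F)
  LS <- fusedLaplacian(Sm)@values
  obj + lam * sum((crossprod(Fm, LS) %*% Fm)[cbind(seq_len(ncol(Fm)),
    seq_len(ncol(Fm)))])
}

#' Fit the multi-smooth-representation fusion clustering model
#'
#' Alternating optimization over the per-view smooth representations
#' \eqn{Z^v}, the fused similarity graph S, the spectral embedding F and the
#' adaptive view weights \eqn{\epsilon^v}:
#' \enumerate{
#'   \item per view, solve the graph-regularized self-expression update
#'     ([updateZ()]) and clip negatives,
#'   \item refresh the fused graph S as the weight-averaged consensus with
#'     spectral pull ([updateS()]),
#'   \item refresh F as the k bottom eigenvectors of \eqn{L_S}
#'     ([updateF()]),
#'   \item refresh the view weights \eqn{\epsilon^v = 1/(2\lVert S -
#'     Z^v\rVert_F)} ([updateWeights()]),
#' }
#' starting from \eqn{S = I}, \eqn{\epsilon^v = 1/t}, and stopping when the
#' relative Frobenius change of S drops below \code{tol} or after
#' \code{maxIter} iterations. The spectral pull is inactive on the first pass
#' (no embedding exists yet). Final labels come from K-means on the rows of F.
#'
#' The objective can fluctuate slightly across iterations in the default
#' configuration: the clipping projection and the weight refresh both break
#' exact coordinate descent. It is logged per iteration, not asserted.
#'
#' @param views list of [OmicsView-class] sharing identical sample ids in
#'   identical order (use [alignViews()] first).
#' @param k number of clusters, \eqn{2 \le k < n}.
#' @param alpha smoothness hyperparameter (default 1).
#' @param beta fusion hyperparameter, > 0 (default 1).
#' @param lam spectral hyperparameter (default 1).
#' @param K KNN neighbour count for the per-view graphs (default 20).
#' @param kernel KNN edge-weight kernel, \code{"heat"} or \code{"binary"}.
#' @param maxIter iteration cap (default 50).
#' @param tol relative-change threshold on S (default 1e-3).
#' @param zMode \code{"as_printed"} (default) or \code{"sylvester"}; see
#'   [updateZ()].
#' @param clip clip negatives in Z and S (default TRUE; disable only for
#'   analyses of the exact descent property).
#' @param standardize z-score features per view first (default TRUE); see
#'   [standardizeView()].
#' @param restarts,seed K-means restarts and RNG seed.
#' @param verbose print per-iteration objective and weights to stderr.
#' @return An [MRFMSCResult-class].
#' @examples
#' sim <- makeMultiview(n = 60, k = 3, dims = c(80, 60), seed = 1)
#' fit <- mrfmsc(sim$views, k = 3, K = 10, seed = 1)
#' table(clusterLabels(fit), sim$labels)
#' @export
mrfmsc <- function(views, k, alpha = 1, beta = 1, lam = 1, K = 20L,
    kernel = c("heat", "binary"), maxIter = 50L, tol = 1e-3,
    zMode = c("as_printed", "sylvester"), clip = TRUE, standardize = TRUE,
    restarts = 50L, seed = 1L, verbose = FALSE) {
  kernel <- match.arg(kernel)
  zMode <- match.arg(zMode)
  if (!length(views)) stop("need at least one view")
  ids <- sampleIds(views[[1L]])
  for (v in views)
    if (!identical(sampleIds(v), ids))
      stop("views must share identical sample ids in identical order; ",
        "run alignViews() first")
  n <- length(ids)
  k <- as.integer(k)
  if (k < 2L || k >= n) stop("need 2 <= k < n")
  if (beta <= 0) stop("beta must be positive")
  if (standardize) views <- lapply(views, standardizeView)
  t <- length(views)

  Llist <- lapply(views, function(v)
    graphLaplacian(knnAffinity(v, K = K, kernel = kernel)))
  grams <- lapply(views, function(v) crossprod(viewValues(v)))

  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  eps <- rep(1 / t, t)
  G <- 0
  Fm <- NULL
  epsTrace <- matrix(eps, nrow = 1L,
    dimnames = list(NULL, vapply(views, viewName, character(1))))
  objTrace <- numeric(0)
  sChange <- numeric(0)
  converged <- FALSE
  iter <- 0L

  while (iter < maxIter) {
    iter <- iter + 1L
    Zlist <- lapply(seq_len(t), function(v)
      updateZ(views[[v]], S, Llist[[v]], eps[v], alpha, beta,
        mode = zMode, clip = clip, gram = grams[[v]]))
    Snew <- updateS(Zlist, eps, G, beta, lam, clip = clip)@S
    dimnames(Snew) <- list(ids, ids)
    Femb <- updateF(Snew, k)
    Fm <- Femb
    G <- pairwiseEmbeddingDists(Femb)
    epsNew <- updateWeights(Snew, Zlist)@eps
    obj <- mrfmscObjective(views, Zlist, Snew, Femb, eps, Llist,
      alpha, beta, lam)
    objTrace <- c(objTrace, obj)
    epsTrace <- rbind(epsTrace, epsNew)
    rel <- fnorm(Snew - S) / max(fnorm(S), .Machine$double.eps)
    sChange <- c(sChange, rel)
    if (verbose)
      message(sprintf("iter %2d  objective %.6g  rel-dS %.3g  eps %s",
        iter, obj, rel, paste(signif(epsNew, 3), collapse = " ")))
    S <- Snew
    eps <- epsNew
    if (rel < tol) { converged <- TRUE; break }
  }

  labels <- kmeansLabels(Fm, k, restarts = restarts, seed = seed)
  names(labels) <- ids
  new("MRFMSCResult",
    labels = labels,
    S = new("FusedGraph", S = S),
    F = Fm,
    Z = Zlist,
    epsTrace = epsTrace,
    objectiveTrace = objTrace,
    sChangeTrace = sChange,
    nIter = iter,
    converged = converged,
    hyperparams = list(k = k, alpha = alpha, beta = beta, lam = lam, K = K,
      kernel = kernel, maxIter = maxIter, tol = tol, zMode = zMode,
      clip = clip, standardize = standardize, restarts = restarts,
      seed = seed))
}

#' Grid search with silhouette-based model screening
#'
#' Fits every combination of the supplied hyperparameter values and returns
#' the fit maximizing the mean silhouette width computed on the rows of the
#' spectral embedding — the screening index used to choose the number of
#' clusters when no ground truth exists.
#'
#' @param views list of aligned [OmicsView-class].
#' @param k,alpha,beta,lam,K vectors of candidate values (scalars allowed).
#' @param silhouetteSpace score clusterings in the geometry of the embedding
#'   rows (\code{"embedding"}, default) or with distances \eqn{1 - S/\max(S)}
#'   from the fused graph (\code{"fused"}).
#' @param ... further arguments passed to [mrfmsc()] (seed, zMode, ...).
#' @param verbose print one line per combination.
#' @return list with elements \code{best} (the winning [MRFMSCResult-class]),
#'   \code{params} (named list of its hyperparameters), and \code{scores}
#'   (data.frame of all combinations with their mean silhouette; failed fits
#'   carry NA and the error message).
#' @examples
#' sim <- makeMultiview(n = 60, k = 3, dims = c(80, 60), seed = 1)
#' gs <- mrfmscGrid(sim$views, k = 2:4, K = 10, seed = 1)
#' gs$params$k
#' @export
mrfmscGrid <- function(views, k, alpha = 1, beta = 1, lam = 1, K = 20L,
    silhouetteSpace = c("embedding", "fused"), ..., verbose = FALSE) {
  silhouetteSpace <- match.arg(silhouetteSpace)
  grid <- expand.grid(k = k, alpha = alpha, beta = beta, lam = lam, K = K,
    KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty hyperparameter grid")
  grid$k <- as.integer(grid$k)
  grid$K <- as.integer(grid$K)
  scores <- rep(NA_real_, nrow(grid))
  errors <- rep(NA_character_, nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      fit <- mrfmsc(views, k = grid$k[i], alpha = grid$alpha[i],
        beta = grid$beta[i], lam = grid$lam[i], K = grid$K[i], ...)
      sil <- if (silhouetteSpace == "embedding") {
        silhouetteMean(embeddingBasis(spectralEmbedding(fit)),
          clusterLabels(fit))
      } else {
        S <- fusedValues(fusedGraph(fit))
        S <- (S + t(S)) / 2
        D <- 1 - S / max(S)
        diag(D) <- 0
        silhouetteMean(NULL, clusterLabels(fit), distances = D)
      }
      list(fit = fit, sil = sil)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res$fit
      scores[i] <- res$sil
    }
    if (verbose)
      message(sprintf("k=%d alpha=%g beta=%g lam=%g K=%d  silhouette %s",
        grid$k[i], grid$alpha[i], grid$beta[i], grid$lam[i], grid$K[i],
        if (is.na(scores[i])) errors[i] else sprintf("%.4f", scores[i])))
  }
  if (all(is.na(scores)))
    stop("all grid fits failed:\n  ",
      paste(unique(stats::na.omit(errors)), collapse = "\n  "))
  best <- which.max(scores)
  list(best = fits[[best]],
    params = as.list(grid[best, , drop = FALSE]),
    scores = cbind(grid, silhouette = scores, error = errors))
}
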