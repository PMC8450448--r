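# internal helpers shared across modules

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

fnorm <- function(x) sqrt(sum(x^2))

# accept OmicsView or plain matrix wherever a data matrix is expected
asViewMatrix <- function(x) {
  if (is(x, "OmicsView")) x@values else as.matrix(x)
}

# accept the dedicated container or a plain matrix
asSquareMatrix <- function(x) {
  m <- if (is(x, "FusedGraph")) x@S
    else if (is(x, "SmoothRepresentation")) x@Z
    else if (is(x, "AffinityGraph")) x@weights
    else if (is(x, "GraphLaplacian")) x@values
    else as.matrix(x)
  if (nrow(m) != ncol(m)) stop("expected a square matrix")
  m
}

asEmbeddingMatrix <- function(x) {
  if (is(x, "SpectralEmbedding")) x@basis else as.matrix(x)
}
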