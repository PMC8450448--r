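#' Read an omics matrix from a delimited text file
#'
#' Reads a TSV or CSV matrix with a header row of identifiers and a first
#' column of identifiers, and returns an [OmicsView-class] in features-by-
#' samples orientation regardless of how the file is laid out.
#'
#' @param path path to a tab- or comma-separated file. Files ending in
#'   \code{.csv} are read comma-separated, anything else tab-separated.
#' @param orientation \code{"features_by_samples"} (default) if rows are
#'   features, \code{"samples_by_features"} if rows are samples (the matrix is
#'   transposed after reading).
#' @param viewName name to attach to the view; defaults to the file base name.
#' @param impute \code{"none"} (default) rejects missing values with an error
#'   naming their coordinates; \code{"mean"} replaces them by the per-feature
#'   mean over the observed samples.
#' @return An [OmicsView-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeViewMatrix(matrix(1:6, 3, 2, dimnames = list(letters[1:3],
#'   c("s1", "s2"))), f)
#' readViewMatrix(f)
#' @export
readViewMatrix <- function(path,
    orientation = c("features_by_samples", "samples_by_features"),
    viewName = NULL, impute = c("none", "mean")) {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = "character", comment.char = "")
  m <- matrix(NA_real_, nrow(df), ncol(df),
    dimnames = list(rownames(df), colnames(df)))
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) &
      !(toupper(trimws(col)) %in% c("NA", "NAN", "")))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
        rownames(df)[bad[1L]], colnames(df)[j], col[bad[1L]]))
    m[, j] <- num
  }
  if (orientation == "samples_by_features") m <- t(m)
  if (anyNA(m)) {
    if (impute == "none") {
      idx <- which(is.na(m), arr.ind = TRUE)
      shown <- utils::head(sprintf("(%s, %s)", rownames(m)[idx[, 1L]],
        colnames(m)[idx[, 2L]]), 5L)
      stop(sprintf(
        "%d missing value(s) at %s%s; use impute = \"mean\" to impute",
        nrow(idx), paste(shown, collapse = ", "),
        if (nrow(idx) > 5L) ", ..." else ""))
    }
    for (i in which(rowSums(is.na(m)) > 0)) {
      mu <- mean(m[i, ], na.rm = TRUE)
      if (!is.finite(mu))
        stop(sprintf("feature '%s' has no observed values", rownames(m)[i]))
      m[i, is.na(m[i, ])] <- mu
    }
  }
  if (is.null(viewName))
    viewName <- sub("\\.[^.]*$", "", basename(path))
  OmicsView(m, viewName)
}

#' Write a labelled numeric matrix as TSV
#'
#' Writes a matrix with its dimnames as row labels and column header, at a
#' fixed significant-digit precision so that a read/write cycle round-trips
#' the values exactly at that precision.
#'
#' @param x numeric matrix with dimnames (or an [OmicsView-class]).
#' @param path output path.
#' @param digits significant digits kept (default 10).
#' @return \code{path}, invisibly.
#' @export
writeViewMatrix <- function(x, path, digits = 10L) {
  m <- asViewMatrix(x)
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  out <- cbind(id = rownames(m),
    matrix(formatC(signif(m, digits), digits = digits, format = "g"),
      nrow(m), ncol(m), dimnames = dimnames(m)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict several views to their common samples
#'
#' Multi-omics layers rarely cover exactly the same samples; every downstream
#' step requires one shared sample set. This restricts each view to the sorted
#' intersection of all sample identifiers, in identical order across views.
#' Idempotent: aligned input comes back unchanged.
#'
#' @param views list of [OmicsView-class] objects.
#' @return list of views with identical \code{sampleIds()} in identical order.
#' @examples
#' a <- OmicsView(matrix(1:6, 2, 3, dimnames = list(NULL, c("a", "b", "c"))))
#' b <- OmicsView(matrix(1:6, 2, 3, dimnames = list(NULL, c("b", "c", "d"))))
#' sampleIds(alignViews(list(a, b))[[1]])
#' @export
alignViews <- function(views) {
  if (!length(views)) stop("need at least one view")
  ids <- lapply(views, sampleIds)
  common <- Reduce(intersect, ids)
  if (length(common) < 2L)
    stop(sprintf("views share %d sample(s); need at least 2", length(common)))
  common <- sort(common)
  lapply(views, function(v) v[, common])
}

#' Write cluster assignments as a two-column TSV
#'
#' Labels are relabelled to consecutive 1-based integers in order of first
#' appearance before writing.
#'
#' @param sampleIds character vector of sample identifiers.
#' @param labels integer cluster labels, same length.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAssignments <- function(sampleIds, labels, path) {
  if (length(sampleIds) != length(labels))
    stop(sprintf("%d sample ids but %d labels",
      length(sampleIds), length(labels)))
  cluster <- if (length(labels)) match(labels, unique(labels)) else integer(0)
  utils::write.table(
    data.frame(sample_id = as.character(sampleIds), cluster = cluster),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score features and drop uninformative ones
#'
#' Centers and scales each feature (row) to mean 0, sd 1 over samples. Omics
#' layers live on incommensurate scales (log expression, methylation beta
#' values, ...), so raw Euclidean distances between samples are dominated by
#' whichever layer has the widest numeric range; per-feature standardization
#' is applied by default before graph construction. Features with zero
#' variance carry no distance information and make the z-score undefined;
#' they are dropped with a warning.
#'
#' With \code{scaleByDim = TRUE} (default) the z-scored matrix is further
#' divided by the square root of its feature count, so each view's Gram
#' matrix \eqn{X^T X} has approximately unit diagonal. Views then contribute on
#' a common scale regardless of how many features they carry, and the
#' model's hyperparameters keep one meaning across views and datasets.
#'
#' @param view an [OmicsView-class].
#' @param scaleByDim divide by \eqn{\sqrt{m_v}} after z-scoring (default
#'   TRUE).
#' @return standardized [OmicsView-class].
#' @export
standardizeView <- function(view, scaleByDim = TRUE) {
  m <- asViewMatrix(view)
  sds <- apply(m, 1L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance feature(s) from view '%s'",
      sum(!keep), viewName(view)))
    if (!any(keep)) stop("all features have zero variance")
    m <- m[keep, , drop = FALSE]
    sds <- sds[keep]
  }
  m <- (m - rowMeans(m)) / sds
  if (scaleByDim) m <- m / sqrt(nrow(m))
  new("OmicsView", values = m, viewName = viewName(view))
}
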