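#' Build the transition-type by (unit, voice) feature matrix
#'
#' Assembles the input of the principal component analysis at one order:
#' one column per (aggregation unit, voice) variable, one row per transition
#' type (`"context->target"`). Under `valueKind = "tp"` rows are the union
#' of all observed types and cells hold conditional probabilities, with 0
#' where a type was never observed in that column (absence is informative).
#' Under `valueKind = "ic"` cells hold information content in bits, which
#' cannot represent absence, so rows are restricted to the types observed in
#' every column. Rows are ordered lexicographically on the pattern text so
#' the matrix is reproducible.
#'
#' @param tps list of [TPDistribution-class] objects, one per column, all of
#'   the same order.
#' @param columnInfo data.frame with one row per element of `tps`, columns
#'   `unit_id`, `voice`, `mode`.
#' @param valueKind `"tp"` (default) or `"ic"`.
#' @return A [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(tps, columnInfo, valueKind = c("tp", "ic")) {
  valueKind <- match.arg(valueKind)
  stopifnot(is.list(tps), length(tps) >= 1L,
            all(vapply(tps, is, logical(1), "TPDistribution")),
            is.data.frame(columnInfo), nrow(columnInfo) == length(tps),
            all(c("unit_id", "voice", "mode") %in% names(columnInfo)))
  ord <- unique(vapply(tps, function(d) d@order, integer(1)))
  if (length(ord) != 1L)
    .stopf("all distributions must share one order (got: %s)",
           paste(ord, collapse = ", "))
  colLab <- paste(columnInfo$unit_id, columnInfo$voice, sep = ":")
  keysPer <- lapply(tps, function(d)
    paste(d@transitions$context, d@transitions$target, sep = "->"))
  empty <- lengths(keysPer) == 0L
  if (valueKind == "tp") {
    if (any(empty))
      .stopf("column(s) with no observed transitions: %s",
             paste(colLab[empty], collapse = ", "))
    rows <- sort(unique(unlist(keysPer)))
  } else {
    if (any(empty))
      .stopf("column(s) with no observed transitions: %s",
             paste(colLab[empty], collapse = ", "))
    rows <- sort(Reduce(intersect, keysPer))
    if (length(rows) == 0L)
      .stopf("no transition type is observed in every column; use valueKind = 'tp'")
  }
  if (length(rows) == 0L) .stopf("empty union of transition types")
  vals <- matrix(0, nrow = length(rows), ncol = length(tps),
                 dimnames = list(rows, colLab))
  for (j in seq_along(tps)) {
    idx <- match(keysPer[[j]], rows)
    keep <- !is.na(idx)
    p <- tps[[j]]@transitions$prob[keep]
    vals[idx[keep], j] <- if (valueKind == "tp") p else informationContent(p)
  }
  new("FeatureMatrix", values = vals,
      columnInfo = as.data.frame(columnInfo,
                                 stringsAsFactors = FALSE),
      order = ord, valueKind = valueKind)
}

#' Correlation-matrix principal component analysis of a feature matrix
#'
#' Standardises every (unit, voice) variable to zero mean and unit variance
#' over the transition types, eigendecomposes the variable correlation
#' matrix, and reports eigenvalues, variance percentages (eigenvalue divided
#' by the number of variables) and per-variable loadings for the first
#' `nReport` components. Components with eigenvalue > 1 count as adopted.
#' Loadings are eigenvectors scaled by the square root of their eigenvalue;
#' each component's sign is fixed so its mean loading is non-negative, since
#' eigenvector sign is otherwise arbitrary.
#'
#' @param fm a [FeatureMatrix-class] with at least 2 columns and 2 rows.
#' @param nReport number of leading components to report loadings for
#'   (2 for a sonata-style run, 3 when mode components are of interest).
#' @return A [PCAResult-class].
#' @export
pcaCorrelation <- function(fm, nReport = 2L) {
  stopifnot(is(fm, "FeatureMatrix"))
  X <- fm@values
  if (ncol(X) < 2L) .stopf("PCA needs at least 2 columns")
  if (nrow(X) < 2L) .stopf("PCA needs at least 2 transition-type rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    .stopf("zero-variance column(s): %s",
           paste(colnames(X)[sds == 0], collapse = ", "))
  C <- stats::cor(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  # a correlation matrix is PSD; eigenvalues below 0 are numerical noise
  # (rank deficiency when there are fewer transition types than variables)
  if (any(vals < -1e-8))
    .stopf("correlation matrix has a substantially negative eigenvalue (%g)",
           min(vals))
  vals[vals < 0] <- 0
  nReport <- min(as.integer(nReport), ncol(X))
  load <- matrix(NA_real_, nrow = ncol(X), ncol = nReport,
                 dimnames = list(colnames(X), paste0("PC", seq_len(nReport))))
  for (k in seq_len(nReport)) {
    v <- e$vectors[, k] * sqrt(max(vals[k], 0))
    if (mean(v) < 0) v <- -v
    load[, k] <- v
  }
  pct <- vals / ncol(X) * 100
  new("PCAResult", eigenvalues = vals, variancePct = pct,
      cumulativePct = cumsum(pct), loadings = load,
      nAdopted = as.integer(sum(vals > 1)), columnInfo = fm@columnInfo)
}

#' Describe adopted components as shared or contrast components
#'
#' For each reported component, summarises the mean loading by voice and by
#' mode and classifies the component: `"shared"` when every loading exceeds
#' `floor` (all variables move together), `"voice-contrast"` /
#' `"mode-contrast"` when the group means differ in sign or by more than
#' `margin`, else `"mixed"`. When both contrasts trigger, the larger group
#' separation wins. Purely descriptive — no test statistics are attached.
#'
#' @param pca a [PCAResult-class].
#' @param floor minimum loading for the `"shared"` label (default 0).
#' @param margin minimum absolute difference of group mean loadings for a
#'   contrast label (default 0.2).
#' @return data.frame with one row per reported component.
#' @export
interpretComponents <- function(pca, floor = 0, margin = 0.2) {
  stopifnot(is(pca, "PCAResult"))
  info <- pca@columnInfo
  out <- list()
  for (k in seq_len(ncol(pca@loadings))) {
    v <- pca@loadings[, k]
    mv <- tapply(v, info$voice, mean)
    byMode <- info$mode %in% c("major", "minor")
    mm <- if (any(byMode)) tapply(v[byMode], info$mode[byMode], mean) else NULL
    voiceSep <- if (all(c("melody", "bass") %in% names(mv)))
      mv[["melody"]] - mv[["bass"]] else NA_real_
    modeSep <- if (!is.null(mm) && all(c("major", "minor") %in% names(mm)))
      mm[["major"]] - mm[["minor"]] else NA_real_
    voiceHit <- !is.na(voiceSep) &&
      (sign(mv[["melody"]]) != sign(mv[["bass"]]) || abs(voiceSep) > margin)
    modeHit <- !is.na(modeSep) &&
      (sign(mm[["major"]]) != sign(mm[["minor"]]) || abs(modeSep) > margin)
    cls <- if (all(v > floor)) "shared"
      else if (voiceHit && (!modeHit || abs(voiceSep) >= abs(modeSep)))
        "voice-contrast"
      else if (modeHit) "mode-contrast"
      else "mixed"
    out[[k]] <- data.frame(
      component = k,
      eigenvalue = pca@eigenvalues[k],
      variance_pct = pca@variancePct[k],
      mean_loading_melody = if ("melody" %in% names(mv)) mv[["melody"]] else NA_real_,
      mean_loading_bass = if ("bass" %in% names(mv)) mv[["bass"]] else NA_real_,
      mean_loading_major = if (!is.null(mm) && "major" %in% names(mm))
        mm[["major"]] else NA_real_,
      mean_loading_minor = if (!is.null(mm) && "minor" %in% names(mm))
        mm[["minor"]] else NA_real_,
      classification = cls,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
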