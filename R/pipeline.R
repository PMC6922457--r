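# CSV writer: config-hash comment header, doubles at fixed 6 decimals for
# diffable reruns.
.writeStamped <- function(df, path, hash) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.6f", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE) # contexts contain commas

  path
}

.stage <- function(name, unit, expr) {
  tryCatch(expr, error = function(e)
    .stopf("stage '%s' failed for %s: %s", name, unit, conditionMessage(e)))
}

#' Run the full melody/bass corpus analysis
#'
#' Orchestrates the pipeline end to end: voice lines (already extracted, or
#' loaded from scores via [loadCorpus()]) are interval-encoded per order,
#' piece-level distributions are pooled per aggregation unit, conditional
#' entropies are tabulated, a correlation-matrix PCA is run per order over
#' the (unit, voice) transition-type profiles, and melody-bass (and, for a
#' mode-paired design, major-minor) entropy correlations are computed.
#'
#' Two run templates mirror the two study designs: `"study1"` (pool all
#' pieces of a unit, report 2 components, pooled-mode correlations) and
#' `"study2"` (same pooling, report 3 components, mode-split melody-bass
#' correlations plus the tonic-paired major-minor analysis).
#'
#' The analysis is deterministic: rerunning with the same configuration and
#' corpus reproduces every output byte for byte, and each written file
#' starts with a `# config_hash:` header identifying the configuration.
#'
#' @param corpus a [MusicCorpus-class] (or [SyntheticCorpus-class]).
#' @param template `"study1"` or `"study2"`.
#' @param orders Markov orders to analyse (subset of 0..5).
#' @param convention interval encoding convention, see [contextTargets()].
#' @param pooling `"by_transitions"` or `"explicit"` (see [poolTP()]).
#' @param valueKind PCA feature values, `"tp"` or `"ic"`.
#' @param nReport components to report loadings for; defaults to 2
#'   (`study1`) or 3 (`study2`).
#' @param alpha significance level for correlation flags.
#' @param outDir optional output directory; when given, writes
#'   `entropies.csv`, `pca_eigenvalues.csv`, `pca_loadings.csv`,
#'   `correlations.csv`, `interpretation.json`, `tp_long.csv` (when
#'   `writeTP`) and `run_log.txt`. Partial outputs are removed if a stage
#'   fails.
#' @param writeTP also export the pooled distributions in long format
#'   (can be large).
#' @return A list of class `"tonalEntropyAnalysis"`: `entropies` (complete
#'   grid), `pca` (per-order [PCAResult-class]), `interpretation`,
#'   `correlations`, `pairedCorrelations` (study2) , `pooledTP`, `config`,
#'   `configHash`.
#' @export
#' @examples
#' sc <- syntheticCorpus(nUnits = 4, tonesPerVoice = 120, alphabet = -3:3,
#'                       seed = 7)
#' res <- runAnalysis(sc, orders = 0:2)
#' res$correlations
runAnalysis <- function(corpus, template = c("study1", "study2"),
                        orders = 0:5,
                        convention = c("window", "chain"),
                        pooling = c("by_transitions", "explicit"),
                        valueKind = c("tp", "ic"), nReport = NULL,
                        alpha = 0.05, outDir = NULL, writeTP = TRUE) {
  template <- match.arg(template)
  convention <- match.arg(convention)
  pooling <- match.arg(pooling)
  valueKind <- match.arg(valueKind)
  stopifnot(is(corpus, "MusicCorpus"))
  orders <- sort(unique(as.integer(orders)))
  if (any(orders < 0L | orders > 5L)) .stopf("orders must lie in 0..5")
  if (is.null(nReport)) nReport <- if (template == "study2") 3L else 2L

  cfg <- list(template = template, orders = orders,
              convention = convention, pooling = pooling,
              valueKind = valueKind, nReport = nReport, alpha = alpha,
              nPieces = length(corpus), units = unitIds(corpus))
  hash <- .configHash(cfg)
  written <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    on.exit({
      # a failed run must not leave partial outputs behind
      if (!is.null(written) && length(written)) unlink(written)
    })
  }

  m <- corpus@manifest
  units <- unitIds(corpus)
  modeOfUnit <- m$mode[match(units, m$unit_id)]

  # --- per-unit pooled distributions and entropies -------------------------
  pooledTP <- list()
  hRows <- list()
  logLines <- c(sprintf("config_hash: %s", hash),
                sprintf("template: %s; convention: %s; pooling: %s; valueKind: %s; nReport: %d; alpha: %g",
                        template, convention, pooling, valueKind, nReport,
                        alpha),
                sprintf("orders: %s", paste(orders, collapse = ",")),
                sprintf("corpus: %d pieces in %d units", nrow(m),
                        length(units)))
  for (ui in seq_along(units)) {
    u <- units[ui]
    pooledTP[[u]] <- list()
    for (v in .VOICES) {
      vls <- linesFor(corpus, unit = u, voice = v)
      pooledTP[[u]][[v]] <- list()
      for (o in orders) {
        ds <- .stage("markov", sprintf("unit %s %s order %d", u, v, o),
                     lapply(vls, lineTP, order = o,
                            convention = convention))
        pooled <- if (all(vapply(ds, nTransitions, numeric(1)) == 0))
          ds[[1]] # every piece too short at this order: empty distribution
        else
          .stage("markov", sprintf("unit %s %s order %d", u, v, o),
                 poolTP(ds, method = pooling,
                        weights = if (pooling == "explicit")
                          rep(1, length(ds)) else NULL))
        pooledTP[[u]][[v]][[as.character(o)]] <- pooled
        hRows[[length(hRows) + 1L]] <- data.frame(
          unit_id = u, voice = v, mode = modeOfUnit[ui], order = o,
          H_bits = if (pooled@nTransitions >= 1)
            conditionalEntropy(pooled, sprintf("%s/%s/order %d", u, v, o))
          else NA_real_, # too short for this order; flagged, not dropped
          stringsAsFactors = FALSE)
      }
      logLines <- c(logLines,
                    sprintf("unit %s %s: %d piece(s), %s tones", u, v,
                            length(vls),
                            sum(vapply(vls, length, integer(1)))))
    }
  }
  if (length(hRows) == 0L) .stopf("stage 'markov' produced no entropies")
  entropies <- .stage("entropy_table", "corpus",
                      entropyTable(do.call(rbind, hRows)))

  # --- per-order PCA -------------------------------------------------------
  pca <- list(); interp <- list(); eigRows <- list(); loadRows <- list()
  for (o in orders) {
    tps <- list(); ci <- list()
    for (ui in seq_along(units)) for (v in .VOICES) {
      d <- pooledTP[[units[ui]]][[v]][[as.character(o)]]
      if (d@nTransitions < 1) next
      tps[[length(tps) + 1L]] <- d
      ci[[length(ci) + 1L]] <- data.frame(unit_id = units[ui], voice = v,
                                          mode = modeOfUnit[ui],
                                          stringsAsFactors = FALSE)
    }
    if (length(tps) < 2L) {
      logLines <- c(logLines, sprintf(
        "order %d: fewer than 2 populated (unit, voice) columns; PCA skipped", o))
      next
    }
    fm <- .stage("components", sprintf("order %d", o),
                 buildFeatureMatrix(tps, do.call(rbind, ci), valueKind))
    p <- .stage("components", sprintf("order %d", o),
                pcaCorrelation(fm, nReport = nReport))
    pca[[as.character(o)]] <- p
    ii <- interpretComponents(p)
    interp[[length(interp) + 1L]] <- cbind(data.frame(order = o), ii)
    eigRows[[length(eigRows) + 1L]] <- data.frame(
      order = o, component = seq_along(p@eigenvalues),
      eigenvalue = p@eigenvalues, variance_pct = p@variancePct,
      cumulative_pct = p@cumulativePct)
    li <- p@columnInfo
    for (k in seq_len(ncol(p@loadings)))
      loadRows[[length(loadRows) + 1L]] <- data.frame(
        order = o, component = k, unit_id = li$unit_id, voice = li$voice,
        mode = li$mode, loading = p@loadings[, k],
        stringsAsFactors = FALSE)
  }
  interp <- if (length(interp)) do.call(rbind, interp) else NULL

  # --- correlation analyses ------------------------------------------------
  corr <- .stage("entropy_stats", "corpus",
                 melodyBassCorrelations(entropies,
                                        splitByMode = template == "study2",
                                        orders = orders, alpha = alpha))
  paired <- NULL
  if (template == "study2")
    paired <- .stage("entropy_stats", "corpus",
                     modePairedCorrelation(entropies, orders = orders,
                                           alpha = alpha))

  # --- outputs -------------------------------------------------------------
  if (!is.null(outDir)) {
    w <- function(df, name) {
      p <- .writeStamped(df, file.path(outDir, name), hash)
      written <<- c(written, p)
    }
    w(entropies, "entropies.csv")
    if (length(eigRows)) {
      w(do.call(rbind, eigRows), "pca_eigenvalues.csv")
      w(do.call(rbind, loadRows), "pca_loadings.csv")
    }
    corrOut <- corr
    if (!is.null(paired)) {
      corrOut$voice <- NA_character_
      paired2 <- paired[, c(setdiff(names(corrOut), "voice"), "voice")]
      corrOut <- rbind(corrOut, paired2[, names(corrOut)])
    }
    w(corrOut, "correlations.csv")
    if (!is.null(interp)) {
      jpath <- file.path(outDir, "interpretation.json")
      jsonlite::write_json(list(config_hash = hash, components = interp),
                           jpath, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
      written <- c(written, jpath)
    }
    if (writeTP) {
      tpl <- tpLongTable(pooledTP)
      w(tpl, "tp_long.csv")
    }
    lpath <- file.path(outDir, "run_log.txt")
    writeLines(logLines, lpath)
    written <- c(written, lpath)
    written <- NULL # success: keep everything
  }

  structure(list(entropies = entropies, pca = pca, interpretation = interp,
                 correlations = corr, pairedCorrelations = paired,
                 pooledTP = pooledTP, config = cfg, configHash = hash),
            class = "tonalEntropyAnalysis")
}

#' @export
print.tonalEntropyAnalysis <- function(x, ...) {
  cat(sprintf("tonalEntropy analysis (%s, %s convention, hash %s)\n",
              x$config$template, x$config$convention, x$configHash))
  cat(sprintf("  %d units, orders %s\n", length(x$config$units),
              paste(x$config$orders, collapse = ",")))
  cat(sprintf("  entropy cells: %d (%d missing)\n", nrow(x$entropies),
              attr(x$entropies, "nMissing")))
  for (o in names(x$pca)) {
    p <- x$pca[[o]]
    cat(sprintf("  order %s PCA: PC1 %.2f%%, %d components > 1\n",
                o, p@variancePct[1], p@nAdopted))
  }
  sig <- x$correlations[which(x$correlations$significant), , drop = FALSE]
  cat(sprintf("  melody-bass correlations: %d of %d significant at alpha = %g\n",
              nrow(sig), nrow(x$correlations), x$config$alpha))
  invisible(x)
}
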