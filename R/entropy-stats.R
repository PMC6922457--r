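#' Assemble the per-unit conditional entropy table
#'
#' Completes the (unit, voice, order) grid from individual entropy records.
#' Combinations without a record (e.g. a unit too short for order 5) are kept
#' as `NA` and flagged, never silently dropped; downstream correlations
#' handle them pairwise.
#'
#' @param records data.frame with columns `unit_id`, `voice`, `mode`,
#'   `order`, `H_bits`, at most one row per (unit, voice, order).
#' @return data.frame covering the full grid (unit order = first appearance),
#'   with attribute `nMissing` giving the number of empty cells.
#' @export
entropyTable <- function(records) {
  need <- c("unit_id", "voice", "mode", "order", "H_bits")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  key <- paste(records$unit_id, records$voice, records$order)
  if (anyDuplicated(key))
    .stopf("duplicate entropy record(s): %s",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  units <- unique(records$unit_id)
  modes <- records$mode[match(units, records$unit_id)]
  grid <- expand.grid(order = sort(unique(records$order)),
                      voice = .VOICES, unit_id = units,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("unit_id", "voice", "order")]
  grid$mode <- modes[match(grid$unit_id, units)]
  idx <- match(paste(grid$unit_id, grid$voice, grid$order), key)
  grid$H_bits <- records$H_bits[idx]
  rownames(grid) <- NULL
  attr(grid, "nMissing") <- sum(is.na(grid$H_bits))
  grid
}

.strengthBand <- function(r) {
  a <- abs(r)
  ifelse(a >= 0.7, "strong",
         ifelse(a >= 0.4, "moderate",
                ifelse(a >= 0.2, "weak", "none")))
}

#' Pearson correlation with exact t-test p-value and strength band
#'
#' The coefficient is computed directly from centred cross-products; the
#' two-sided p-value comes from the t transformation
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Strength bands: strong for `0.7 <= |r| <= 1`, moderate for
#' `0.4 <= |r| < 0.7`, weak for `0.2 <= |r| < 0.4`, none below.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite values.
#' @param label analysis label carried into the result.
#' @param alpha significance level for the `significant` flag.
#' @return One-row data.frame: `label`, `n`, `r`, `p`, `strength`,
#'   `significant`.
#' @export
#' @examples
#' pearsonCor(1:10, 2 * (1:10) + 1)$r  # exactly 1
pearsonCor <- function(x, y, label = "", alpha = 0.05) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) .stopf("correlation needs n >= 3 complete pairs (got %d)", n)
  dx <- x - mean(x); dy <- y - mean(y)
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0)
    .stopf("correlation undefined: zero variance in %s%s",
           if (vx == 0) "x" else "y",
           if (nzchar(label)) paste0(" (", label, ")") else "")
  r <- sum(dx * dy) / sqrt(vx * vy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  data.frame(label = label, n = n, r = r, p = p,
             strength = .strengthBand(r), significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Melody-bass entropy correlations per order
#'
#' Correlates, across aggregation units, the conditional entropy of the
#' melody with that of the bass line, one result per order (and per mode
#' when `splitByMode`). Units missing either voice's entropy at an order are
#' removed pairwise; fewer than 3 complete pairs yields a flagged
#' not-computable row instead of an error.
#'
#' @param tbl an [entropyTable()] result.
#' @param splitByMode correlate separately within major and minor units.
#' @param orders orders to analyse (default: all present).
#' @param alpha significance level.
#' @return data.frame of correlation rows (columns as [pearsonCor()], plus
#'   `analysis`, `order`, `mode`, `computable`).
#' @export
melodyBassCorrelations <- function(tbl, splitByMode = FALSE,
                                   orders = sort(unique(tbl$order)),
                                   alpha = 0.05) {
  modes <- if (splitByMode) c("major", "minor") else "all"
  out <- list()
  for (o in orders) for (md in modes) {
    sub <- tbl[tbl$order == o & (md == "all" | tbl$mode == md), ]
    mel <- sub[sub$voice == "melody", ]
    bas <- sub[sub$voice == "bass", ]
    h <- merge(mel[, c("unit_id", "H_bits")], bas[, c("unit_id", "H_bits")],
               by = "unit_id", suffixes = c("_mel", "_bass"))
    lab <- sprintf("order%d_melody_vs_bass%s", o,
                   if (md == "all") "" else paste0("_", md))
    ok <- is.finite(h$H_bits_mel) & is.finite(h$H_bits_bass)
    if (sum(ok) < 3L) {
      out[[length(out) + 1L]] <- data.frame(
        analysis = "melody_vs_bass", order = o, mode = md, label = lab,
        n = sum(ok), r = NA_real_, p = NA_real_, strength = NA_character_,
        significant = NA, computable = FALSE, stringsAsFactors = FALSE)
      next
    }
    res <- pearsonCor(h$H_bits_mel[ok], h$H_bits_bass[ok], lab, alpha)
    out[[length(out) + 1L]] <- cbind(
      data.frame(analysis = "melody_vs_bass", order = o, mode = md,
                 stringsAsFactors = FALSE),
      res, data.frame(computable = TRUE))
  }
  do.call(rbind, out)
}

#' Major-minor paired entropy correlation per voice and order
#'
#' Pairs every major-mode unit with a minor-mode unit (by shared tonic:
#' C major with C minor, and so on) and correlates their conditional
#' entropies, separately per voice and order. The default pairing strips a
#' trailing `_major` / `_minor` token from the unit ids and matches the
#' remaining tonic labels; supply `pairing` when unit ids follow another
#' scheme.
#'
#' @param tbl an [entropyTable()] result with both modes present.
#' @param pairing named character vector mapping each major `unit_id` to its
#'   minor partner; `NULL` for tonic-based matching.
#' @param orders orders to analyse.
#' @param alpha significance level.
#' @return data.frame of correlation rows per voice and order.
#' @export
modePairedCorrelation <- function(tbl, pairing = NULL,
                                  orders = sort(unique(tbl$order)),
                                  alpha = 0.05) {
  majors <- unique(tbl$unit_id[tbl$mode == "major"])
  minors <- unique(tbl$unit_id[tbl$mode == "minor"])
  if (length(majors) == 0L || length(minors) == 0L)
    .stopf("paired mode analysis needs units of both modes")
  if (is.null(pairing)) {
    tonM <- sub("[_ ]?major$", "", majors)
    tonm <- sub("[_ ]?minor$", "", minors)
    if (anyDuplicated(tonM) || anyDuplicated(tonm) ||
        !setequal(tonM, tonm))
      .stopf("cannot derive a tonic pairing from unit ids; unpaired: %s",
             paste(c(setdiff(tonM, tonm), setdiff(tonm, tonM)),
                   collapse = ", "))
    pairing <- stats::setNames(minors[match(tonM, tonm)], majors)
  } else {
    un <- c(setdiff(majors, names(pairing)), setdiff(minors, pairing))
    if (length(un))
      .stopf("unpaired unit(s): %s", paste(un, collapse = ", "))
  }
  out <- list()
  for (o in orders) for (v in .VOICES) {
    sub <- tbl[tbl$order == o & tbl$voice == v, ]
    hMaj <- sub$H_bits[match(names(pairing), sub$unit_id)]
    hMin <- sub$H_bits[match(unname(pairing), sub$unit_id)]
    lab <- sprintf("order%d_major_vs_minor_%s", o, v)
    ok <- is.finite(hMaj) & is.finite(hMin)
    if (sum(ok) < 3L) {
      out[[length(out) + 1L]] <- data.frame(
        analysis = "major_vs_minor", order = o, mode = "paired",
        voice = v, label = lab, n = sum(ok), r = NA_real_, p = NA_real_,
        strength = NA_character_, significant = NA, computable = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    res <- pearsonCor(hMaj[ok], hMin[ok], lab, alpha)
    out[[length(out) + 1L]] <- cbind(
      data.frame(analysis = "major_vs_minor", order = o, mode = "paired",
                 voice = v, stringsAsFactors = FALSE),
      res, data.frame(computable = TRUE))
  }
  do.call(rbind, out)
}
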