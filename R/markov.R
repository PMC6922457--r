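.emptyTP <- function(order, convention) {
  new("TPDistribution", order = as.integer(order), convention = convention,
      transitions = data.frame(context = character(0), target = integer(0),
                               count = numeric(0), prob = numeric(0),
                               stringsAsFactors = FALSE),
      contexts = data.frame(context = character(0), count = numeric(0),
                            prob = numeric(0), stringsAsFactors = FALSE),
      nTransitions = 0)
}

.tpFromCounts <- function(context, target, count, ord, convention) {
  o <- base::order(context, target, method = "radix")
  context <- context[o]; target <- target[o]; count <- count[o]
  n <- sum(count)
  ctxCount <- rowsum(count, context, reorder = TRUE)
  ctx <- data.frame(context = rownames(ctxCount),
                    count = as.vector(ctxCount),
                    prob = as.vector(ctxCount) / n,
                    stringsAsFactors = FALSE)
  denom <- ctx$count[match(context, ctx$context)]
  tr <- data.frame(context = context, target = as.integer(target),
                   count = count, prob = count / denom,
                   stringsAsFactors = FALSE)
  rownames(tr) <- NULL
  new("TPDistribution", order = as.integer(ord), convention = convention,
      transitions = tr, contexts = ctx, nTransitions = n)
}

#' Estimate an order-n transitional probability distribution
#'
#' Plug-in (maximum likelihood) estimation from observed (context, target)
#' pairs: counts tally every occurrence, conditional probabilities are counts
#' divided by their context total, and the context distribution is the
#' context totals divided by the number of transitions. No smoothing or bias
#' correction is applied — unobserved patterns are absent, not given mass.
#'
#' @param pairs data.frame with columns `context`, `target`, as produced by
#'   [contextTargets()], or a [VoiceLine-class]/pitch vector (then encoded
#'   first at `order`).
#' @param order Markov order, 0..5.
#' @param convention interval encoding convention, see [contextTargets()].
#' @return A [TPDistribution-class]; empty input yields a distribution with
#'   `nTransitions == 0`.
#' @export
#' @examples
#' tp <- estimateTP(contextTargets(c(60L, 62L, 60L, 62L, 60L), 1), order = 1)
#' transitions(tp)
estimateTP <- function(pairs, order, convention = c("window", "chain")) {
  convention <- match.arg(convention)
  if (is(pairs, "VoiceLine") || is.numeric(pairs))
    pairs <- contextTargets(pairs, order, convention)
  stopifnot(is.data.frame(pairs),
            all(c("context", "target") %in% names(pairs)))
  order <- as.integer(order)
  if (nrow(pairs) == 0L) return(.emptyTP(order, convention))
  nOff <- lengths(regmatches(pairs$context[1],
                             gregexpr("-?[0-9]+", pairs$context[1])))
  expected <- if (convention == "window") max(order - 1L, 0L) else order
  if (nOff != expected)
    .stopf("context '%s' has %d offsets; order-%d %s pairs must have %d (mixed orders in input?)",
           pairs$context[1], nOff, order, convention, expected)
  key <- paste(pairs$context, pairs$target, sep = "\t")
  tab <- table(key)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  .tpFromCounts(vapply(parts, `[`, character(1), 1L),
                as.integer(vapply(parts, `[`, character(1), 2L)),
                as.numeric(tab), order, convention)
}

#' Information content of a transitional probability
#'
#' The surprisal of one observed transition, `log2(1/p)` bits. Information
#' content is only defined for observed transitions (p > 0); unobserved
#' patterns are absent from the model rather than infinitely surprising.
#'
#' @param p probability (vectorised), each value in (0, 1].
#' @return Bits, same length as `p`.
#' @export
#' @examples
#' informationContent(c(1, 0.5, 0.25))  # 0 1 2
informationContent <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    .stopf("information content is only defined for probabilities in (0, 1]")
  log2(1 / p)
}

#' Conditional entropy of a transitional probability distribution
#'
#' The context-weighted average surprisal
#' `H = -sum_a P(a) sum_b P(b|a) log2 P(b|a)` in bits, the uncertainty of
#' the distribution. `0 * log 0` is treated as 0 (only observed transitions
#' carry mass in a plug-in distribution, so the sum runs over them).
#'
#' @param d a [TPDistribution-class] with at least one transition.
#' @param label optional identifier (unit/voice/order) used in the error
#'   message for empty distributions.
#' @return Entropy in bits (non-negative scalar).
#' @export
#' @examples
#' tp <- estimateTP(data.frame(context = "()", target = rep(1:8, 3)), 0)
#' conditionalEntropy(tp)  # 3 bits: uniform over 8 targets
conditionalEntropy <- function(d, label = NULL) {
  stopifnot(is(d, "TPDistribution"))
  if (d@nTransitions < 1 || nrow(d@transitions) == 0L)
    .stopf("conditional entropy undefined for an empty distribution%s",
           if (is.null(label)) "" else paste0(" (", label, ")"))
  tr <- d@transitions
  ctxProb <- d@contexts$prob[match(tr$context, d@contexts$context)]
  keep <- tr$prob > 0
  -sum(ctxProb[keep] * tr$prob[keep] * log2(tr$prob[keep]))
}

#' Pool transitional probability distributions across pieces
#'
#' Computes the weighted average of several same-order distributions, e.g.
#' over all movements of a sonata or the prelude/fugue pairs of one key.
#'
#' The default `"by_transitions"` weighting pools raw counts (each piece
#' weighted by its own number of order-n transitions), which makes the
#' pooled object the genuine empirical distribution of the concatenated
#' unit. `"explicit"` uses caller-supplied piece weights: the pooled joint
#' distribution is `sum_m w_m P_m(a) P_m(b|a)` with `w_m` the normalised
#' weights, so each conditional is averaged with weights proportional to
#' `w_m` times the piece's context share.
#'
#' @param ds list of [TPDistribution-class] objects of identical order and
#'   convention.
#' @param weights non-negative numeric, one per distribution; required for
#'   `method = "explicit"`, ignored (and derived from transition counts) for
#'   `"by_transitions"`.
#' @param method pooling scheme.
#' @return A pooled [TPDistribution-class]. Pooled counts are the weighted
#'   joint mass scaled by the total transition count (integral for
#'   `"by_transitions"`).
#' @export
poolTP <- function(ds, weights = NULL,
                   method = c("by_transitions", "explicit")) {
  method <- match.arg(method)
  stopifnot(is.list(ds), length(ds) >= 1L,
            all(vapply(ds, is, logical(1), "TPDistribution")))
  ord <- unique(vapply(ds, function(d) d@order, integer(1)))
  conv <- unique(vapply(ds, function(d) d@convention, character(1)))
  if (length(ord) != 1L || length(conv) != 1L)
    .stopf("cannot pool distributions of mixed order/convention (orders: %s)",
           paste(ord, collapse = ", "))
  ns <- vapply(ds, function(d) d@nTransitions, numeric(1))
  if (method == "by_transitions") {
    weights <- ns
  } else {
    if (is.null(weights) || length(weights) != length(ds))
      .stopf("explicit pooling needs one weight per distribution")
    if (any(weights < 0)) .stopf("weights must be non-negative")
    weights[ns == 0] <- 0 # an empty piece cannot contribute
  }
  if (sum(weights) == 0)
    .stopf("all pooling weights are zero (no transitions to pool)")
  w <- weights / sum(weights)

  ctxs <- character(0); tgts <- integer(0); mass <- numeric(0)
  for (m in seq_along(ds)) {
    if (w[m] == 0) next
    tr <- ds[[m]]@transitions
    jp <- tr$count / ds[[m]]@nTransitions # joint P_m(a, b)
    ctxs <- c(ctxs, tr$context)
    tgts <- c(tgts, tr$target)
    mass <- c(mass, w[m] * jp)
  }
  key <- paste(ctxs, tgts, sep = "\t")
  agg <- rowsum(mass, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\t", fixed = TRUE)
  .tpFromCounts(vapply(parts, `[`, character(1), 1L),
                as.integer(vapply(parts, `[`, character(1), 2L)),
                as.vector(agg) * sum(ns), ord, conv)
}

#' Order-n transitional probability distribution of a voice line
#'
#' Convenience composition of [contextTargets()] and [estimateTP()].
#'
#' @inheritParams contextTargets
#' @return A [TPDistribution-class].
#' @export
lineTP <- function(line, order, convention = c("window", "chain"),
                   quiet = TRUE) {
  convention <- match.arg(convention)
  estimateTP(contextTargets(line, order, convention, quiet = quiet),
             order, convention)
}

#' Export pooled distributions as a long-format table
#'
#' One row per (unit, voice, order, context, target) with count, conditional
#' probability and information content in bits.
#'
#' @param tps named list: `tps[[unit]][[voice]][[as.character(order)]]` is a
#'   [TPDistribution-class], as built by [runAnalysis()].
#' @param meta data.frame with columns `unit_id`, `mode`.
#' @return data.frame with columns `unit_id,voice,order,context,target,count,prob,ic_bits`.
#' @export
tpLongTable <- function(tps, meta = NULL) {
  rows <- list()
  for (u in names(tps)) for (v in names(tps[[u]]))
    for (o in names(tps[[u]][[v]])) {
      d <- tps[[u]][[v]][[o]]
      if (!is(d, "TPDistribution") || nrow(d@transitions) == 0L) next
      tr <- d@transitions
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = u, voice = v, order = d@order,
        context = tr$context, target = tr$target,
        count = tr$count, prob = tr$prob,
        ic_bits = informationContent(tr$prob),
        stringsAsFactors = FALSE)
    }
  if (length(rows) == 0L)
    return(data.frame(unit_id = character(0), voice = character(0),
                      order = integer(0), context = character(0),
                      target = integer(0), count = numeric(0),
                      prob = numeric(0), ic_bits = numeric(0)))
  do.call(rbind, rows)
}
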