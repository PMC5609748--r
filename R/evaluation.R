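# Scoring predicted networks against a gold standard.

.pairKeys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

.edgeKeys <- function(edgeList) {
  e <- edges(edgeList)
  .pairKeys(e$from, e$to)
}

# Enumerate the unordered pair universe as keys.
.universeKeys <- function(gold, universe, pairs) {
  if (!is.null(pairs)) {
    stopifnot(is.data.frame(pairs) || is.matrix(pairs))
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    keys <- .pairKeys(as.character(pairs[[1L]]), as.character(pairs[[2L]]))
    return(unique(keys[as.character(pairs[[1L]]) != as.character(pairs[[2L]])]))
  }
  nodes <- sort(nodeIds(gold))
  if (universe == "all-pairs") {
    if (length(nodes) < 2L) stop("empty pair universe")
    idx <- utils::combn(nodes, 2L)
    return(.pairKeys(idx[1L, ], idx[2L, ]))
  }
  # tf-target: unordered pairs (u, v) with u a regulator, v any node
  tfs <- sort(tfIds(gold))
  if (!length(tfs))
    stop("gold standard has no regulator ids; use universe = \"all-pairs\"")
  keys <- unlist(lapply(tfs, function(tf)
    .pairKeys(tf, setdiff(nodes, tf))), use.names = FALSE)
  unique(keys)
}

#' Confusion counts and rates of a predicted network
#'
#' Compares a predicted edge set with a gold standard over a pair
#' universe. TP are predicted gold edges, FP predicted non-gold pairs,
#' FN gold edges missed, TN the remaining pairs. Rates follow
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' accuracy = (TP+TN)/(TP+TN+FP+FN), specificity = TN/(TN+FP); a rate
#' with zero denominator is NA (undefined), never 0. Matching ignores
#' edge direction (a gold TF -> target pair matches an undirected edge).
#'
#' @param predicted,gold [EdgeList-class] objects over a shared gene
#'   namespace.
#' @param universe `"tf-target"` (default; unordered pairs with at least
#'   one regulator endpoint, the universe implied by a TF-target gold
#'   standard) or `"all-pairs"` (all unordered pairs of gold nodes), or
#'   supply `pairs` explicitly.
#' @param pairs optional two-column data frame / matrix of pairs
#'   overriding `universe`.
#' @return a [ConfusionMetrics-class].
#' @examples
#' gold <- EdgeList(c("a", "a"), c("b", "c"))
#' pred <- EdgeList("a", "b")
#' confusionMetrics(pred, gold, universe = "all-pairs")
#' @export
confusionMetrics <- function(predicted, gold,
                             universe = c("tf-target", "all-pairs"),
                             pairs = NULL) {
  stopifnot(is(predicted, "EdgeList"), is(gold, "EdgeList"))
  universe <- match.arg(universe)
  uni <- .universeKeys(gold, universe, pairs)
  if (!length(uni)) stop("empty pair universe")
  goldKeys <- .edgeKeys(gold)
  outside <- setdiff(goldKeys, uni)
  if (length(outside)) {
    message(length(outside),
            " gold edge(s) outside the pair universe excluded")
    goldKeys <- intersect(goldKeys, uni)
  }
  predKeys <- intersect(.edgeKeys(predicted), uni)
  tp <- length(intersect(predKeys, goldKeys))
  fp <- length(setdiff(predKeys, goldKeys))
  fn <- length(setdiff(goldKeys, predKeys))
  tn <- length(uni) - tp - fp - fn
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  new("ConfusionMetrics",
      tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
      fn = as.integer(fn),
      precision = rate(tp, tp + fp),
      recall = rate(tp, tp + fn),
      accuracy = rate(tp + tn, tp + tn + fp + fn),
      specificity = rate(tn, tn + fp),
      universeSize = length(uni))
}

#' True-positive overlap between reconstructed networks
#'
#' For each network, counts its true-positive edges (predicted edges
#' present in the gold standard) and how many of them are shared with
#' the reference network's true positives — the "common edges"
#' comparison used to ask whether alternative reconstructions add
#' information beyond the best one.
#'
#' @param networks named list of [EdgeList-class] objects.
#' @param gold gold-standard [EdgeList-class].
#' @param reference name of the reference network in `networks`.
#' @return data.frame with columns `label`, `tp`, `commonWithReference`.
#' @export
tpOverlap <- function(networks, gold, reference) {
  stopifnot(length(networks) >= 2L, !is.null(names(networks)))
  if (!reference %in% names(networks))
    stop("unknown reference label: ", reference)
  goldKeys <- .edgeKeys(gold)
  tpSets <- lapply(networks, function(nw) intersect(.edgeKeys(nw), goldKeys))
  refSet <- tpSets[[reference]]
  data.frame(
    label = names(networks),
    tp = vapply(tpSets, length, integer(1)),
    commonWithReference = vapply(tpSets, function(s)
      length(intersect(s, refSet)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
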