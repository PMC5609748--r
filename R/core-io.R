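#' Construct an ExpressionMatrix from a numeric matrix
#'
#' @param values numeric genes x samples matrix.
#' @param geneIds,sampleIds identifiers; default to existing dimnames.
#' @return an [ExpressionMatrix-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, geneIds = rownames(values),
                             sampleIds = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(geneIds), as.character(sampleIds))
  new("ExpressionMatrix", values = values)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' all remaining cells numeric. Rows containing missing or non-numeric
#' cells are dropped (a message reports how many); duplicated gene ids
#' are an error.
#'
#' @param path file path.
#' @param delimiter field separator, `"\t"` (default) or `","`.
#' @return an [ExpressionMatrix-class]; the number of dropped rows is
#'   attached as attribute `"droppedRows"`.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop("expression file must have a gene-id column and at least 2 samples")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, colnames(raw)[-1L]))
  bad <- apply(num, 1L, anyNA)
  if (any(bad))
    message(sum(bad), " row(s) with missing or non-numeric values dropped")
  num <- num[!bad, , drop = FALSE]
  if (nrow(num) < 2L)
    stop("fewer than 2 genes remain after filtering")
  out <- ExpressionMatrix(num)
  attr(out, "droppedRows") <- sum(bad)
  out
}

#' Write an expression matrix as delimited text
#'
#' Values are printed with 15 significant digits so a write/read round
#' trip reproduces them exactly at double precision.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param path output file path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path, delimiter = "\t") {
  stopifnot(is(expr, "ExpressionMatrix"))
  v <- exprValues(expr)
  df <- data.frame(gene = rownames(v),
                   formatC(v, digits = 15, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(v))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Average replicates, log-transform and center an expression matrix
#'
#' Replicate samples are averaged within group on the absolute
#' (untransformed) scale; the log2 transform, when requested, is applied
#' to those averages; finally every gene row is centered to mean zero.
#' Centering is always applied, because the downstream Gaussian model
#' assumes zero-mean observations.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param replicateMap optional named character vector mapping every
#'   sample id to a replicate-group label.
#' @param log2Transform logical; take log2 after replicate averaging.
#'   Requires strictly positive values.
#' @return a centered [ExpressionMatrix-class] (one column per replicate
#'   group when `replicateMap` is given).
#' @examples
#' m <- ExpressionMatrix(matrix(c(1, 2, 3), 2, 3, byrow = TRUE,
#'        dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
#' exprValues(preprocessExpression(m))  # each row becomes (-1, 0, 1)
#' @export
preprocessExpression <- function(expr, replicateMap = NULL,
                                 log2Transform = FALSE) {
  stopifnot(is(expr, "ExpressionMatrix"))
  v <- exprValues(expr)
  if (!is.null(replicateMap)) {
    miss <- setdiff(colnames(v), names(replicateMap))
    if (length(miss))
      stop("samples missing from replicateMap: ", paste(miss, collapse = ", "))
    groups <- replicateMap[colnames(v)]
    glev <- unique(groups)
    v <- vapply(glev, function(g)
      rowMeans(v[, groups == g, drop = FALSE]), numeric(nrow(v)))
    colnames(v) <- glev
  }
  if (log2Transform) {
    if (any(v <= 0))
      stop("log2 transform requires strictly positive values")
    v <- log2(v)
  }
  v <- v - rowMeans(v)
  ExpressionMatrix(v)
}

#' Sample covariance of a centered expression matrix
#'
#' Uses divisor n (not n - 1), matching the multivariate-normal
#' likelihood exp\{-(n/2) tr(S Theta)\} under which the Wishart update is
#' a weighted average of S and the prior scale. The input must already be
#' row-centered; this is enforced, not assumed.
#'
#' @param expr an [ExpressionMatrix-class] or a plain numeric
#'   genes x samples matrix.
#' @return symmetric p x p covariance matrix with gene ids as dimnames.
#' @export
sampleCovariance <- function(expr) {
  v <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  if (any(abs(rowMeans(v)) > 1e-8))
    stop("expression matrix must be centered (row means zero); ",
         "run preprocessExpression() first")
  S <- tcrossprod(v) / ncol(v)
  (S + t(S)) / 2
}

#' Construct an EdgeList from endpoint vectors
#'
#' Pairs are canonicalized (unordered), duplicates collapsed and
#' self-loops dropped with a message.
#'
#' @param from,to character vectors of endpoints.
#' @param weight optional numeric weights (first occurrence kept when a
#'   duplicate pair collapses).
#' @param nodeIds node universe; defaults to the union of endpoints.
#' @param tfIds optional regulator ids (see [EdgeList-class]).
#' @return an [EdgeList-class]; dropped self-loop count attached as
#'   attribute `"droppedSelfLoops"`.
#' @export
EdgeList <- function(from = character(), to = character(), weight = NULL,
                     nodeIds = NULL, tfIds = character()) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  if (is.null(weight)) weight <- rep(NA_real_, length(from))
  loops <- from == to
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  from2 <- pmin(from, to)[!loops]
  to2 <- pmax(from, to)[!loops]
  w <- weight[!loops]
  key <- paste(from2, to2, sep = "\r")
  keep <- !duplicated(key)
  e <- data.frame(from = from2[keep], to = to2[keep], weight = w[keep],
                  stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  if (is.null(nodeIds)) nodeIds <- sort(unique(c(from, to)))
  out <- new("EdgeList", edges = e, nodeIds = as.character(nodeIds),
             tfIds = as.character(tfIds))
  attr(out, "droppedSelfLoops") <- sum(loops)
  out
}

#' Read a two- or three-column edge list
#'
#' Column 1 is the regulator (TF) id, column 2 the target id; an optional
#' numeric third column is read as a weight. Edges are stored unordered.
#'
#' @param path file path; tab- or whitespace-separated.
#' @return an [EdgeList-class] whose `tfIds` slot holds the distinct
#'   first-column ids.
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2L | nf > 3L))
    stop("malformed edge-list line(s): ",
         paste(which(nf < 2L | nf > 3L), collapse = ", "))
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  w <- vapply(fields, function(f)
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else NA_real_,
    numeric(1))
  EdgeList(from, to, weight = w, tfIds = unique(from[from != to]))
}

#' Write an edge list as tab-separated text
#'
#' @param edgeList an [EdgeList-class].
#' @param path output file path.
#' @param writeWeights include the weight column (6 decimal places) when
#'   any weight is present.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(edgeList, path, writeWeights = TRUE) {
  stopifnot(is(edgeList, "EdgeList"))
  e <- edges(edgeList)
  lines <- if (writeWeights && any(!is.na(e$weight)))
    sprintf("%s\t%s\t%.6f", e$from, e$to, e$weight)
  else sprintf("%s\t%s", e$from, e$to)
  writeLines(lines, path)
  invisible(path)
}

#' Restrict two species' expression matrices to their shared genes
#'
#' Genes present in only one matrix are dropped from both; the target
#' species' row order is preserved (the related matrix is reordered to
#' match).
#'
#' @param target,related [ExpressionMatrix-class] objects.
#' @return list with elements `target` and `related`.
#' @export
intersectGenes <- function(target, related) {
  shared <- intersect(geneIds(target), geneIds(related))
  if (length(shared) < 2L)
    stop("fewer than 2 genes shared between the two species")
  list(target = ExpressionMatrix(exprValues(target)[shared, , drop = FALSE]),
       related = ExpressionMatrix(exprValues(related)[shared, , drop = FALSE]))
}
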