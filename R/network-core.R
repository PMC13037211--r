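#' Load an undirected interactome from a two-column edge list
#'
#' Reads a tab-separated edge list of protein identifiers, optionally maps
#' identifiers to official symbols (many-to-one allowed, e.g. Entrez to HGNC),
#' removes self-loops and merges duplicate interactions. Comment lines
#' starting with \code{#} and blank lines are ignored.
#'
#' @param path path to a TSV with exactly two columns and no header (set
#'   \code{header = TRUE} to skip one header row).
#' @param idMap optional named character vector (\code{id -> symbol}) or path
#'   to a two-column TSV mapping file; unmapped rows are dropped with a
#'   logged count.
#' @param header logical; skip the first non-comment row.
#' @return an \linkS4class{InteractionNetwork}; loading diagnostics (dropped
#'   self-loops, merged duplicates, unmapped rows) are in its metadata.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tA", "B\tC"), f)
#' net <- loadEdgeList(f)
#' networkEdgeCount(net) # 2: the reversed duplicate is merged
loadEdgeList <- function(path, idMap = NULL, header = FALSE) {
  if (!file.exists(path)) stopf("edge list file not found: %s", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineNo <- which(keep)
  rows <- raw[keep]
  if (header) {
    if (length(rows) == 0L) stopf("edge list %s has no rows", path)
    rows <- rows[-1L]
    lineNo <- lineNo[-1L]
  }
  if (length(rows) == 0L) stopf("edge list %s has no data rows", path)
  fields <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stopf(
      "malformed edge list row at line %d of %s: expected 2 tab-separated columns, got %d",
      lineNo[bad[1L]], path, lengths(fields)[bad[1L]]
    )
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  nUnmapped <- 0L
  if (!is.null(idMap)) {
    if (is.character(idMap) && is.null(names(idMap)) && length(idMap) == 1L) {
      idMap <- readIdMap(idMap)
    }
    ma <- idMap[a]
    mb <- idMap[b]
    ok <- !is.na(ma) & !is.na(mb)
    nUnmapped <- sum(!ok)
    if (nUnmapped > 0L) hnpLog("dropped %d edge row(s) with unmapped identifier(s)", nUnmapped)
    a <- unname(ma[ok])
    b <- unname(mb[ok])
    if (length(a) == 0L) stopf("no edges remain after identifier mapping")
  }
  InteractionNetwork(
    data.frame(a = a, b = b, stringsAsFactors = FALSE),
    metadata = list(source = path, unmappedRows = nUnmapped)
  )
}

#' Read a two-column identifier-mapping table
#'
#' @param path TSV with columns (source id, symbol); comment lines starting
#'   with \code{#} are ignored. Many-to-one mappings are allowed; a source id
#'   mapped to several symbols keeps the first occurrence with a warning.
#' @return named character vector \code{id -> symbol}.
#' @export
readIdMap <- function(path) {
  if (!file.exists(path)) stopf("id map file not found: %s", path)
  tab <- utils::read.delim(path,
    header = FALSE, comment.char = "#",
    colClasses = "character"
  )
  if (ncol(tab) != 2L) stopf("id map %s must have exactly 2 columns", path)
  if (anyDuplicated(tab[[1L]])) {
    warning("duplicate source ids in map; keeping first occurrence", call. = FALSE)
    tab <- tab[!duplicated(tab[[1L]]), ]
  }
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Unweighted shortest-path lengths between two node sets
#'
#' Breadth-first-search shortest paths on the interactome. Unreachable pairs
#' are returned as \code{Inf}, an explicit marker that downstream metrics
#' exclude rather than treat as a distance.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param sources,targets nonempty character vectors of symbols present in
#'   the network (see [restrictToNetwork()] to pre-filter).
#' @return numeric matrix, \code{sources} x \code{targets}, of integer path
#'   lengths with \code{Inf} marking unreachable pairs.
#' @export
shortestPathLengths <- function(net, sources, targets) {
  sources <- .asSymbols(sources)
  targets <- .asSymbols(targets)
  if (length(sources) == 0L || length(targets) == 0L) {
    stopf("sources and targets must be nonempty")
  }
  nodes <- proteins(net)
  out <- setdiff(c(sources, targets), nodes)
  if (length(out)) {
    stopf("node(s) not in network: %s", paste(utils::head(out, 5), collapse = ", "))
  }
  d <- igraph::distances(net@graph, v = sources, to = targets, algorithm = "unweighted")
  dimnames(d) <- list(sources, targets)
  d
}

#' First-degree neighbors of a node set
#'
#' Union of the adjacency lists of \code{H}; may overlap \code{H} itself.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param H character vector of symbols (or a
#'   \linkS4class{WeightedProteinSet}); must lie in the network.
#' @return character vector of neighbor symbols (empty for empty \code{H}).
#' @export
neighborsOf <- function(net, H) {
  H <- .asSymbols(H)
  if (length(H) == 0L) return(character(0))
  out <- setdiff(H, proteins(net))
  if (length(out)) stopf("node(s) not in network: %s", paste(utils::head(out, 5), collapse = ", "))
  adj <- igraph::adjacent_vertices(net@graph, v = H)
  unique(unlist(lapply(adj, function(v) v$name), use.names = FALSE))
}

#' Partition network nodes into degree bins for null sampling
#'
#' Starts from log2-spaced degree intervals \code{[2^k, 2^(k+1))} (degree 0,
#' possible after self-loop removal, forms its own initial interval) and
#' merges any bin holding fewer than \code{minBinSize} nodes into the
#' next-higher interval (the top bin merges downward). Deterministic for a
#' fixed network.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param minBinSize minimum nodes per bin after merging (default 100, the
#'   scale appropriate for genome-wide interactomes; lower it for small
#'   networks).
#' @return a \linkS4class{DegreeBinning}.
#' @export
buildDegreeBins <- function(net, minBinSize = 100L) {
  minBinSize <- as.integer(minBinSize)
  if (minBinSize < 1L) stopf("minBinSize must be >= 1")
  deg <- degreeOf(net)
  if (minBinSize > length(deg)) stopf("minBinSize (%d) exceeds network size (%d)", minBinSize, length(deg))
  # initial log2 class: -1 for degree 0, else floor(log2(degree))
  cls <- ifelse(deg == 0L, -1L, floor(log2(pmax(deg, 1L))))
  levelsAsc <- sort(unique(cls))
  # merge sparse classes into the next-higher class; top class merges down
  groups <- lapply(levelsAsc, function(l) names(deg)[cls == l])
  ranges <- lapply(levelsAsc, function(l) {
    d <- deg[cls == l]
    c(min(d), max(d))
  })
  i <- 1L
  while (i <= length(groups)) {
    if (length(groups[[i]]) < minBinSize) {
      if (i < length(groups)) {
        groups[[i + 1L]] <- c(groups[[i]], groups[[i + 1L]])
        ranges[[i + 1L]] <- c(min(ranges[[i]][1L], ranges[[i + 1L]][1L]),
                              max(ranges[[i]][2L], ranges[[i + 1L]][2L]))
        groups[[i]] <- NULL
        ranges[[i]] <- NULL
      } else if (i > 1L) {
        groups[[i - 1L]] <- c(groups[[i - 1L]], groups[[i]])
        ranges[[i - 1L]] <- c(min(ranges[[i - 1L]][1L], ranges[[i]][1L]),
                              max(ranges[[i - 1L]][2L], ranges[[i]][2L]))
        groups[[i]] <- NULL
        ranges[[i]] <- NULL
        i <- i - 1L
      } else {
        stopf("cannot satisfy minBinSize = %d with %d nodes", minBinSize, length(deg))
      }
    } else {
      i <- i + 1L
    }
  }
  binOf <- integer(length(deg))
  names(binOf) <- names(deg)
  for (b in seq_along(groups)) binOf[groups[[b]]] <- b
  methods::new("DegreeBinning",
    bins = groups, binOf = binOf,
    binRanges = do.call(rbind, ranges), minBinSize = minBinSize
  )
}

#' Restrict a weighted protein set to the nodes of a network
#'
#' Members absent from the interactome are dropped (logged and recorded in
#' the result's metadata); proximity metrics are undefined for off-network
#' nodes.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param S a \linkS4class{WeightedProteinSet}.
#' @return the restricted \linkS4class{WeightedProteinSet}; its metadata
#'   holds \code{nDropped} and \code{dropped}.
#' @export
restrictToNetwork <- function(net, S) {
  stopifnot(methods::is(S, "WeightedProteinSet"))
  w <- proteinWeights(S)
  inNet <- names(w) %in% proteins(net)
  dropped <- names(w)[!inNet]
  if (all(!inNet)) stopf("no member of the set is present in the network; metrics undefined")
  if (length(dropped)) hnpLog("restrictToNetwork: dropped %d member(s) absent from the network", length(dropped))
  md <- S@metadata
  md$nDropped <- length(dropped)
  md$dropped <- dropped
  WeightedProteinSet(w[inNet], label = setLabel(S), metadata = md)
}
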