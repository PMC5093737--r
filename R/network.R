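#' Gene interaction network
#'
#' An undirected, unweighted graph over gene identifiers, stored as a sorted
#' node vector, a canonical two-column edge matrix and a symmetric adjacency
#' list. Gene identifiers are treated as case-sensitive opaque strings; no
#' symbol normalization is performed. Self-loops are dropped (their endpoint
#' is kept as an isolated node) and duplicate or reciprocal edges are
#' collapsed.
#'
#' @param edges two-column character matrix or data frame of edge endpoints.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes; endpoints of `edges` are always included.
#' @return An object of class `gene_network` with components `nodes` (sorted
#'   character vector), `edges` (two-column character matrix, each row sorted,
#'   rows deduplicated and ordered) and `adjacency` (named list of sorted
#'   neighbor vectors, one per node).
#' @examples
#' net <- gene_network(rbind(c("TP53", "MDM2"), c("TP53", "ATM")))
#' net$adjacency$TP53
#' @export
gene_network <- function(edges = NULL, nodes = character()) {
  if (is.null(edges)) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("edges must have exactly two columns")
    storage.mode(em) <- "character"
  }
  nodes <- unique(c(as.character(nodes), as.vector(em)))
  # drop self-loops, keep their endpoints as isolated nodes
  keep <- em[, 1L] != em[, 2L]
  em <- em[keep, , drop = FALSE]
  if (nrow(em)) {
    swap <- em[, 1L] > em[, 2L]
    em[swap, ] <- em[swap, c(2L, 1L), drop = FALSE]
    em <- unique(em)
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  nodes <- sort(nodes)
  adjacency <- lapply(stats::setNames(nodes, nodes), function(x) character())
  if (nrow(em)) {
    nb <- c(split(em[, 2L], factor(em[, 1L], levels = nodes)),
            split(em[, 1L], factor(em[, 2L], levels = nodes)))
    for (v in nodes) {
      a <- c(nb[[v]], nb[[length(nodes) + match(v, nodes)]])
      adjacency[[v]] <- sort(unique(a))
    }
  }
  colnames(em) <- c("from", "to")
  structure(list(nodes = nodes, edges = em, adjacency = adjacency),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

validate_network <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (any(net$edges[, 1L] == net$edges[, 2L])) stop("self-loop present")
  if (anyDuplicated(paste(net$edges[, 1L], net$edges[, 2L]))) {
    stop("duplicate edge present")
  }
  if (!all(as.vector(net$edges) %in% net$nodes)) {
    stop("edge endpoint missing from node set")
  }
  for (v in names(net$adjacency)) {
    for (u in net$adjacency[[v]]) {
      if (!(v %in% net$adjacency[[u]])) stop("adjacency not symmetric")
    }
  }
  invisible(net)
}

#' Read a gene network from an edge-list file
#'
#' Accepts a two-column TSV edge list (`fmt = "edge_tsv"`) or a three-column
#' SIF file (`fmt = "sif"`, the middle interaction-type column is ignored).
#' Lines starting with `#` are comments. Self-loop rows contribute their gene
#' as an isolated node but no edge; duplicate and reciprocal edges are
#' collapsed. The number of dropped records is reported via `message()`.
#'
#' @param path file path.
#' @param fmt `"edge_tsv"` or `"sif"`.
#' @return A [gene_network()].
#' @export
read_network <- function(path, fmt = c("edge_tsv", "sif")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  want <- if (fmt == "sif") 3L else 2L
  parts <- strsplit(lines[idx], "[\t ]+")
  nf <- lengths(parts)
  bad <- which(nf != want)
  if (length(bad)) {
    stop(sprintf("malformed network row at line %d: expected %d fields, got %d",
                 idx[bad[1L]], want, nf[bad[1L]]))
  }
  if (!length(parts)) stop("empty network: no edges in ", path)
  em <- do.call(rbind, parts)
  if (fmt == "sif") em <- em[, c(1L, 3L), drop = FALSE]
  n_raw <- nrow(em)
  net <- gene_network(em)
  dropped <- n_raw - nrow(net$edges)
  if (dropped > 0L) {
    message(sprintf("read_network: dropped %d self-loop/duplicate record(s)",
                    dropped))
  }
  if (length(net$nodes) == 0L) stop("empty network: no nodes in ", path)
  net
}

#' Write a gene network as a two-column TSV edge list
#'
#' Isolated nodes are written as self-referencing comment lines so that
#' reading the file back reproduces the same node and edge sets.
#'
#' @param net a [gene_network()].
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#from\tto", con)
  if (nrow(net$edges)) {
    writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), con)
  }
  iso <- setdiff(net$nodes, unique(as.vector(net$edges)))
  # a self-loop row keeps the gene in the node universe without adding an edge
  if (length(iso)) writeLines(paste(iso, iso, sep = "\t"), con)
  invisible(path)
}

#' Connected components of a gene network
#'
#' Breadth-first labelling; used by the generators and in validity checks.
#'
#' @param net a [gene_network()].
#' @return Named integer vector of component labels, one per node.
#' @export
network_components <- function(net) {
  comp <- stats::setNames(rep(NA_integer_, length(net$nodes)), net$nodes)
  k <- 0L
  for (v in net$nodes) {
    if (!is.na(comp[[v]])) next
    k <- k + 1L
    queue <- v
    comp[[v]] <- k
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- net$adjacency[[u]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

is_connected <- function(net, genes = NULL) {
  comp <- network_components(net)
  if (!is.null(genes)) {
    sub <- subgraph(net, genes)
    comp <- network_components(sub)
  }
  length(unique(comp)) <= 1L
}

subgraph <- function(net, genes) {
  keep <- net$edges[, 1L] %in% genes & net$edges[, 2L] %in% genes
  gene_network(net$edges[keep, , drop = FALSE], nodes = genes)
}
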