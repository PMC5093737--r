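#' Small subnetwork
#'
#' A connected gene set of size 2..max grown around a seed gene, carrying its
#' mutual exclusivity score (`mes`) and rank-normalized score (`rmes`) once
#' computed.
#'
#' @param genes character vector of member genes (at least 2).
#' @param seed the seed gene the subnetwork was grown from.
#' @param mes,rmes optional scores.
#' @param net optional [gene_network()]; when given, the members must induce
#'   a connected subgraph containing `seed`.
#' @return An object of class `small_subnetwork`.
#' @export
small_subnetwork <- function(genes, seed = genes[[1L]], mes = NA_real_,
                             rmes = NA_real_, net = NULL) {
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("a small subnetwork needs at least 2 genes")
  if (anyDuplicated(genes)) stop("duplicate genes in subnetwork")
  if (!seed %in% genes) stop("seed must be a member of the subnetwork")
  if (!is.null(net)) {
    if (!all(genes %in% net$nodes)) stop("subnetwork gene absent from network")
    if (!is_connected(net, genes)) stop("subnetwork is not connected")
  }
  structure(list(genes = genes, seed = seed, mes = mes, rmes = rmes),
            class = "small_subnetwork")
}

#' @export
print.small_subnetwork <- function(x, ...) {
  cat(sprintf("small_subnetwork [%s] seed=%s mes=%s rmes=%s\n",
              paste(x$genes, collapse = ","), x$seed,
              format(x$mes), format(x$rmes)))
  invisible(x)
}

#' Number of subnetwork genes altered in one sample
#'
#' `m(s, V)`: how many genes of the subnetwork `V` are altered in sample `s`.
#' It equals 1 for every contributing sample of a perfectly mutually
#' exclusive pattern and `|V|` when all subnetwork genes are altered in all
#' samples. The count is always taken on the full `V`, independent of any
#' sample-removal state used while accumulating the score.
#'
#' @param sample a sample identifier present in `mat`.
#' @param V character vector of gene identifiers present in `mat`.
#' @param mat an [alteration_matrix()].
#' @return Integer in `0..length(V)`.
#' @export
count_mutated <- function(sample, V, mat) {
  if (!sample %in% colnames(mat)) stop("unknown sample: ", sample)
  miss <- setdiff(V, rownames(mat))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  sum(unclass(mat)[V, sample])
}

# canonical processing order of subnetwork genes: descending alteration
# count over the whole matrix, ties broken lexicographically by identifier
mes_gene_order <- function(V, mat) {
  counts <- rowSums(unclass(mat)[V, , drop = FALSE])
  V[order(-counts, V)]
}

#' Mutual exclusivity score of a small subnetwork
#'
#' Each sample altered in at least one subnetwork gene contributes exactly
#' once, with weight `1 / m(s, V)` — inversely related to the number of
#' subnetwork genes altered in it. Genes are processed in order of
#' decreasing alteration count; gene `v` collects the weights of all
#' still-pending samples altered in `v` (those samples are then removed from
#' the pending set) and contributes the square root of the collected mass.
#' The per-gene square root rewards subnetworks whose genes are altered in
#' approximately the same number of samples. See the package vignette for
#' the exact functional form and its rationale.
#'
#' @param sn a [small_subnetwork()] or a character vector of at least two
#'   genes.
#' @param mat an [alteration_matrix()] containing all subnetwork genes.
#' @return Non-negative scalar MES.
#' @seealso [mes_oracle()] for the literal reference implementation,
#'   [score_subnetwork()] for a per-gene breakdown.
#' @export
mes <- function(sn, mat) {
  V <- if (inherits(sn, "small_subnetwork")) sn$genes else as.character(sn)
  if (length(V) < 2L) stop("MES is defined for subnetworks of >= 2 genes")
  miss <- setdiff(V, rownames(mat))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  Vs <- sort(V)  # index order == lexicographic order for the C++ tie-break
  gs <- lapply(Vs, function(g) which(unclass(mat)[g, ] == 1L) - 1L)
  cpp_mes_single(gs, ncol(mat))
}

#' Per-gene MES breakdown of a small subnetwork
#'
#' Debug view of the score: the processing order, each gene's accumulated
#' sample weight (its "bucket") and square-root contribution.
#'
#' @inheritParams mes
#' @return A data frame with columns `gene`, `n_altered`, `bucket`,
#'   `contribution`, in processing order; the summed `contribution` equals
#'   [mes()].
#' @export
score_subnetwork <- function(sn, mat) {
  V <- if (inherits(sn, "small_subnetwork")) sn$genes else as.character(sn)
  ord <- mes_gene_order(V, mat)
  m <- unclass(mat)[V, , drop = FALSE]
  mV <- colSums(m)
  pending <- colnames(mat)[mV > 0L]
  rows <- lapply(ord, function(v) {
    sv <- intersect(pending, colnames(mat)[m[v, ] == 1L])
    pending <<- setdiff(pending, sv)
    bucket <- sum(1 / mV[sv])
    data.frame(gene = v, n_altered = sum(m[v, ]), bucket = bucket,
               contribution = sqrt(bucket))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Literal reference implementation of the mutual exclusivity score
#'
#' An unoptimized transcription of the sample-accounting rules with explicit
#' sample sets and explicit removal, kept independent of the compiled
#' implementation so the two can be checked against each other.
#'
#' @param V character vector of at least two genes.
#' @param mat an [alteration_matrix()].
#' @return Non-negative scalar MES.
#' @export
mes_oracle <- function(V, mat) {
  V <- as.character(V)
  if (length(V) < 2L) stop("MES is defined for subnetworks of >= 2 genes")
  # S: samples pending to contribute — initially every sample altered in at
  # least one gene of V
  S <- character()
  for (s in colnames(mat)) {
    altered_in_V <- FALSE
    for (v in V) if (unclass(mat)[v, s] == 1L) altered_in_V <- TRUE
    if (altered_in_V) S <- c(S, s)
  }
  # m(s, V) fixed on the full V
  m_sV <- vapply(colnames(mat), function(s) count_mutated(s, V, mat), 0)
  total <- 0
  for (v in mes_gene_order(V, mat)) {
    bucket <- 0
    used <- character()
    for (s in S) {
      if (unclass(mat)[v, s] == 1L) {
        bucket <- bucket + 1 / m_sV[[s]]
        used <- c(used, s)   # a sample can only contribute once
      }
    }
    S <- setdiff(S, used)
    total <- total + sqrt(bucket)
  }
  total
}

# MES with a caller-imposed processing order (internal; used by property
# tests that hold the order fixed while perturbing the matrix)
mes_fixed_order <- function(V_ordered, mat) {
  m <- unclass(mat)[V_ordered, , drop = FALSE]
  mV <- colSums(m)
  pending <- which(mV > 0L)
  total <- 0
  for (i in seq_along(V_ordered)) {
    sv <- pending[m[i, pending] == 1L]
    total <- total + sqrt(sum(1 / mV[sv]))
    pending <- setdiff(pending, sv)
  }
  total
}

#' Rank-normalize MES values within a batch
#'
#' MES values are ranked and mapped to `[0, 1]`: the highest-MES subnetwork
#' gets `rmes = 1` (most evidence for mutual exclusivity) and the lowest
#' `rmes = 0`, via `(ascending rank - 1) / (N - 1)` with tied values
#' receiving the mean of their ascending ranks. A single-element batch gets
#' `rmes = 1`.
#'
#' @param batch list of [small_subnetwork()] objects with `mes` set.
#' @return The same list with `rmes` filled in.
#' @export
rank_mes <- function(batch) {
  if (!length(batch)) stop("rank_mes: empty batch")
  mvals <- vapply(batch, function(sn) sn$mes, 0)
  if (anyNA(mvals)) stop("rank_mes: unset mes in batch")
  rm <- rmes_from_mes(mvals)
  for (i in seq_along(batch)) batch[[i]]$rmes <- rm[[i]]
  batch
}

rmes_from_mes <- function(mvals) {
  n <- length(mvals)
  if (n == 1L) return(1)
  (rank(mvals, ties.method = "average") - 1) / (n - 1)
}
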