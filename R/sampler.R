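#' Seed genes for subnetwork growth
#'
#' Seed genes are all genes altered in at least one sample that are also
#' present in the network; growth starts from every seed in every iteration.
#' Altered genes missing from the network can never enter a subnetwork and
#' are reported via `message()`.
#'
#' @param net a [gene_network()].
#' @param mat an [alteration_matrix()].
#' @return Sorted character vector of seed genes.
#' @export
eligible_seeds <- function(net, mat) {
  altered <- rownames(mat)[rowSums(mat) > 0L]
  off <- setdiff(altered, net$nodes)
  if (length(off)) {
    message(sprintf("eligible_seeds: %d altered gene(s) absent from network",
                    length(off)))
  }
  seeds <- sort(intersect(altered, net$nodes))
  if (!length(seeds)) stop("no usable seed genes")
  seeds
}

#' Grow one small subnetwork from a seed gene
#'
#' Starting from the seed, repeatedly draws one frontier gene (a non-member
#' neighbor of the current members) with probability proportional to its
#' current gene score, until the target size is reached or the frontier is
#' empty. If every frontier gene has score zero the draw is uniform, so
#' growth never deadlocks. Returns `NULL` when the seed is isolated
#' (subnetworks need at least two genes); a stalled subnetwork of
#' intermediate size is still returned.
#'
#' @param seed seed gene, must be a network node.
#' @param scores named numeric vector of current gene scores (names must
#'   cover the network nodes).
#' @param net a [gene_network()].
#' @param size target number of genes (>= 2).
#' @return A [small_subnetwork()] or `NULL`. Uses R's RNG stream; seed it
#'   with [set.seed()] for reproducibility.
#' @export
grow_subnetwork <- function(seed, scores, net, size) {
  stopifnot(size >= 2L)
  if (!seed %in% net$nodes) stop("seed not in network: ", seed)
  members <- seed
  while (length(members) < size) {
    frontier <- setdiff(sort(unique(unlist(net$adjacency[members],
                                           use.names = FALSE))), members)
    if (!length(frontier)) break
    w <- scores[frontier]
    if (sum(w) <= 0) w <- rep(1, length(frontier))
    pick <- frontier[sample.int(length(frontier), 1L, prob = w)]
    members <- c(members, pick)
  }
  if (length(members) < 2L) return(NULL)
  small_subnetwork(members, seed = seed)
}

#' Subnetwork size used at a given iteration
#'
#' Sizes are cycled across iterations (default cycle 3,4,5,6) so gene sets
#' of different sizes are evaluated for mutual exclusivity; all subnetworks
#' within one iteration share the size.
#'
#' @param iteration zero-based iteration index.
#' @param sizes non-empty integer vector of sizes (each >= 2).
#' @return One element of `sizes`.
#' @export
iteration_size <- function(iteration, sizes = c(3L, 4L, 5L, 6L)) {
  if (!length(sizes)) stop("sizes must be non-empty")
  sizes[[(iteration %% length(sizes)) + 1L]]
}
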