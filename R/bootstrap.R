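#' Resample tumor samples with replacement
#'
#' Draws exactly as many sample columns as the input has, i.i.d. with
#' replacement; duplicated samples receive suffixed unique identifiers
#' (`S1`, `S1.1`, ...). Uses R's RNG stream.
#'
#' @param mat an [alteration_matrix()] with at least one sample.
#' @return A resampled [alteration_matrix()] with the same gene rows.
#' @export
resample_samples <- function(mat) {
  n <- ncol(mat)
  if (n < 1L) stop("resample_samples: no samples")
  idx <- sample.int(n, n, replace = TRUE)
  out <- unclass(mat)[, idx, drop = FALSE]
  colnames(out) <- make.unique(colnames(mat)[idx])
  as_altmat(out)
}

#' Bootstrap support ranking of the prioritization
#'
#' Runs the full prioritization on `B` sample-level bootstrap resamples and
#' re-ranks genes by the minimal rank threshold at which they attain the
#' required bootstrap support: for thresholds `t = 1, 2, ...`, the support
#' `support(g, t)` is the fraction of bootstrap runs in which gene `g` was
#' ranked at or better than `t`; a gene's key is the smallest `t` at which
#' its support reaches `support` (default 95%). Genes are ordered by
#' ascending key — the top gene attains the required support at the
#' strictest threshold — with ties broken by higher support at that key,
#' then lexicographically. Genes that never attain the support are omitted.
#'
#' Replicate RNG seeds are derived deterministically from
#' `params$rng_seed`, so the whole procedure is reproducible.
#'
#' @param net a [gene_network()].
#' @param mat an [alteration_matrix()].
#' @param params an [ssame_params()].
#' @param B number of bootstrap replicates (default `params$bootstrap_B`).
#' @param support required support fraction
#'   (default `params$bootstrap_support`).
#' @return A data frame of class `ranked_genes` with columns `gene`, `rank`,
#'   `bootstrap_threshold` (the key `t`) and `bootstrap_support` (support at
#'   the key); attribute `support_matrix` holds the full gene-by-threshold
#'   support surface.
#' @export
bootstrap_rank <- function(net, mat, params = ssame_params(),
                           B = params$bootstrap_B,
                           support = params$bootstrap_support) {
  stopifnot(B >= 1L)
  set.seed(params$rng_seed)
  child_seeds <- sample.int(.Machine$integer.max, B)
  ranks <- NULL
  for (b in seq_len(B)) {
    set.seed(child_seeds[[b]])
    mb <- resample_samples(mat)
    pb <- params
    pb$rng_seed <- child_seeds[[b]]
    fit <- suppressMessages(run_ssa_me(net, mb, pb))
    rk <- fit$ranking
    if (is.null(ranks)) {
      genes <- sort(rk$gene)
      ranks <- matrix(Inf, nrow = length(genes), ncol = B,
                      dimnames = list(genes, NULL))
    }
    # a gene absent from a run's output keeps rank +Inf for that run
    ranks[rk$gene, b] <- rk$rank
  }
  support_scan(ranks, support)
}

# minimal-rank-threshold scan over a gene x replicate rank matrix
# (Inf marks a gene absent from that replicate's output)
support_scan <- function(ranks, support) {
  genes <- rownames(ranks)
  thresholds <- seq_len(length(genes))
  supp <- vapply(thresholds,
                 function(t) rowMeans(ranks <= t), numeric(length(genes)))
  supp <- matrix(supp, nrow = length(genes),
                 dimnames = list(genes, thresholds))
  key <- apply(supp, 1L, function(s) {
    hit <- which(s >= support)
    if (length(hit)) hit[[1L]] else NA_integer_
  })
  sel <- !is.na(key)
  g <- genes[sel]
  k <- key[sel]
  s_at_key <- supp[cbind(which(sel), k)]
  ord <- order(k, -s_at_key, g)
  out <- data.frame(gene = g[ord], rank = seq_along(g),
                    bootstrap_threshold = unname(k[ord]),
                    bootstrap_support = unname(s_at_key[ord]))
  attr(out, "support_matrix") <- supp
  class(out) <- c("ranked_genes", "data.frame")
  out
}
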