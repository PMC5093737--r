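#' Gene score state
#'
#' Per-gene bookkeeping of a reinforced run: the current score `g_i` in
#' `[0, 1]`, the running maximum, the convergence iteration (first iteration
#' from which the score stays at or above 99% of its final maximum) and the
#' up-to-5 highest-MES subnetworks the gene was ever part of.
#'
#' @param genes character vector of genes tracked (network genes, plus any
#'   altered genes absent from the network).
#' @param score initial score per gene (default 0.5 everywhere).
#' @return An object of class `gene_score_state`.
#' @export
gene_score_state <- function(genes, score = 0.5) {
  genes <- as.character(genes)
  score <- rep_len(score, length(genes))
  stopifnot(all(score >= 0 & score <= 1))
  structure(list(genes = genes,
                 score = stats::setNames(score, genes),
                 max_score = stats::setNames(score, genes),
                 last_below = stats::setNames(rep(0L, length(genes)), genes),
                 convergence_iter = stats::setNames(rep(1L, length(genes)),
                                                    genes),
                 top_subnetworks = stats::setNames(
                   vector("list", length(genes)), genes),
                 iteration = 0L),
            class = "gene_score_state")
}

#' @export
print.gene_score_state <- function(x, ...) {
  cat(sprintf("gene_score_state: %d genes, iteration %d, %d score(s) > 0.9\n",
              length(x$genes), x$iteration, sum(x$score > 0.9)))
  invisible(x)
}

#' One reinforced-learning score update
#'
#' Applies `score' = min(1, f * score + r * best)` to every tracked gene,
#' where `best` is the highest rMES over the batch subnetworks containing
#' the gene and 0 for genes in no subnetwork (their score therefore decays).
#' Scores exceeding 1 are topped off at 1. Running maxima, convergence
#' bookkeeping and the per-gene top-5 retained subnetworks are updated.
#'
#' `run_ssa_me()` performs this update in compiled code; this R
#' implementation is the reference for unit tests and single-step use.
#'
#' @param state a [gene_score_state()].
#' @param batch list of [small_subnetwork()] with `rmes` set (may be empty).
#' @param params an [ssame_params()].
#' @return The updated state, with `iteration` advanced by one.
#' @export
update_scores <- function(state, batch, params) {
  f <- params$forgetfulness
  r <- params$reinforcement
  best <- stats::setNames(numeric(length(state$genes)), state$genes)
  for (sn in batch) {
    if (is.na(sn$rmes)) stop("update_scores: unset rmes in batch")
    g <- intersect(sn$genes, state$genes)
    best[g] <- pmax(best[g], sn$rmes)
  }
  state$score <- pmin(f * state$score + r * best, 1)  # top-off at 1
  state$iteration <- state$iteration + 1L
  state$max_score <- pmax(state$max_score, state$score)
  below <- state$score < 0.99 * state$max_score
  state$last_below[below] <- state$iteration
  state$convergence_iter <- state$last_below + 1L
  for (sn in batch) {
    for (g in intersect(sn$genes, state$genes)) {
      state$top_subnetworks[[g]] <-
        keep_top5(state$top_subnetworks[[g]], sn)
    }
  }
  state
}

# bounded best-of list keyed on (mes desc, sorted gene list asc); an
# incoming subnetwork displaces the worst entry only when strictly better
keep_top5 <- function(lst, sn, k = 5L) {
  key <- function(x) list(x$mes, paste(sort(x$genes), collapse = "\r"))
  better <- function(a, b) {  # TRUE when a strictly better than b
    ka <- key(a); kb <- key(b)
    ka[[1L]] > kb[[1L]] || (ka[[1L]] == kb[[1L]] && ka[[2L]] < kb[[2L]])
  }
  if (length(lst) < k) {
    lst[[length(lst) + 1L]] <- sn
  } else {
    worst <- 1L
    for (i in seq_along(lst)) if (better(lst[[worst]], lst[[i]])) worst <- i
    if (better(sn, lst[[worst]])) lst[[worst]] <- sn
  }
  ord <- order(-vapply(lst, function(x) x$mes, 0),
               vapply(lst, function(x) paste(sort(x$genes), collapse = "\r"),
                      ""))
  lst[ord]
}

#' Run the full reinforced subnetwork-sampling prioritization
#'
#' Initializes every gene score to 0.5, then iterates: pick the iteration's
#' subnetwork size, grow one subnetwork per seed gene (neighbor selection
#' proportional to current scores), score each subnetwork for mutual
#' exclusivity (MES), rank-normalize within the iteration's batch (rMES) and
#' update gene scores with the forgetfulness/reinforcement rule. Stops at
#' `params$iterations` or earlier when the top-`stop_top_k` gene set is
#' stable for `stop_patience` iterations. The entire run is driven by
#' `params$rng_seed` and is exactly reproducible.
#'
#' Altered genes absent from the network are tracked but can never join a
#' subnetwork, so their scores simply decay from 0.5; a startup message
#' reports their count.
#'
#' @param net a [gene_network()].
#' @param mat an [alteration_matrix()].
#' @param params an [ssame_params()].
#' @return A list of class `ssame_fit` with components `state` (a
#'   [gene_score_state()] augmented with `iter_stats`, a per-iteration data
#'   frame of work counters and score summaries) and `ranking` (a
#'   [rank_genes()] data frame).
#' @export
run_ssa_me <- function(net, mat, params = ssame_params()) {
  stopifnot(inherits(net, "gene_network"), inherits(mat, "alteration_matrix"),
            inherits(params, "ssame_params"))
  seeds <- eligible_seeds(net, mat)
  genes <- net$nodes  # sorted: C++ index ties == lexicographic ties
  gidx <- stats::setNames(seq_along(genes), genes)
  adj0 <- lapply(net$adjacency, function(nb) unname(gidx[nb]) - 1L)
  m <- unclass(mat)
  gene_samples <- lapply(genes, function(g) {
    if (g %in% rownames(m)) which(m[g, ] == 1L) - 1L else integer()
  })
  set.seed(params$rng_seed)
  res <- cpp_run(adj0, gene_samples, ncol(mat),
                 unname(gidx[seeds]) - 1L, params$sizes,
                 params$forgetfulness, params$reinforcement,
                 params$iterations, params$stop_top_k, params$stop_patience)
  T_ran <- res$n_iterations
  state <- gene_score_state(genes)
  state$score <- stats::setNames(res$score, genes)
  state$max_score <- stats::setNames(res$max_score, genes)
  state$convergence_iter <- stats::setNames(res$convergence_iter, genes)
  state$last_below <- state$convergence_iter - 1L
  state$iteration <- T_ran
  state$top_subnetworks <- stats::setNames(lapply(seq_along(genes), function(i) {
    lapply(res$top_subnetworks[[i]], function(e) {
      small_subnetwork(genes[e$genes], seed = genes[e$genes][[1L]],
                       mes = e$mes, rmes = NA_real_)
    })
  }), genes)
  state$iter_stats <- data.frame(
    iteration = seq_len(T_ran),
    size = vapply(seq_len(T_ran) - 1L, iteration_size, 0L,
                  sizes = params$sizes),
    grow_attempts = res$grow_attempts,
    mes_evaluations = res$mes_evaluations,
    mean_score = res$mean_score,
    n_high = res$n_high)
  # altered genes outside the network: pure decay from 0.5, never reinforced
  off <- setdiff(rownames(mat)[rowSums(mat) > 0L], net$nodes)
  if (length(off)) {
    off <- sort(off)
    f <- params$forgetfulness
    state$genes <- c(state$genes, off)
    state$score <- c(state$score,
                     stats::setNames(rep(0.5 * f^T_ran, length(off)), off))
    state$max_score <- c(state$max_score,
                         stats::setNames(rep(0.5, length(off)), off))
    # monotone decay from 0.5: once below 0.99 * 0.5 it never recovers
    cv <- if (f < 1 && 0.5 * f^T_ran < 0.99 * 0.5) T_ran + 1L else 1L
    state$convergence_iter <- c(state$convergence_iter,
                                stats::setNames(rep(cv, length(off)), off))
    state$top_subnetworks <- c(state$top_subnetworks,
                               stats::setNames(vector("list", length(off)),
                                               off))
  }
  state$seeds <- seeds
  structure(list(state = state, ranking = rank_genes(state)),
            class = "ssame_fit")
}

#' @export
print.ssame_fit <- function(x, ...) {
  cat(sprintf("ssame_fit: %d iterations over %d genes (%d seeds)\n",
              x$state$iteration, length(x$state$genes),
              length(x$state$seeds)))
  cat("top of ranking:\n")
  print(utils::head(x$ranking, 5L))
  invisible(x)
}

#' Rank genes by maximal score and convergence speed
#'
#' Genes are ranked by the maximal score they reached; ties are broken by
#' how fast the score converged (earlier convergence ranks higher) and then
#' lexicographically for full determinism.
#'
#' @param state a [gene_score_state()] after a completed run.
#' @return A data frame of class `ranked_genes` with columns `gene`, `rank`,
#'   `max_score`, `convergence_iter`.
#' @export
rank_genes <- function(state) {
  ord <- order(-state$max_score, state$convergence_iter, state$genes)
  out <- data.frame(gene = state$genes[ord],
                    rank = seq_along(state$genes),
                    max_score = unname(state$max_score[ord]),
                    convergence_iter = unname(state$convergence_iter[ord]))
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' Mutual exclusivity pattern of a prioritized gene
#'
#' The union of the gene's up-to-5 retained highest-MES subnetworks, plus
#' the alteration sub-matrix restricted to those genes with rows ordered by
#' descending alteration count. Note there is no guarantee that all genes
#' within the retrieved pattern are mutually exclusive with each other: the
#' union may combine several distinct patterns that each involve the
#' prioritized gene.
#'
#' @param gene a gene identifier present in `state`.
#' @param state a [gene_score_state()] after a run.
#' @param mat the [alteration_matrix()] the run was scored on.
#' @return A list with `genes` (the pattern) and `tiles` (0/1 matrix,
#'   pattern genes x samples).
#' @export
extract_pattern <- function(gene, state, mat) {
  if (!gene %in% state$genes) stop("unknown gene: ", gene)
  sns <- state$top_subnetworks[[gene]]
  if (!length(sns)) {
    warning("no retained subnetworks for ", gene, "; singleton pattern")
    genes <- gene
  } else {
    genes <- sort(unique(unlist(lapply(sns, function(sn) sn$genes))))
  }
  present <- intersect(genes, rownames(mat))
  tiles <- unclass(mat)[present, , drop = FALSE]
  tiles <- tiles[order(-rowSums(tiles), rownames(tiles)), , drop = FALSE]
  list(genes = genes, tiles = tiles)
}
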