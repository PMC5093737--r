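#' ROC curve and AUC of a ranking against a truth set
#'
#' Sweeps the rank cut-off over the full ranking: sensitivity is the
#' fraction of truth genes retrieved among the highest-ranked genes at a
#' cut-off, specificity the fraction of non-truth universe genes below it.
#' Universe genes absent from the ranking share the worst rank. The
#' trapezoidal AUC equals the fraction of truth/non-truth gene pairs ranked
#' concordantly, with tied pairs counting one half.
#'
#' @param ranked a [rank_genes()] data frame (or any data frame with `gene`
#'   and `rank` columns).
#' @param truth character vector of true driver genes (non-empty, subset of
#'   `universe`).
#' @param universe character vector of all genes considered (typically all
#'   network genes).
#' @return List with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(ranked, truth, universe) {
  truth <- unique(truth)
  if (!length(truth)) stop("empty truth set")
  stopifnot(all(truth %in% universe), all(ranked$gene %in% universe))
  universe <- unique(universe)
  rk <- stats::setNames(rep(length(ranked$gene) + 1, length(universe)),
                        universe)
  rk[ranked$gene] <- ranked$rank
  pos <- universe %in% truth
  P <- sum(pos); N <- sum(!pos)
  if (N == 0L) stop("truth covers the whole universe")
  cuts <- sort(unique(rk))
  tpr <- vapply(cuts, function(t) sum(rk[pos] <= t) / P, 0)
  fpr <- vapply(cuts, function(t) sum(rk[!pos] <= t) / N, 0)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Positive predictive value at a rank cut-off
#'
#' The number of truth genes among the `k` highest-ranked genes divided by
#' `k`.
#'
#' @inheritParams roc_curve
#' @param k cut-off, `1 <= k <= nrow(ranked)`.
#' @return Scalar in `[0, 1]`.
#' @export
ppv_at_cutoff <- function(ranked, truth, k) {
  stopifnot(k >= 1, k <= nrow(ranked))
  mean(ranked$gene[seq_len(k)] %in% truth)
}

# deterministic per-condition/rep child seeds from one master seed
derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max, n)
}

run_sim_auc <- function(net, cfg, params) {
  bundle <- simulate_study(cfg, net)
  fit <- suppressMessages(run_ssa_me(bundle$analysis_network, bundle$mat,
                                     params))
  roc_curve(fit$ranking, bundle$truth, bundle$network$nodes)$auc
}

#' Network-robustness experiment
#'
#' Runs seeded simulate-prioritize-evaluate pipelines for several degrees of
#' network connectedness (edge deletion/addition fractions) and reports the
#' AUC per condition and replicate. Underconnected networks are expected to
#' lower performance more than overconnected ones.
#'
#' @param net reference [gene_network()].
#' @param cfg a [simulation_config()]; its `rng_seed` is the experiment
#'   master seed and its perturbation field is overridden per condition.
#' @param params an [ssame_params()].
#' @param reps simulations per condition.
#' @param conditions data frame with columns `mode` and `fraction`.
#' @return Data frame with columns `condition`, `mode`, `fraction`, `rep`,
#'   `auc`.
#' @export
experiment_network_robustness <- function(net, cfg, params, reps = 10L,
                                          conditions = data.frame(
                                            mode = c("none", "delete",
                                                     "delete", "delete",
                                                     "add", "add", "add"),
                                            fraction = c(0, 0.10, 0.25, 0.50,
                                                         0.10, 0.25, 0.50))) {
  seeds <- matrix(derive_seeds(cfg$rng_seed, nrow(conditions) * reps),
                  nrow = nrow(conditions))
  out <- list()
  for (i in seq_len(nrow(conditions))) {
    for (rep in seq_len(reps)) {
      ci <- cfg
      ci$perturbation <- list(mode = conditions$mode[[i]],
                              fraction = conditions$fraction[[i]])
      ci$rng_seed <- seeds[i, rep]
      p_run <- params
      p_run$rng_seed <- seeds[i, rep]
      out[[length(out) + 1L]] <- data.frame(
        condition = paste0(conditions$mode[[i]], "_",
                           conditions$fraction[[i]]),
        mode = conditions$mode[[i]], fraction = conditions$fraction[[i]],
        rep = rep, auc = run_sim_auc(net, ci, p_run))
    }
  }
  do.call(rbind, out)
}

#' Forgetfulness/reinforcement grid experiment
#'
#' Evaluates every (f, r) combination on the same `reps` simulated datasets
#' and reports the AUC per combination and replicate; performance is
#' expected to peak on the diagonal where `r + f` is close to 1.
#'
#' @param net reference [gene_network()].
#' @param cfg a [simulation_config()] (master seed source).
#' @param f_values,r_values grids of forgetfulness/reinforcement values.
#' @param params template [ssame_params()] supplying iterations, sizes, etc.
#' @param reps simulated datasets shared by all combinations.
#' @return Data frame with columns `f`, `r`, `rep`, `auc`.
#' @export
experiment_parameter_grid <- function(net, cfg, f_values, r_values, params,
                                      reps = 3L) {
  seeds <- derive_seeds(cfg$rng_seed, reps)
  out <- list()
  for (rep in seq_len(reps)) {
    ci <- cfg
    ci$rng_seed <- seeds[[rep]]
    bundle <- simulate_study(ci, net)
    for (f in f_values) {
      for (r in r_values) {
        p_run <- params
        p_run$forgetfulness <- f
        p_run$reinforcement <- r
        p_run$rng_seed <- seeds[[rep]]
        fit <- suppressMessages(run_ssa_me(bundle$analysis_network,
                                           bundle$mat, p_run))
        auc <- roc_curve(fit$ranking, bundle$truth, net$nodes)$auc
        out[[length(out) + 1L]] <- data.frame(f = f, r = r, rep = rep,
                                              auc = auc)
      }
    }
  }
  do.call(rbind, out)
}

#' Seed-count scaling experiment
#'
#' Documents the linear time complexity in the number of seed genes: one
#' subnetwork is grown (and scored once, when growth succeeds) per seed per
#' iteration, so the hardware-independent work unit — MES evaluations per
#' iteration — equals the seed count exactly. Wall time is reported for
#' information only, never asserted.
#'
#' @param net a [gene_network()].
#' @param mat an [alteration_matrix()] over (at least) the network genes.
#' @param seed_counts seed-gene counts to test; for each, the
#'   `seed_counts[i]` most frequently altered genes keep their alterations
#'   and all other gene rows are zeroed (seeds are added by mutation
#'   frequency).
#' @param params an [ssame_params()] (use few iterations).
#' @return Data frame with columns `n_seeds`, `iterations`,
#'   `mes_evals_per_iter`, `grow_attempts_per_iter`, `seconds`.
#' @export
experiment_seed_scaling <- function(net, mat, seed_counts,
                                    params = ssame_params(iterations = 5L,
                                                          stop_patience = 0L)) {
  freq <- sort(rowSums(mat), decreasing = TRUE)
  freq <- freq[freq > 0L]
  freq <- freq[names(freq) %in% net$nodes]
  out <- list()
  for (ns in seed_counts) {
    if (ns > length(freq)) stop("not enough altered genes for ", ns, " seeds")
    keep <- names(freq)[seq_len(ns)]
    m2 <- unclass(mat)
    m2[!rownames(m2) %in% keep, ] <- 0L
    m2 <- as_altmat(m2)
    t0 <- proc.time()[["elapsed"]]
    fit <- suppressMessages(run_ssa_me(net, m2, params))
    secs <- proc.time()[["elapsed"]] - t0
    st <- fit$state$iter_stats
    out[[length(out) + 1L]] <- data.frame(
      n_seeds = ns, iterations = nrow(st),
      mes_evals_per_iter = mean(st$mes_evaluations),
      grow_attempts_per_iter = mean(st$grow_attempts),
      seconds = secs)
  }
  do.call(rbind, out)
}
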