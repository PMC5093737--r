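#' Configuration of the synthetic tumor-cohort generator
#'
#' The generator emulates a cohort in which one connected "driver pathway"
#' (the target gene set, picked by a random walker with restart on the
#' network) carries mutually exclusive alterations in a fixed fraction of
#' samples (default 30%), with a small per-sample chance of a co-mutation in
#' a second target gene (default 5%), on top of per-sample background
#' alterations at random non-target genes.
#'
#' @param n_samples number of tumor samples.
#' @param target_fraction fraction of samples carrying a planted target
#'   alteration (implemented as an exact `round()` count for determinism).
#' @param co_mutation_prob per signal-sample chance of one extra alteration
#'   in a second target gene (non-perfect mutual exclusivity).
#' @param restart_prob restart probability of the target-set walker.
#' @param max_target_edges walker stops after visiting this many distinct
#'   interactions.
#' @param max_target_genes hard cap on the target set size (last-added genes
#'   beyond the cap are dropped; the kept prefix stays connected).
#' @param background_counts either an explicit per-sample alteration count
#'   vector (length `n_samples`, used verbatim) or a list
#'   `list(dist = "nbinom", rate_per_gene =, size =, mean =)` describing a
#'   negative binomial; when `mean` is `NULL` it is set at generation time
#'   to `rate_per_gene` times the number of background genes, so background
#'   per-gene alteration frequency — the quantity MES is sensitive to — is
#'   held at realistic tumor-cohort levels regardless of network size (see
#'   the vignette). The default rate 0.005 reproduces a mean of 50
#'   alterations per sample on a 10,000-gene reference network.
#' @param perturbation list `list(mode =, fraction =)` with mode `"none"`,
#'   `"delete"` or `"add"`; applied to the analysis network only — the
#'   target set is always drawn on the unperturbed network.
#' @param rng_seed master seed of the bundle.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 300L, target_fraction = 0.30,
                              co_mutation_prob = 0.05, restart_prob = 0.05,
                              max_target_edges = 20L, max_target_genes = 20L,
                              background_counts = list(dist = "nbinom",
                                                       rate_per_gene = 0.005,
                                                       size = 5,
                                                       mean = NULL),
                              perturbation = list(mode = "none",
                                                  fraction = 0),
                              rng_seed = 1L) {
  stopifnot(n_samples >= 1, target_fraction >= 0, target_fraction <= 1,
            co_mutation_prob >= 0, co_mutation_prob <= 1,
            restart_prob > 0, restart_prob <= 1,
            max_target_edges >= 1, max_target_genes >= 2,
            perturbation$mode %in% c("none", "delete", "add"))
  structure(list(n_samples = as.integer(n_samples),
                 target_fraction = target_fraction,
                 co_mutation_prob = co_mutation_prob,
                 restart_prob = restart_prob,
                 max_target_edges = as.integer(max_target_edges),
                 max_target_genes = as.integer(max_target_genes),
                 background_counts = background_counts,
                 perturbation = perturbation,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Generate a connected scale-free test network
#'
#' Preferential attachment: a seed triangle is grown by attaching each new
#' node to an existing node drawn proportionally to degree, then extra
#' degree-biased edges are added until exactly `round(n_nodes *
#' mean_degree / 2)` edges exist. A stand-in for a real interaction network
#' with comparable local structure (hubs, short paths); uses R's RNG stream.
#'
#' @param n_nodes number of genes (>= 3).
#' @param mean_degree target mean degree (>= 2 so the growth phase can
#'   complete; the triangle is returned for `n_nodes = 3, mean_degree = 2`).
#' @return A connected [gene_network()] with nodes `g0001`, `g0002`, ...
#' @export
generate_test_network <- function(n_nodes, mean_degree = 4) {
  stopifnot(n_nodes >= 3)
  m_target <- round(n_nodes * mean_degree / 2)
  if (m_target < n_nodes || m_target > choose(n_nodes, 2)) {
    stop("infeasible mean degree for this node count")
  }
  width <- max(4L, nchar(as.character(n_nodes)))
  nodes <- sprintf(paste0("g%0", width, "d"), seq_len(n_nodes))
  deg <- integer(n_nodes)
  from <- integer(m_target); to <- integer(m_target)
  from[1:3] <- c(1L, 1L, 2L); to[1:3] <- c(2L, 3L, 3L)
  deg[1:3] <- 2L
  k <- 3L
  adj <- vector("list", n_nodes)
  adj[[1L]] <- c(2L, 3L); adj[[2L]] <- c(1L, 3L); adj[[3L]] <- c(1L, 2L)
  if (n_nodes > 3L) {
    for (v in 4:n_nodes) {
      u <- sample.int(v - 1L, 1L, prob = deg[seq_len(v - 1L)])
      k <- k + 1L
      from[k] <- u; to[k] <- v
      deg[u] <- deg[u] + 1L; deg[v] <- 1L
      adj[[u]] <- c(adj[[u]], v); adj[[v]] <- u
    }
  }
  while (k < m_target) {
    u <- sample.int(n_nodes, 1L, prob = deg)
    cand <- setdiff(seq_len(n_nodes), c(u, adj[[u]]))
    if (!length(cand)) next
    v <- if (length(cand) == 1L) cand else {
      cand[sample.int(length(cand), 1L, prob = deg[cand])]
    }
    k <- k + 1L
    from[k] <- min(u, v); to[k] <- max(u, v)
    deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  gene_network(cbind(nodes[from], nodes[to]))
}

#' Randomly perturb network connectedness
#'
#' `mode = "delete"` removes `round(fraction * |E|)` uniformly chosen edges
#' (the node set is retained, possibly leaving isolated nodes);
#' `mode = "add"` inserts the same number of new edges uniformly over
#' currently non-adjacent node pairs. Models an under- or over-connected
#' reference network. Uses R's RNG stream.
#'
#' @param net a [gene_network()].
#' @param mode `"delete"` or `"add"`.
#' @param fraction fraction of the current edge count, in `(0, 1]`.
#' @return The perturbed [gene_network()] over the same node set.
#' @export
perturb_network <- function(net, mode = c("delete", "add"), fraction) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction <= 1)
  E <- nrow(net$edges)
  k <- round(fraction * E)
  if (mode == "delete") {
    drop <- sample.int(E, k)
    return(gene_network(net$edges[-drop, , drop = FALSE], nodes = net$nodes))
  }
  n <- length(net$nodes)
  if (k > choose(n, 2) - E) stop("cannot add ", k, " edges: too few non-adjacent pairs")
  have <- new.env(hash = TRUE, size = E + k)
  for (i in seq_len(E)) {
    assign(paste(net$edges[i, 1L], net$edges[i, 2L], sep = "\r"), TRUE, have)
  }
  new_from <- character(k); new_to <- character(k)
  added <- 0L
  while (added < k) {
    ij <- sample.int(n, 2L)
    a <- net$nodes[min(ij)]; b <- net$nodes[max(ij)]
    keyv <- paste(a, b, sep = "\r")
    if (!exists(keyv, envir = have, inherits = FALSE)) {
      assign(keyv, TRUE, have)
      added <- added + 1L
      new_from[added] <- a; new_to[added] <- b
    }
  }
  gene_network(rbind(net$edges, cbind(new_from, new_to)), nodes = net$nodes)
}

#' Select a connected target gene set by random walk with restart
#'
#' From a uniformly chosen start gene (isolated starts are redrawn), the
#' walker either restarts to the start gene (probability
#' `cfg$restart_prob`) or steps to a uniformly chosen neighbor, until
#' `cfg$max_target_edges` distinct interactions have been traversed or a
#' step cap is hit (whichever comes first, e.g. on a component with fewer
#' edges). The distinct visited genes, in first-visit order, form the target
#' set, truncated to `cfg$max_target_genes` by dropping the last-added
#' genes; the kept prefix is always connected. Uses R's RNG stream.
#'
#' @param net a [gene_network()] with at least one edge.
#' @param cfg a [simulation_config()].
#' @param step_cap maximum walker steps.
#' @return Character vector of target genes (>= 2).
#' @export
sample_target_set <- function(net, cfg, step_cap = 1e5) {
  if (!nrow(net$edges)) stop("network has no edges")
  repeat {
    start <- net$nodes[[sample.int(length(net$nodes), 1L)]]
    if (length(net$adjacency[[start]])) break
  }
  w <- walk_with_restart(net, start, cfg$restart_prob,
                         cfg$max_target_edges, step_cap)
  utils::head(w$genes, cfg$max_target_genes)
}

# the restart walker itself, returning diagnostics (internal)
walk_with_restart <- function(net, start, restart_prob, max_edges, step_cap) {
  cur <- start
  visited_genes <- start
  seen_edges <- new.env(hash = TRUE)
  n_edges_seen <- 0L
  steps <- 0L
  restarts <- 0L
  while (n_edges_seen < max_edges && steps < step_cap) {
    steps <- steps + 1L
    if (stats::runif(1L) < restart_prob) {
      restarts <- restarts + 1L
      cur <- start
      next
    }
    nb <- net$adjacency[[cur]]
    nxt <- nb[[sample.int(length(nb), 1L)]]
    keyv <- paste(min(cur, nxt), max(cur, nxt), sep = "\r")
    if (!exists(keyv, envir = seen_edges, inherits = FALSE)) {
      assign(keyv, TRUE, seen_edges)
      n_edges_seen <- n_edges_seen + 1L
    }
    if (!nxt %in% visited_genes) visited_genes <- c(visited_genes, nxt)
    cur <- nxt
  }
  list(genes = visited_genes, n_steps = steps, n_restarts = restarts,
       n_edges = n_edges_seen)
}

#' Generate a synthetic alteration matrix with a planted pattern
#'
#' Three layers, all drawn from R's RNG stream:
#' * background — every sample receives `k_s` alterations at uniformly
#'   chosen distinct non-target genes, `k_s` taken verbatim from an explicit
#'   `cfg$background_counts` vector or drawn from the configured negative
#'   binomial;
#' * planted signal — exactly `round(target_fraction * n_samples)` samples
#'   each receive one alteration in one target gene, genes assigned
#'   round-robin over a random permutation so per-gene counts are
#'   near-uniform (uniform per-gene counts are the regime in which mutual
#'   exclusivity scores are highest);
#' * noise — each signal sample independently gains, with probability
#'   `cfg$co_mutation_prob`, one extra alteration in a different target
#'   gene.
#'
#' @param net a [gene_network()] supplying the gene universe.
#' @param target character vector of target genes (subset of the nodes).
#' @param cfg a [simulation_config()].
#' @return List with `mat` (an [alteration_matrix()], all network genes x
#'   samples) and `truth` (the target gene set).
#' @export
generate_alterations <- function(net, target, cfg) {
  stopifnot(all(target %in% net$nodes))
  genes <- net$nodes
  bg_genes <- setdiff(genes, target)
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  m <- matrix(0L, length(genes), n, dimnames = list(genes, samples))
  bc <- cfg$background_counts
  if (is.numeric(bc)) {
    if (length(bc) != n) stop("explicit background_counts must have length n_samples")
    k_s <- as.integer(bc)
  } else {
    mu <- if (!is.null(bc$mean)) bc$mean else bc$rate_per_gene * length(bg_genes)
    k_s <- stats::rnbinom(n, size = bc$size, mu = mu)
  }
  k_s <- pmin(k_s, length(bg_genes))
  for (j in seq_len(n)) {
    if (k_s[[j]] > 0L) {
      hit <- sample(bg_genes, k_s[[j]])
      m[cbind(match(hit, genes), j)] <- 1L
    }
  }
  n_sig <- round(cfg$target_fraction * n)
  if (n_sig > 0L && length(target)) {
    if (n_sig < length(target)) {
      warning("fewer signal samples than target genes: some targets unmutated")
    }
    sig <- sample(samples, n_sig)
    perm <- sample(target)
    assigned <- perm[((seq_len(n_sig) - 1L) %% length(perm)) + 1L]
    m[cbind(match(assigned, genes), match(sig, samples))] <- 1L
    if (length(target) > 1L) {
      co <- stats::runif(n_sig) < cfg$co_mutation_prob
      for (j in which(co)) {
        other <- setdiff(target, assigned[[j]])
        extra <- other[[sample.int(length(other), 1L)]]
        m[match(extra, genes), match(sig[[j]], samples)] <- 1L
      }
    }
  }
  list(mat = alteration_matrix(m), truth = target)
}

#' Generate one complete simulated study bundle
#'
#' Composes the generators under one master seed: target set drawn on the
#' given (unperturbed) network, alteration matrix with the planted pattern,
#' and the configured network perturbation for the analysis network. When
#' `out_dir` is given, writes `network.tsv`, `analysis_network.tsv`,
#' `matrix.tsv`, `truth.txt` and `config.json` so any stage can be re-run
#' from files.
#'
#' @param cfg a [simulation_config()].
#' @param net a [gene_network()]; the reference network the bundle is built
#'   on.
#' @param out_dir optional output directory.
#' @return List of class `sim_study` with `network`, `analysis_network`,
#'   `mat`, `truth`, `config`.
#' @export
simulate_study <- function(cfg, net, out_dir = NULL) {
  set.seed(cfg$rng_seed)
  target <- sample_target_set(net, cfg)
  gen <- generate_alterations(net, target, cfg)
  analysis_net <- if (cfg$perturbation$mode == "none" ||
                        cfg$perturbation$fraction == 0) {
    net
  } else {
    perturb_network(net, cfg$perturbation$mode, cfg$perturbation$fraction)
  }
  bundle <- structure(list(network = net, analysis_network = analysis_net,
                           mat = gen$mat, truth = gen$truth, config = cfg),
                      class = "sim_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_network(net, file.path(out_dir, "network.tsv"))
    write_network(analysis_net, file.path(out_dir, "analysis_network.tsv"))
    write_alterations(gen$mat, file.path(out_dir, "matrix.tsv"))
    writeLines(gen$truth, file.path(out_dir, "truth.txt"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                           auto_unbox = TRUE, null = "null")
    }
  }
  bundle
}
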