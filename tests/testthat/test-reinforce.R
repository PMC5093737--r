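test_that("update_scores applies min(1, f*g + r*best) with best = max rMES", {
  p <- ssame_params(forgetfulness = 0.995, reinforcement = 0.005)
  st <- gene_score_state(c("A", "B", "C"))
  batch <- list(small_subnetwork(c("A", "B"), mes = 2, rmes = 1),
                small_subnetwork(c("A", "C"), mes = 1, rmes = 0.4))
  st2 <- update_scores(st, batch, p)
  expect_equal(unname(st2$score["A"]), 0.995 * 0.5 + 0.005 * 1)  # max, not sum
  expect_equal(unname(st2$score["B"]), 0.5025)
  # gene in no subnetwork: best = 0, pure decay
  st3 <- update_scores(gene_score_state("Z"), list(), p)
  expect_equal(unname(st3$score["Z"]), 0.4975)
  # top-off at 1
  pcap <- ssame_params(forgetfulness = 0.5, reinforcement = 0.9)
  stc <- gene_score_state(c("A", "B"), score = 1)
  stc2 <- update_scores(stc, list(small_subnetwork(c("A", "B"), mes = 1,
                                                   rmes = 1)), pcap)
  expect_equal(unname(stc2$score["A"]), 1)
})

test_that("scores stay in [0,1] across the published parameter grid", {
  b <- toy_study(seed = 6L, n_nodes = 40L, n_samples = 30L)
  for (f in c(0.99, 0.9995)) {
    for (r in c(0.0005, 0.01)) {
      p <- ssame_params(forgetfulness = f, reinforcement = r,
                        iterations = 60L, rng_seed = 1L)
      fit <- suppressMessages(run_ssa_me(b$analysis_network, b$mat, p))
      expect_true(all(fit$state$score >= 0 & fit$state$score <= 1))
      expect_true(all(fit$state$max_score >= fit$state$score - 1e-12))
    }
  }
})

test_that("r = 0 decays every score to 0.5 * f^T, matching the compiled path", {
  b <- toy_study(seed = 8L, n_nodes = 40L, n_samples = 30L)
  T <- 400L
  f <- 0.995
  p <- ssame_params(forgetfulness = f, reinforcement = 0, iterations = T,
                    rng_seed = 5L, stop_patience = 0L)
  fit <- suppressMessages(run_ssa_me(b$analysis_network, b$mat, p))
  expected <- 0.5
  for (i in seq_len(T)) expected <- f * expected  # same arithmetic sequence
  expect_equal(unname(fit$state$score), rep(expected, length(fit$state$score)),
               tolerance = 1e-14)
})

test_that("constant best(g) drives scores to the fixed point r*m/(1-f)", {
  # iterate the R reference update with a constant-rmes batch
  for (triple in list(c(f = 0.995, r = 0.005, m = 0.6),
                      c(f = 0.99, r = 0.01, m = 0.3),
                      c(f = 0.9, r = 0.05, m = 1.0))) {
    p <- ssame_params(forgetfulness = triple[["f"]],
                      reinforcement = triple[["r"]])
    st <- gene_score_state(c("A", "B"))
    batch <- list(small_subnetwork(c("A", "B"), mes = 1,
                                   rmes = triple[["m"]]))
    for (i in 1:3000) st <- update_scores(st, batch, p)
    fp <- min(1, triple[["r"]] * triple[["m"]] / (1 - triple[["f"]]))
    expect_equal(unname(st$score["A"]), fp, tolerance = 1e-6)
  }
})

test_that("rank_genes orders by max score, then convergence, then name", {
  st <- gene_score_state(c("A", "B", "C", "D"))
  st$max_score[] <- c(1.0, 0.7, 1.0, 0.7)
  st$convergence_iter[] <- c(4000L, 100L, 1200L, 100L)
  rk <- rank_genes(st)
  expect_identical(rk$gene, c("C", "A", "B", "D"))  # tie at 1.0 -> faster
  expect_identical(rk$rank, 1:4)                    # full tie -> lexicographic
})

test_that("extract_pattern unions the retained subnetworks", {
  st <- gene_score_state(c("A", "B", "C", "D"))
  st$top_subnetworks[["A"]] <- list(
    small_subnetwork(c("A", "B", "C"), mes = 3),
    small_subnetwork(c("A", "C", "D"), mes = 2))
  mat <- disjoint_matrix(c(3L, 2L, 1L, 1L), genes = c("A", "B", "C", "D"))
  pat <- extract_pattern("A", st, mat)
  expect_setequal(pat$genes, c("A", "B", "C", "D"))
  expect_identical(rownames(pat$tiles)[1L], "A")  # ordered by alteration count
  # five identical subnetworks collapse to that subnetwork
  st$top_subnetworks[["B"]] <- rep(list(
    small_subnetwork(c("A", "B"), mes = 1)), 5L)
  expect_setequal(extract_pattern("B", st, mat)$genes, c("A", "B"))
  expect_warning(pat2 <- extract_pattern("C", st, mat), "singleton")
  expect_identical(pat2$genes, "C")
})

test_that("top-subnetwork retention is bounded at 5 with highest MES kept", {
  # direct bounded-merge property on the R reference
  withr::local_seed(14)
  lst <- list()
  best_seen <- -Inf
  for (i in 1:500) {
    sn <- small_subnetwork(sample(LETTERS[1:6], 3L), mes = stats::runif(1))
    best_seen <- max(best_seen, sn$mes)
    lst <- ssame:::keep_top5(lst, sn)
    expect_lte(length(lst), 5L)
    ms <- vapply(lst, `[[`, 0, "mes")
    expect_identical(ms, sort(ms, decreasing = TRUE))
  }
  expect_equal(lst[[1L]]$mes, best_seen)
  # and through a full run
  b <- toy_study(seed = 16L, n_nodes = 40L, n_samples = 30L)
  fit <- suppressMessages(run_ssa_me(b$analysis_network, b$mat,
                                     ssame_params(iterations = 800L,
                                                  rng_seed = 4L)))
  lens <- lengths(fit$state$top_subnetworks)
  expect_true(all(lens <= 5L))
  expect_gt(max(lens), 0L)
})

test_that("genes that reach a high score remain consistently high", {
  # stability of convergence: once reinforced to a high score, a gene does
  # not fall back (no inflections); see vignette for why a global
  # low/high bimodality is not expected at this cohort scale
  b <- toy_study(seed = 18L, n_nodes = 100L, n_samples = 80L)
  p <- ssame_params(iterations = 5000L, rng_seed = 9L)
  fit <- suppressMessages(run_ssa_me(b$analysis_network, b$mat, p))
  st <- fit$state
  high <- st$max_score > 0.9
  expect_gt(sum(high), 0L)
  expect_lt(mean(st$score[high] < 0.9 * st$max_score[high]), 0.05)
  # and genes never entering a subnetwork decay towards zero
  off <- setdiff(rownames(b$mat)[rowSums(b$mat) > 0], b$network$nodes)
  expect_true(all(st$score <= st$max_score))
})

test_that("every gene starts at 0.5 and max_score never decreases", {
  st <- gene_score_state(c("A", "B"))
  expect_true(all(st$score == 0.5))
  b <- toy_study(seed = 19L, n_nodes = 40L, n_samples = 30L)
  p <- ssame_params(iterations = 30L, rng_seed = 2L)
  st2 <- gene_score_state(b$analysis_network$nodes)
  prev_max <- st2$max_score
  # iterate the R update through real sampled batches
  set.seed(1)
  for (it in 0:14) {
    sz <- iteration_size(it)
    batch <- list()
    for (seed in eligible_seeds(b$analysis_network, b$mat)) {
      sn <- grow_subnetwork(seed, st2$score, b$analysis_network, sz)
      if (!is.null(sn)) {
        sn$mes <- mes(sn, b$mat)
        batch[[length(batch) + 1L]] <- sn
      }
    }
    batch <- rank_mes(batch)
    st2 <- update_scores(st2, batch, p)
    expect_true(all(st2$max_score >= prev_max - 1e-15))
    expect_true(all(st2$score >= 0 & st2$score <= 1))
    prev_max <- st2$max_score
  }
})
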