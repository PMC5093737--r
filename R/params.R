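#' Parameters of the reinforced subnetwork-sampling run
#'
#' The two central knobs are the *forgetfulness* `f` — the fraction of a
#' gene's score retained each iteration — and the *reinforcement* `r` — the
#' maximal per-iteration score increment, scaled by the gene's best rMES.
#' The defaults `f = 0.995`, `r = 0.005`, 5000 iterations follow the
#' method's published operating point; performance is best when
#' `r + f` is close to 1 and `r` is small (< 0.01), since a large `r` or a
#' small `f` makes the iteration prone to stochastic effects.
#'
#' @param forgetfulness `f`, in `(0, 1]`.
#' @param reinforcement `r`, in `[0, 1)`; `r = 0` is a degenerate setting
#'   (pure decay) accepted for diagnostics.
#' @param iterations maximum number of iterations (>= 1).
#' @param sizes integer vector of subnetwork sizes cycled across iterations.
#' @param rng_seed integer seed driving all randomness of a run.
#' @param bootstrap_B number of bootstrap replicates for [bootstrap_rank()].
#' @param bootstrap_support required bootstrap support fraction.
#' @param stop_top_k,stop_patience early-stopping rule: stop when the set of
#'   `stop_top_k` highest-scoring genes is unchanged for `stop_patience`
#'   consecutive iterations; `stop_patience = 0` disables early stopping.
#' @return An object of class `ssame_params`.
#' @export
ssame_params <- function(forgetfulness = 0.995, reinforcement = 0.005,
                         iterations = 5000L, sizes = c(3L, 4L, 5L, 6L),
                         rng_seed = 1L, bootstrap_B = 1000L,
                         bootstrap_support = 0.95,
                         stop_top_k = 100L, stop_patience = 500L) {
  stopifnot(forgetfulness > 0, forgetfulness <= 1,
            reinforcement >= 0, reinforcement < 1,
            iterations >= 1, length(sizes) >= 1, all(sizes >= 2),
            bootstrap_B >= 0, bootstrap_support > 0, bootstrap_support <= 1,
            stop_top_k >= 1, stop_patience >= 0)
  structure(list(forgetfulness = forgetfulness,
                 reinforcement = reinforcement,
                 iterations = as.integer(iterations),
                 sizes = as.integer(sizes),
                 rng_seed = as.integer(rng_seed),
                 bootstrap_B = as.integer(bootstrap_B),
                 bootstrap_support = bootstrap_support,
                 stop_top_k = as.integer(stop_top_k),
                 stop_patience = as.integer(stop_patience)),
            class = "ssame_params")
}

#' @export
print.ssame_params <- function(x, ...) {
  cat(sprintf(paste0("ssame_params: f=%g r=%g iterations=%d sizes=%s ",
                     "seed=%d B=%d support=%g\n"),
              x$forgetfulness, x$reinforcement, x$iterations,
              paste(x$sizes, collapse = ","), x$rng_seed, x$bootstrap_B,
              x$bootstrap_support))
  invisible(x)
}
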