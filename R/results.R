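#' Write prioritization results as plain TSV files
#'
#' Produces, under `out_dir`:
#' * `ranked_genes.tsv` — the ranking with `gene`, `rank`, `max_score`,
#'   `convergence_iter` and any bootstrap columns;
#' * `node_attributes.tsv` — per-gene final score and number of altered
#'   samples, suitable as a node-attribute table for network viewers;
#' * `patterns/<gene>.tsv` — the mutual exclusivity pattern of each of the
#'   `top_n` highest-ranked genes ([extract_pattern()]): pattern genes as
#'   rows, samples as columns.
#'
#' All files are UTF-8, LF, tab-separated.
#'
#' @param ranked a `ranked_genes` data frame (from [rank_genes()] or
#'   [bootstrap_rank()]); must be non-empty.
#' @param state the [gene_score_state()] of the run.
#' @param mat the [alteration_matrix()] the run used.
#' @param out_dir output directory (created if needed).
#' @param top_n number of top-ranked genes to export patterns for.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(ranked, state, mat, out_dir, top_n = 10L) {
  if (!nrow(ranked)) stop("empty ranking")
  dir.create(file.path(out_dir, "patterns"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- file.path(out_dir, "ranked_genes.tsv")
  utils::write.table(ranked, paths[[1L]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nalt <- stats::setNames(rep(0L, length(state$genes)), state$genes)
  common <- intersect(state$genes, rownames(mat))
  nalt[common] <- rowSums(unclass(mat)[common, , drop = FALSE])
  node_df <- data.frame(gene = state$genes,
                        score = unname(state$score[state$genes]),
                        n_samples_altered = unname(nalt[state$genes]))
  p2 <- file.path(out_dir, "node_attributes.tsv")
  utils::write.table(node_df, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p2)
  for (g in utils::head(ranked$gene, top_n)) {
    pat <- suppressWarnings(extract_pattern(g, state, mat))
    df <- data.frame(gene = rownames(pat$tiles),
                     pat$tiles[, , drop = FALSE], check.names = FALSE)
    if (!nrow(df)) df <- data.frame(gene = g)
    pp <- file.path(out_dir, "patterns", paste0(g, ".tsv"))
    utils::write.table(df, pp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pp)
  }
  invisible(paths)
}

#' Read back a ranked-genes TSV
#'
#' @param path a `ranked_genes.tsv` written by [write_results()].
#' @return A `ranked_genes` data frame.
#' @export
read_ranked <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  class(df) <- c("ranked_genes", "data.frame")
  df
}
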