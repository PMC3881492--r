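# Accuracy evaluation and diagnostics: Spearman correlation against
# simulation ground truth, the ambiguity graph over targets, and the
# abundance result table.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (the accuracy metric used
#' to compare estimated against ground-truth abundances). If either
#' vector is constant the correlation is undefined and `NA` is returned
#' (with a warning) rather than a number.
#'
#' @param est,truth Numeric vectors of equal length (>= 2).
#' @return A value in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
spearman_correlation <- function(est, truth) {
  stopifnot(is.numeric(est), is.numeric(truth))
  if (length(est) != length(truth) || length(est) < 2L) {
    stop("est and truth must have equal length >= 2", call. = FALSE)
  }
  if (length(unique(est)) == 1L || length(unique(truth)) == 1L) {
    warning("Spearman correlation undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(est, truth, method = "spearman")
}

#' Connected components of the ambiguity graph
#'
#' The ambiguity graph has one node per target and an edge between two
#' targets whenever some fragment aligns to both. Targets in different
#' components are independent in the likelihood, so EM can be run per
#' component.
#'
#' @param fragments List of [fragment_record()]s.
#' @param n_targets Number of targets.
#' @return Integer vector of component labels (length `n_targets`,
#'   labels `1..n_components`).
#' @export
ambiguity_components <- function(fragments, n_targets) {
  edges <- list()
  for (f in fragments) {
    ts <- unique(vapply(f$alignments, `[[`, integer(1), "target_id")) + 1L
    if (length(ts) > 1L) {
      edges[[length(edges) + 1L]] <- rbind(ts[1L], ts[-1L])
    }
  }
  g <- igraph::make_empty_graph(n = n_targets, directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  as.integer(igraph::components(g)$membership)
}

#' Build the abundance result table
#'
#' @param result An `em_result` from [run_em()]/[run_em_parallel()].
#' @return A data frame with one row per target: name, length, effective
#'   length, expected count, sampling probability `tau`, and a
#'   length-normalized relative abundance (`tau/efflen` rescaled to one
#'   million, TPM-like).
#' @export
abundance_table <- function(result) {
  stopifnot(inherits(result, "em_result"))
  rel <- result$tau / result$eff_lengths
  data.frame(target = result$target_names,
             length = result$target_lengths,
             eff_length = result$eff_lengths,
             est_counts = result$counts,
             tau = result$tau,
             rel_abundance = rel / sum(rel) * 1e6,
             stringsAsFactors = FALSE)
}

#' Write the abundance table as TSV
#'
#' @param result An `em_result`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_abundance_table <- function(result, path) {
  tab <- abundance_table(result)
  tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }, error = function(e) {
    stop(sprintf("failed to write abundance table to '%s': %s",
                 path, conditionMessage(e)), call. = FALSE)
  })
  invisible(path)
}

#' Read back an abundance table
#' @param path TSV path written by [write_abundance_table()].
#' @return Data frame.
#' @export
read_abundance_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
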