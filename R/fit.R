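# Modelling front end: fragem() fits the assignment model and returns a
# classed object with the usual accessor methods.

#' Fit the fragment assignment model
#'
#' The main user-facing entry point: runs batch EM over a set of fragment
#' records and targets and returns a fitted-model object. `fragments` and
#' `targets` may be in-memory record lists or paths to the
#' newline-delimited base64 record files produced by
#' [preprocess_sam_fasta()] or [simulate_experiment()].
#'
#' @param fragments List of [fragment_record()]s, or a file path.
#' @param targets List of [target_record()]s, or a file path.
#' @param config An [em_config()].
#' @param workers Number of local worker processes; 1 (default) runs the
#'   serial engine, more uses the partitioned broadcast/accumulate
#'   executor.
#' @return An object of class `"fragem"` wrapping the `em_result`, with
#'   `print`, `summary`, `coef` (sampling probabilities), `fitted`
#'   (expected counts), `logLik` and `plot` methods.
#' @examples
#' cfg <- sim_config(n_targets = 12, n_groups = 4, n_fragments = 400,
#'                   len_range = c(300, 500), seed = 42)
#' tg <- simulate_targets(cfg)
#' sim <- simulate_experiment(tg, cfg)
#' fit <- fragem(sim$fragments, tg, em_config(bias_enabled = FALSE))
#' head(coef(fit))
#' @export
fragem <- function(fragments, targets, config = em_config(), workers = 1L) {
  if (is.character(fragments)) fragments <- read_record_file(fragments, "fragment")
  if (is.character(targets)) targets <- read_record_file(targets, "target")
  result <- if (workers > 1L) {
    run_em_parallel(fragments, targets, config, n_workers = workers)
  } else {
    run_em(fragments, targets, config)
  }
  structure(list(result = result,
                 table = abundance_table(result),
                 config = config,
                 n_fragments = length(fragments),
                 call = match.call()),
            class = "fragem")
}

#' @export
print.fragem <- function(x, ...) {
  r <- x$result
  cat("Batch EM fragment assignment fit\n")
  cat(sprintf("  targets:    %d\n", length(r$tau)))
  cat(sprintf("  fragments:  %s\n", format(r$n_fragments, big.mark = ",")))
  cat(sprintf("  iterations: %d (%s)\n", r$iterations,
              if (r$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  bias:       %s\n", if (x$config$bias_enabled) "corrected" else "off"))
  cat(sprintf("  log-likelihood: %.4f\n", utils::tail(r$loglik_trace, 1L)))
  invisible(x)
}

#' @export
summary.fragem <- function(object, ...) {
  tab <- object$table
  structure(list(fit = object,
                 top = tab[order(-tab$est_counts), ][seq_len(min(10L, nrow(tab))), ],
                 ambiguous_share = NA_real_),
            class = "summary.fragem")
}

#' @export
print.summary.fragem <- function(x, ...) {
  print(x$fit)
  cat("\nTop targets by expected count:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.fragem <- function(object, ...) {
  stats::setNames(object$result$tau, object$result$target_names)
}

#' @export
fitted.fragem <- function(object, ...) {
  stats::setNames(object$result$counts, object$result$target_names)
}

#' @export
logLik.fragem <- function(object, ...) {
  ll <- utils::tail(object$result$loglik_trace, 1L)
  structure(ll, df = length(object$result$tau) - 1L, class = "logLik")
}

#' @export
plot.fragem <- function(x, ...) {
  tr <- x$result$loglik_trace
  graphics::plot(seq_along(tr), tr, type = "l", xlab = "iteration",
                 ylab = "data log-likelihood",
                 main = "EM log-likelihood trace", ...)
  invisible(x)
}
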