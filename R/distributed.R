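# Partitioned broadcast/accumulate executor. The master broadcasts a
# read-only parameter snapshot each round; workers (local R processes)
# run the E-step over their cached fragment partitions — and, on bias
# update rounds, the expected-window accumulation over their target
# partitions — and send additive accumulators back. The master combines
# them in ascending partition-ordinal order (a fixed reduction order, so
# results are reproducible bit for bit across worker counts) and runs the
# M-step. Contract: results equal the serial engine.

#' Partition a stream of fragment records
#'
#' Splits records into `ceiling(n/partition_size)` order-preserving
#' partitions; all but the last hold exactly `partition_size` records.
#'
#' @param records List of [fragment_record()]s.
#' @param partition_size Records per partition (>= 1).
#' @return List of `fragment_partition` objects (fields `ordinal`,
#'   `fragments`); empty input gives an empty list.
#' @export
partition_fragments <- function(records, partition_size) {
  stopifnot(partition_size >= 1L)
  n <- length(records)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = partition_size)
  lapply(seq_along(starts), function(i) {
    structure(list(ordinal = i,
                   fragments = records[starts[i]:min(starts[i] + partition_size - 1L, n)],
                   compiled = NULL),
              class = "fragment_partition")
  })
}

#' Partition the target set
#'
#' @param targets List of [target_record()]s.
#' @param partition_size Targets per partition.
#' @return List of `target_partition` objects.
#' @export
partition_targets <- function(targets, partition_size) {
  stopifnot(partition_size >= 1L)
  n <- length(targets)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = partition_size)
  lapply(seq_along(starts), function(i) {
    structure(list(ordinal = i,
                   targets = targets[starts[i]:min(starts[i] + partition_size - 1L, n)]),
              class = "target_partition")
  })
}

#' Build a broadcast parameter snapshot
#'
#' A read-only copy of the model parameters plus an iteration stamp.
#' Workers must never mutate it; [run_em_parallel()] verifies this with a
#' checksum before and after every round.
#'
#' @param params A [new_model_params()] snapshot.
#' @param iteration Iteration stamp.
#' @return An object of class `"broadcast_params"`.
#' @export
broadcast_params <- function(params, iteration) {
  structure(list(params = params, iteration = as.integer(iteration)),
            class = "broadcast_params")
}

.bc_checksum <- function(x) {
  # cheap content checksum of a serialized object (sum of byte values)
  b <- serialize(x, NULL, version = 3L)
  sum(as.double(b))
}

#' E-step over one fragment partition
#'
#' Computes the accumulator equal to the sum of [e_step_fragment()]
#' contributions over the partition, in record order, touching no shared
#' mutable state.
#'
#' @param part A partition from [partition_fragments()].
#' @param bcast A [broadcast_params()] snapshot.
#' @param targets List of [target_record()]s.
#' @param cfg An [em_config()].
#' @param want_aux Accumulate the auxiliary count banks too?
#' @return An `em_accumulator`.
#' @export
map_partition_estep <- function(part, bcast, targets, cfg = em_config(),
                                want_aux = TRUE) {
  stopifnot(inherits(part, "fragment_partition"))
  ti <- .target_info(targets, cfg)
  shape <- .acc_shape(ti$n, cfg)
  if (length(part$fragments) == 0L) return(zero_accumulator(shape))
  chunk <- .compile_chunk(part$fragments, ti, cfg)
  chunk <- tryCatch(.chunk_aux_cache(chunk, bcast$params, cfg), error = function(e) {
    stop(sprintf("partition %d: %s", part$ordinal, conditionMessage(e)), call. = FALSE)
  })
  eff <- .eff_lengths(ti$lens, bcast$params$fld)
  bc <- list(shape = shape, log_tau = bcast$params$log_tau, log_eff = log(eff),
             want_aux = want_aux, bias_on = cfg$bias_enabled)
  tryCatch(.estep_chunk(chunk, bc), error = function(e) {
    stop(sprintf("partition %d: %s", part$ordinal, conditionMessage(e)), call. = FALSE)
  })
}

#' Expected bias windows over one target partition
#'
#' The partial expected-frequency window counts for the partition's
#' targets, weighted exactly as in [update_bias_expected()].
#'
#' @param part A partition from [partition_targets()].
#' @param bcast A [broadcast_params()] snapshot.
#' @param cfg An [em_config()].
#' @param tau_all,eff_all Full abundance and effective-length vectors
#'   (indexed by target id + 1).
#' @return An `em_accumulator` carrying `b5_counts`/`b3_counts`.
#' @export
map_partition_bias_expected <- function(part, bcast, cfg = em_config(),
                                        tau_all = bcast$params$tau,
                                        eff_all = NULL) {
  stopifnot(inherits(part, "target_partition"))
  ids <- vapply(part$targets, `[[`, integer(1), "id")
  codes <- lapply(part$targets, function(t) .unpack_codes(t$seq, t$length))
  lens <- vapply(part$targets, `[[`, integer(1), "length")
  if (is.null(eff_all)) {
    stop("eff_all (effective lengths for all targets) is required", call. = FALSE)
  }
  tmpl <- .chain_uniform(cfg$bias_up, cfg$bias_down, cfg$bias_order)
  local_ti <- list(n = length(part$targets), codes = codes, lens = lens,
                   off = c(0L, cumsum(lens))[seq_along(lens)])
  slide <- .slide_cache(local_ti, cfg)
  acc <- zero_accumulator(.acc_shape(length(tau_all), cfg))
  ec <- .bias_expected_counts(slide, tau_all[ids + 1L], eff_all[ids + 1L],
                              bcast$params$fld, lens)
  acc$b5_counts <- ec$c5
  acc$b3_counts <- ec$c3
  acc
}

#' Combine accumulators in ordinal order
#'
#' Entrywise sum, reduced left to right in the order given (ascending
#' partition ordinal) so the floating-point reduction is deterministic.
#'
#' @param parts List of `em_accumulator`s (structurally compatible).
#' @param shape Shape for the zero accumulator when `parts` is empty.
#' @return An `em_accumulator`.
#' @export
combine_accumulators <- function(parts, shape = NULL) {
  if (length(parts) == 0L) {
    if (is.null(shape)) stop("empty accumulator list needs an explicit shape", call. = FALSE)
    return(zero_accumulator(shape))
  }
  out <- parts[[1L]]
  for (i in seq_along(parts)[-1L]) out <- .acc_add(out, parts[[i]])
  out
}

# --- parallel driver ----------------------------------------------------

# Worker-side round: compute E-step accumulators for the worker's cached
# fragment chunks (and bias-expected counts for its target slides when
# requested). Runs inside a PSOCK worker; state lives in .fragem_worker.
.worker_setup <- function(chunks, ordinals, slides, t_ordinals, cfg) {
  env <- globalenv()
  assign(".fragem_worker",
         list(chunks = chunks, ordinals = ordinals, cache_version = -1L,
              slides = slides, t_ordinals = t_ordinals, cfg = cfg),
         envir = env)
  length(chunks)
}

.worker_round <- function(bc) {
  st <- get(".fragem_worker", envir = globalenv())
  cfg <- st$cfg
  before <- .bc_checksum(bc$bcast)
  if (st$cache_version != bc$aux_version) {
    st$chunks <- lapply(st$chunks, .chunk_aux_cache, params = bc$bcast$params, cfg = cfg)
    st$cache_version <- bc$aux_version
    assign(".fragem_worker", st, envir = globalenv())
  }
  ebc <- list(shape = bc$shape, log_tau = bc$bcast$params$log_tau,
              log_eff = bc$log_eff, want_aux = bc$want_aux,
              bias_on = cfg$bias_enabled)
  accs <- lapply(st$chunks, .estep_chunk, bc = ebc)
  bias_accs <- NULL
  if (isTRUE(bc$want_bias_expected)) {
    bias_accs <- lapply(st$slides, function(sl) {
      acc <- zero_accumulator(bc$shape)
      ec <- .bias_expected_counts(sl$slide, bc$next_tau[sl$ids + 1L],
                                  bc$next_eff[sl$ids + 1L],
                                  bc$next_fld, sl$lens)
      acc$b5_counts <- ec$c5
      acc$b3_counts <- ec$c3
      acc
    })
  }
  list(ordinals = st$ordinals, accs = accs,
       t_ordinals = st$t_ordinals, bias_accs = bias_accs,
       checksum_before = before, checksum_after = .bc_checksum(bc$bcast))
}

#' Run the batch EM on local worker processes
#'
#' The broadcast/accumulate executor: fragments are partitioned and the
#' compiled partitions cached on `n_workers` local R processes
#' (round-robin by ordinal). Each round the master broadcasts the current
#' parameter snapshot, workers map the E-step over their partitions (and,
#' on auxiliary-update rounds with bias enabled, the expected-window
#' accumulation over target partitions), and the master combines the
#' accumulators in ascending ordinal order before the M-step. Results are
#' contractually equal to [run_em()] (identical arithmetic per partition;
#' a deterministic reduction order), and bit-identical across worker
#' counts at a fixed partition size.
#'
#' A failed worker round is retried once on the master for the affected
#' partitions, then raises a hard error.
#'
#' @param fragments List of [fragment_record()]s.
#' @param targets List of [target_record()]s.
#' @param cfg An [em_config()]; `partition_size` and
#'   `target_partition_size` control the partitioning.
#' @param n_workers Number of local worker processes (>= 1).
#' @param init_tau,n_iters As in [run_em()].
#' @return An `em_result`, as from [run_em()].
#' @export
run_em_parallel <- function(fragments, targets, cfg = em_config(),
                            n_workers = 2L, init_tau = NULL, n_iters = NULL) {
  stopifnot(n_workers >= 1L, length(fragments) >= 1L, length(targets) >= 1L)
  ti <- .target_info(targets, cfg)
  parts <- partition_fragments(fragments, cfg$partition_size)
  n_parts <- length(parts)
  chunks <- lapply(parts, function(p) .compile_chunk(p$fragments, ti, cfg))
  tparts <- if (cfg$bias_enabled) partition_targets(targets, cfg$target_partition_size) else list()
  slides <- lapply(tparts, function(tp) {
    lens <- vapply(tp$targets, `[[`, integer(1), "length")
    codes <- lapply(tp$targets, function(t) .unpack_codes(t$seq, t$length))
    lti <- list(n = length(tp$targets), codes = codes, lens = lens,
                off = c(0L, cumsum(lens))[seq_along(lens)])
    list(slide = .slide_cache(lti, cfg),
         ids = vapply(tp$targets, `[[`, integer(1), "id"), lens = lens)
  })

  cl <- parallel::makePSOCKcluster(n_workers)
  on.exit(parallel::stopCluster(cl), add = TRUE)
  lp <- .libPaths()
  parallel::clusterCall(cl, function(paths) {
    .libPaths(paths)
    loadNamespace("fragem")
    TRUE
  }, lp)
  w_of_part <- ((seq_len(n_parts) - 1L) %% n_workers) + 1L
  w_of_tpart <- if (length(slides)) ((seq_along(slides) - 1L) %% n_workers) + 1L else integer(0)
  for (w in seq_len(n_workers)) {
    sel <- which(w_of_part == w)
    tsel <- which(w_of_tpart == w)
    parallel::clusterCall(cl[w], fragem:::.worker_setup,
                          chunks = chunks[sel], ordinals = sel,
                          slides = slides[tsel], t_ordinals = tsel, cfg = cfg)
  }

  shape <- .acc_shape(ti$n, cfg)
  params <- .init_params(ti$n, cfg, init_tau)
  loglik_trace <- numeric(0)
  relchg_trace <- numeric(0)
  mass_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  last_acc <- NULL
  aux_version <- 0L
  max_iters <- if (is.null(n_iters)) cfg$max_iters else as.integer(n_iters)
  ap <- cfg$abundance_pseudocount
  if (is.null(ap)) ap <- 1e-8 * length(fragments)

  run_round <- function(bc) {
    res <- vector("list", n_workers)
    for (w in seq_len(n_workers)) {
      res[[w]] <- tryCatch(
        parallel::clusterCall(cl[w], fragem:::.worker_round, bc = bc)[[1L]],
        error = function(e) e)
    }
    # retry failed workers once on the master
    for (w in seq_len(n_workers)) {
      if (inherits(res[[w]], "error")) {
        warning(sprintf("worker %d failed (%s); retrying its partitions on the master",
                        w, conditionMessage(res[[w]])), call. = FALSE)
        sel <- which(w_of_part == w)
        tsel <- which(w_of_tpart == w)
        retry <- tryCatch({
          .worker_setup(chunks[sel], sel, slides[tsel], tsel, cfg)
          .worker_round(bc)
        }, error = function(e) {
          stop(sprintf("partition(s) %s failed after retry: %s",
                       paste(sel, collapse = ","), conditionMessage(e)), call. = FALSE)
        })
        res[[w]] <- retry
      }
    }
    res
  }

  eff <- .eff_lengths(ti$lens, params$fld)   # initial chains equal: no adjustment
  while (iter < max_iters) {
    iter <- iter + 1L
    want_aux <- aux_update_due(iter, cfg)
    bcast <- broadcast_params(params, iter)
    chk0 <- .bc_checksum(bcast)
    bc <- list(shape = shape, bcast = bcast, log_eff = log(eff),
               want_aux = want_aux, aux_version = aux_version,
               want_bias_expected = FALSE)
    res <- run_round(bc)
    for (r in res) {
      if (any(c(r$checksum_before, r$checksum_after) != chk0)) {
        stop("broadcast snapshot was mutated by a worker", call. = FALSE)
      }
    }
    # combine E-step accumulators in ascending partition ordinal order
    accs <- vector("list", n_parts)
    for (r in res) for (i in seq_along(r$ordinals)) accs[[r$ordinals[i]]] <- r$accs[[i]]
    acc <- combine_accumulators(accs, shape)
    last_acc <- acc
    loglik_trace <- c(loglik_trace, acc$loglik)
    mass_trace <- c(mass_trace, acc$mass)
    prev_tau <- params$tau

    # M-step on the master; bias expected counts via the target partitions
    params <- .params_set_tau(params, m_step_normalize(acc$counts, ap))
    if (want_aux) {
      params$fld <- .fld_set(params$fld, m_step_normalize(acc$fld_counts, cfg$pseudocount))
      ec <- acc$err_counts + cfg$pseudocount
      grp <- rep(seq_len(length(ec) %/% 4L), each = 4L)
      tot <- rowsum(ec, grp)
      p <- aperm(array(ec / tot[grp], dim = c(4L, 4L, cfg$max_read_len, 2L)), c(4L, 3L, 2L, 1L))
      params$err <- .err_set(params$err, p)
      if (cfg$bias_enabled) {
        params$bias$obs5 <- .chain_normalize(params$bias$obs5, acc$b5_counts, cfg$pseudocount)
        params$bias$obs3 <- .chain_normalize(params$bias$obs3, acc$b3_counts, cfg$pseudocount)
        eff2 <- .eff_lengths(ti$lens, params$fld)
        bc2 <- list(shape = shape, bcast = bcast, log_eff = log(eff2),
                    want_aux = FALSE, aux_version = aux_version,
                    want_bias_expected = TRUE,
                    next_tau = params$tau, next_eff = eff2, next_fld = params$fld)
        res2 <- run_round(bc2)
        baccs <- vector("list", length(slides))
        for (r in res2) {
          if (!is.null(r$bias_accs)) {
            for (i in seq_along(r$t_ordinals)) baccs[[r$t_ordinals[i]]] <- r$bias_accs[[i]]
          }
        }
        bacc <- combine_accumulators(baccs, shape)
        params$bias$exp5 <- .chain_normalize(params$bias$exp5,
                                             .rescale_mass(bacc$b5_counts, sum(acc$b5_counts)),
                                             cfg$pseudocount)
        params$bias$exp3 <- .chain_normalize(params$bias$exp3,
                                             .rescale_mass(bacc$b3_counts, sum(acc$b3_counts)),
                                             cfg$pseudocount)
      }
      aux_version <- aux_version + 1L
      eff <- .eff_lengths(ti$lens, params$fld)
      if (cfg$bias_enabled) {
        adj <- numeric(ti$n)
        for (sl in slides) {
          adj[sl$ids + 1L] <- .bias_adjusted_eff(sl$slide, params$bias, params$fld,
                                                 sl$lens, eff[sl$ids + 1L])
        }
        eff <- adj
      }
    }
    sel <- params$tau >= cfg$min_prob
    relchg_trace <- c(relchg_trace,
                      if (any(sel)) max(abs(params$tau[sel] - prev_tau[sel]) / prev_tau[sel]) else 0)
    if (is.null(n_iters) && check_convergence(prev_tau, params$tau, cfg)) {
      converged <- TRUE
      break
    }
  }
  structure(list(params = params,
                 counts = last_acc$counts,
                 tau = params$tau,
                 eff_lengths = eff,
                 target_names = ti$names,
                 target_lengths = ti$lens,
                 n_fragments = length(fragments),
                 iterations = iter,
                 converged = converged,
                 loglik_trace = loglik_trace,
                 max_rel_change_trace = relchg_trace,
                 mass_trace = mass_trace),
            class = "em_result")
}
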