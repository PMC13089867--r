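#' Sample inter-stimulus intervals under a model-decorrelation constraint
#'
#' ISIs are i.i.d. draws from a truncated exponential distribution whose
#' post-truncation mean equals `mean`. When a condition sequence and one or
#' more model RDMs are supplied, the drawn ISIs are permuted until, for
#' every model, the absolute Spearman correlation between the ISI following
#' trial t and the model distance between the conditions of trials t and
#' t+1 is below `max_rho`; this prevents temporal autocorrelation of the
#' design from mimicking model structure.
#'
#' @param n Number of intervals.
#' @param mean Target mean in seconds (3 s in the scanner, 2.5 s during
#'   eyetracking).
#' @param bounds Truncation bounds in seconds; default `c(0.5, 8)`.
#' @param models List of [rdm()] model matrices used for the constraint;
#'   empty list skips the permutation search.
#' @param conditions Integer condition sequence (length `n`); required when
#'   `models` is non-empty.
#' @param max_rho Constraint bound on |Spearman|, default 0.1.
#' @param max_tries Permutation search budget, default 10000.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` ISIs with attributes `tries` (permutations
#'   used) and `rho` (achieved correlation per model).
#' @export
sample_isi_sequence <- function(n, mean, bounds = c(0.5, 8), models = list(),
                                conditions = NULL, max_rho = 0.1,
                                max_tries = 10000, seed = NULL) {
  stopifnot(n >= 1, mean > bounds[1], mean < bounds[2])
  with_seed(seed, {
    isi <- rtruncexp(n, mean, bounds)
    if (!length(models)) {
      attr(isi, "tries") <- 0L
      attr(isi, "rho") <- numeric(0)
      return(isi)
    }
    stopifnot(!is.null(conditions), length(conditions) == n)
    dists <- lapply(models, function(m) {
      m <- unclass(m)
      m[cbind(conditions[-n], conditions[-1])]
    })
    rho_of <- function(x) {
      vapply(dists, function(d) {
        if (stats::sd(d) == 0 || stats::sd(x[-n]) == 0) return(0)
        stats::cor(x[-n], d, method = "spearman")
      }, numeric(1))
    }
    best <- isi
    best_rho <- rho_of(isi)
    tries <- 0L
    while (max(abs(best_rho)) >= max_rho && tries < max_tries) {
      tries <- tries + 1L
      cand <- sample(isi)
      r <- rho_of(cand)
      if (max(abs(r)) < max(abs(best_rho))) {
        best <- cand
        best_rho <- r
      }
    }
    if (max(abs(best_rho)) >= max_rho) {
      stop(sprintf("constraint-failure: best |rho| = %.3f after %d permutations",
                   max(abs(best_rho)), tries), call. = FALSE)
    }
    attr(best, "tries") <- tries
    attr(best, "rho") <- best_rho
    best
  })
}

# truncated exponential on [a, b]: rate solved so the truncated mean hits
# `mean`; inverse-CDF sampling
rtruncexp <- function(n, mean, bounds) {
  a <- bounds[1]; b <- bounds[2]
  stopifnot(mean > a, mean < b)
  tmean <- function(l) {
    if (abs(l) < 1e-9) return((a + b) / 2)
    1 / l + (a * exp(-l * a) - b * exp(-l * b)) / (exp(-l * a) - exp(-l * b))
  }
  # mean below midpoint => positive rate; above => negative
  lam <- stats::uniroot(function(l) tmean(l) - mean, c(-50, 50),
                        tol = 1e-10)$root
  if (abs(lam) < 1e-9) return(stats::runif(n, a, b))
  u <- stats::runif(n)
  fa <- exp(-lam * a); fb <- exp(-lam * b)
  -log(fa - u * (fa - fb)) / lam
}

# serially balanced condition sequence: n_stim trials, equal condition
# counts, ordered-transition counts with spread <= 1; greedy min-count walk
# with random restarts
balanced_condition_sequence <- function(n_stim, max_restarts = 1000) {
  stopifnot(n_stim %% 4 == 0, n_stim >= 8)
  cap <- ceiling((n_stim - 1) / 16)
  for (r in seq_len(max_restarts)) {
    counts <- matrix(0L, 4, 4)
    rem <- rep(n_stim %/% 4L, 4)
    seqv <- integer(n_stim)
    cur <- sample.int(4, 1)
    seqv[1] <- cur
    rem[cur] <- rem[cur] - 1L
    ok <- TRUE
    for (t in seq_len(n_stim)[-1]) {
      feas <- which(rem > 0 & counts[cur, ] < cap)
      if (!length(feas)) { ok <- FALSE; break }
      mins <- feas[counts[cur, feas] == min(counts[cur, feas])]
      nxt <- if (length(mins) == 1) mins else sample(mins, 1)
      counts[cur, nxt] <- counts[cur, nxt] + 1L
      rem[nxt] <- rem[nxt] - 1L
      seqv[t] <- nxt
      cur <- nxt
    }
    if (ok && (max(counts) - min(counts)) <= 1L) return(seqv)
  }
  stop("counterbalancing search failed; check trial counts", call. = FALSE)
}

#' Generate one run of the recall task
#'
#' Produces the ordered trial table for a single eyetracker or fMRI run:
#' stimulus trials with counterbalanced condition transitions (every ordered
#' state pair precedes every state a near-equal number of times), plus probe
#' trials attached to a quarter of the stimulus trials at pseudorandom,
#' non-adjacent positions. Half of the probes present the true successor
#' pair. ISIs follow [sample_isi_sequence()].
#'
#' @param graph A [build_graph()] object.
#' @param session `"fmri"` (response window 1.4 s, ISI mean 3 s) or
#'   `"eyetracker"` (1.2 s, 2.5 s).
#' @param n_trials Total trials per run (default 80).
#' @param n_probe Probe trials per run (default 16).
#' @param run Run id stored in the table.
#' @param isi_models List of model [rdm()]s for the ISI decorrelation
#'   constraint. `NULL` (default) uses the affordance, link-distance and
#'   magnitude models; `list()` skips the constraint.
#' @param stim_duration Stimulus presentation time in seconds (default 1.5).
#' @param start Onset of the first trial in seconds (default 2).
#' @param seed Optional integer seed; the same seed reproduces the run
#'   exactly.
#' @return A tibble with one row per trial: `trial`, `type`, `number`,
#'   `state`, `onset`, `duration`, `isi`, `is_probe`, `probe_lo`,
#'   `probe_hi`, `probe_correct`, `response_window`, `run`, `session`.
#' @export
generate_run_sequence <- function(graph, session = c("fmri", "eyetracker"),
                                  n_trials = 80, n_probe = 16, run = 1L,
                                  isi_models = NULL, stim_duration = 1.5,
                                  start = 2, seed = NULL) {
  session <- match.arg(session)
  n_stim <- n_trials - n_probe
  if (n_stim <= 0 || n_stim %% 4 != 0) {
    stop("infeasible-design: (n_trials - n_probe) must be a positive multiple of 4",
         call. = FALSE)
  }
  if (is.null(isi_models)) {
    isi_models <- list(affordance_rdm(graph), linkdist_rdm(graph),
                       magnitude_rdm(graph))
  }
  isi_mean <- if (session == "fmri") 3.0 else 2.5
  rw <- if (session == "fmri") 1.4 else 1.2
  with_seed(seed, {
    cond <- balanced_condition_sequence(n_stim)
    # assign each stimulus trial a number of the right state
    nums <- graph_numbers(graph)
    by_state <- split(nums, state_of(nums, graph))
    number <- vapply(cond, function(s) {
      pool <- by_state[[as.character(s)]]
      pool[sample.int(length(pool), 1)]
    }, integer(1))
    isi <- sample_isi_sequence(n_stim, isi_mean, models = isi_models,
                               conditions = cond)
    # non-adjacent probe positions, uniform over valid configurations
    probe_after <- sort(sample.int(n_stim - n_probe + 1L, n_probe)) +
      seq_len(n_probe) - 1L
    probe_correct <- sample(rep(c(TRUE, FALSE), length.out = n_probe))
    probe_isi <- rtruncexp(n_probe, isi_mean, c(0.5, 8))

    rows <- vector("list", n_trials)
    onset <- start
    k <- 0L
    pi <- 0L
    for (t in seq_len(n_stim)) {
      k <- k + 1L
      rows[[k]] <- list(type = "stimulus", number = number[t],
                        state = cond[t], onset = onset,
                        duration = stim_duration, isi = isi[t],
                        is_probe = FALSE, probe_lo = NA_integer_,
                        probe_hi = NA_integer_, probe_correct = NA)
      onset <- onset + stim_duration + isi[t]
      if (t %in% probe_after) {
        pi <- pi + 1L
        k <- k + 1L
        pair <- successors(number[t], graph)
        if (!probe_correct[pi]) {
          # foil: shift one element by 1 toward an invalid pair
          idx <- sample.int(2, 1)
          shift <- sample(c(-1L, 1L), 1)
          pair[idx] <- pair[idx] + shift
          if (pair[1] == pair[2]) pair[idx] <- pair[idx] + 2L * shift
          pair <- sort(pair)
        }
        rows[[k]] <- list(type = "probe", number = NA_integer_,
                          state = NA_integer_, onset = onset,
                          duration = rw, isi = probe_isi[pi],
                          is_probe = TRUE, probe_lo = pair[1],
                          probe_hi = pair[2], probe_correct = probe_correct[pi])
        onset <- onset + rw + probe_isi[pi]
      }
    }
    out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    out$trial <- seq_len(nrow(out))
    out$response_window <- rw
    out$run <- as.integer(run)
    out$session <- session
    dplyr::relocate(out, "trial")
  })
}

#' Ordered condition-transition counts of a run
#'
#' @param trials A tibble from [generate_run_sequence()] (or any table with
#'   `type` and `state` columns).
#' @return 4x4 integer matrix: entry (i, j) counts stimulus trials of state
#'   j immediately preceded (among stimulus trials) by state i.
#' @export
transition_counts <- function(trials) {
  s <- trials$state[trials$type == "stimulus"]
  m <- matrix(0L, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  for (t in seq_along(s)[-1]) m[s[t - 1], s[t]] <- m[s[t - 1], s[t]] + 1L
  m
}

#' Training schedule of interleaved exploration and test blocks
#'
#' Each block pairs 16 free-exploration trials with 18 feedback test trials;
#' extended generalization tests of 24 trials on previously unseen numbers
#' (no feedback) are inserted after the listed blocks.
#'
#' @param n_blocks Number of training blocks.
#' @param extended_after Integer vector of block indices after which an
#'   extended test occurs (may be empty).
#' @param exploration_trials,test_trials,extended_trials Per-block counts.
#' @return A list of class `training_schedule` with tibbles `blocks` and
#'   `extended`, plus totals `n_test_trials` and `n_generalization_trials`.
#' @examples
#' sched <- make_training_schedule(40, extended_after = c(20, 40))
#' sched$n_test_trials # 720
#' @export
make_training_schedule <- function(n_blocks, extended_after = integer(),
                                   exploration_trials = 16, test_trials = 18,
                                   extended_trials = 24) {
  stopifnot(n_blocks >= 1, all(extended_after >= 1 & extended_after <= n_blocks))
  blocks <- tibble::tibble(
    block = seq_len(n_blocks),
    exploration_trials = as.integer(exploration_trials),
    test_trials = as.integer(test_trials)
  )
  extended <- tibble::tibble(
    after_block = as.integer(extended_after),
    n_trials = as.integer(extended_trials),
    feedback = FALSE
  )
  structure(
    list(blocks = blocks, extended = extended,
         n_test_trials = sum(blocks$test_trials),
         n_generalization_trials = sum(extended$n_trials)),
    class = "training_schedule"
  )
}

#' @export
print.training_schedule <- function(x, ...) {
  cat(sprintf("<training_schedule> %d blocks (%d test trials), %d extended test(s) (%d trials)\n",
              nrow(x$blocks), x$n_test_trials, nrow(x$extended),
              x$n_generalization_trials))
  invisible(x)
}

#' Write / read a run's events table as BIDS-style TSV
#'
#' Columns: `onset`, `duration`, `trial_type` (`state1`..`state4` or
#' `probe`), `number`, `isi`, `probe_correct`, `response_window`.
#'
#' @param trials Tibble from [generate_run_sequence()].
#' @param path File path for the TSV.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns a trial tibble equivalent to the one written.
#' @export
write_events_tsv <- function(trials, path) {
  ev <- tibble::tibble(
    onset = trials$onset,
    duration = trials$duration,
    trial_type = ifelse(trials$type == "probe", "probe",
                        paste0("state", trials$state)),
    number = trials$number,
    isi = trials$isi,
    probe_lo = trials$probe_lo,
    probe_hi = trials$probe_hi,
    probe_correct = trials$probe_correct,
    response_window = trials$response_window,
    run = trials$run,
    session = trials$session
  )
  readr::write_tsv(ev, path, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                        progress = FALSE)
  state <- rep(NA_integer_, nrow(ev))
  is_stim <- ev$trial_type != "probe"
  state[is_stim] <- as.integer(sub("state", "", ev$trial_type[is_stim]))
  tibble::tibble(
    trial = seq_len(nrow(ev)),
    type = ifelse(ev$trial_type == "probe", "probe", "stimulus"),
    number = as.integer(ev$number),
    state = state,
    onset = ev$onset,
    duration = ev$duration,
    isi = ev$isi,
    is_probe = ev$trial_type == "probe",
    probe_lo = as.integer(ev$probe_lo),
    probe_hi = as.integer(ev$probe_hi),
    probe_correct = as.logical(ev$probe_correct),
    response_window = ev$response_window,
    run = as.integer(ev$run),
    session = ev$session
  )
}
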