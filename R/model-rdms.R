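#' Shared-affordance model RDM
#'
#' The main hypothesis matrix: states affording similar actions should evoke
#' similar neural patterns. Dissimilarity between states i and j is the
#' number of shared signed actions subtracted from the maximum of 2:
#' `2 - |A_i intersect A_j|`. With the default affordances, states 1 and 4
#' share both actions (dissimilarity 0) and states 1 and 2 share only +2
#' (dissimilarity 1).
#'
#' @param graph A [build_graph()] object.
#' @return An [rdm()] with entries in 0..2.
#' @export
affordance_rdm <- function(graph) {
  count_rdm(lapply(graph$affordances, identity), type = "affordance")
}

#' Action-magnitude model RDM
#'
#' Control model: dissimilarity based on shared unsigned action magnitudes,
#' ignoring sign. By default magnitudes are treated as multisets (state 1's
#' \{2, 2\} shares both elements with state 4's \{2, 2\} but only one with
#' state 2's \{1, 2\}), which preserves the two-action count symmetry of the
#' affordance model; `multiset = FALSE` gives the plain-set reading.
#'
#' @param graph A [build_graph()] object.
#' @param multiset Count shared magnitudes with multiplicity (default TRUE).
#' @return An [rdm()] with entries in 0..2.
#' @export
magnitude_rdm <- function(graph, multiset = TRUE) {
  mags <- lapply(graph$affordances, abs)
  if (!multiset) mags <- lapply(mags, unique)
  count_rdm(mags, type = "magnitude", max_count = 2)
}

# generic "2 minus shared-element count" dissimilarity over per-state
# (multi)sets; multiset intersection size via pmin of tabulations
count_rdm <- function(sets, type, max_count = 2) {
  shared <- function(a, b) {
    vals <- union(a, b)
    sum(pmin(tabulate(match(a, vals), length(vals)),
             tabulate(match(b, vals), length(vals))))
  }
  m <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    m[i, j] <- max_count - shared(sets[[i]], sets[[j]])
    m[j, i] <- m[i, j]
  }
  rdm(m, type = type)
}

#' Link-distance model RDM
#'
#' Control model: minimum number of afforded-action steps between states on
#' the state-transition graph (see [link_distance_matrix()]).
#'
#' @param graph A [build_graph()] object.
#' @return An [rdm()].
#' @export
linkdist_rdm <- function(graph) {
  rdm(unname(link_distance_matrix(graph)), type = "linkdist")
}

#' Shared-successor-state model RDM
#'
#' Dissimilarity `2 - |succ(i) intersect succ(j)|` where `succ(s)` is the set
#' of states reachable from s in one action. Provided so the relation
#' between the magnitude model and next-state prediction can be computed
#' rather than assumed; see the package vignette.
#'
#' @param graph A [build_graph()] object.
#' @return An [rdm()].
#' @export
shared_successor_rdm <- function(graph) {
  count_rdm(state_transitions(graph), type = "shared_successor")
}

#' Behavioral model RDM from per-state summaries
#'
#' Builds a participant-specific model RDM from one summary value per state:
#' either a scalar (e.g. mean probe-trial reaction time, compared by
#' absolute difference) or a 2-D point (e.g. median gaze position, compared
#' by Euclidean distance).
#'
#' @param per_state_values For `metric = "absdiff"`, a numeric vector of
#'   length 4 (names or order = states 1..4). For `metric = "euclidean"`, a
#'   4x2 matrix / data frame of (x, y) rows, or a list of length-2 vectors.
#' @param metric `"absdiff"` or `"euclidean"`.
#' @return An [rdm()].
#' @examples
#' behavior_rdm(c(0.5, 0.7, 0.7, 0.5)) # reaction-time model
#' @export
behavior_rdm <- function(per_state_values, metric = c("absdiff", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "absdiff") {
    v <- unlist(per_state_values)
    if (length(v) != 4 || anyNA(v)) {
      stop("incomplete-input: need one finite value per state", call. = FALSE)
    }
    if (!is.null(names(v)) && all(as.character(1:4) %in% names(v))) {
      v <- v[as.character(1:4)]
    }
    m <- abs(outer(v, v, `-`))
  } else {
    if (is.list(per_state_values)) per_state_values <- do.call(rbind, per_state_values)
    xy <- as.matrix(per_state_values)
    if (nrow(xy) != 4 || ncol(xy) != 2 || anyNA(xy)) {
      stop("incomplete-input: need one (x, y) pair per state", call. = FALSE)
    }
    m <- as.matrix(stats::dist(xy))
  }
  rdm(unname(m), type = paste0("behavior_", metric))
}
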