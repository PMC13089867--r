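#' Default affordance sets of the four task states
#'
#' Each state on the repeating number-line graph affords exactly two signed
#' numerical operations: state 1 affords -2/+2, state 2 affords +1/+2,
#' state 3 affords -2/-1, and state 4 affords -2/+2.
#'
#' @return Named list of length 4; element `s` is the integer action set of
#'   state `s`.
#' @export
default_affordances <- function() {
  list(`1` = c(-2L, 2L), `2` = c(1L, 2L), `3` = c(-2L, -1L), `4` = c(-2L, 2L))
}

#' Build a repeating state-action graph on the number line
#'
#' The task space is a module of four consecutive state-bearing numbers
#' (states 1 to 4) followed by one unused "gap" number, tiled along the
#' number line with period 5. All numbers are restricted to be greater than
#' 20 to avoid interference from over-learned single-digit arithmetic;
#' shifting `offset` relabels the numbers without changing the state-level
#' structure, which is how number-state mappings are counterbalanced across
#' participants.
#'
#' @param offset Integer > 20; the smallest state-bearing number (state 1 of
#'   the first module).
#' @param n_modules Positive integer; number of tiled modules.
#' @param affordances Named list mapping state ids `"1"`..`"4"` to integer
#'   action sets; defaults to [default_affordances()]. Overriding breaks the
#'   guarantees of the standard design and is only checked for closure.
#' @return An object of class `state_action_graph` with fields `offset`,
#'   `n_modules`, `period` (always 5) and `affordances`.
#' @examples
#' g <- build_graph(21, 2)
#' state_of(26, g) # 1
#' successors(23, g) # 21 22
#' @export
build_graph <- function(offset, n_modules, affordances = default_affordances()) {
  offset <- as.integer(offset)
  n_modules <- as.integer(n_modules)
  if (length(offset) != 1 || is.na(offset) || offset <= 20) {
    stop("invalid-offset: all task numbers must be greater than 20", call. = FALSE)
  }
  if (length(n_modules) != 1 || is.na(n_modules) || n_modules < 1) {
    stop("n_modules must be a positive integer", call. = FALSE)
  }
  stopifnot(is.list(affordances), length(affordances) == 4)
  names(affordances) <- as.character(1:4)
  affordances <- lapply(affordances, function(a) sort(as.integer(a)))
  g <- structure(
    list(offset = offset, n_modules = n_modules, period = 5L,
         affordances = affordances),
    class = "state_action_graph"
  )
  if (!graph_is_closed(g)) {
    stop("affordance override breaks graph closure: an action leaves the state-bearing slots",
         call. = FALSE)
  }
  g
}

# Closure at the state level under infinite period-5 tiling: every action
# applied at state slot j (0-based) must land on a slot in 0..3, never the
# gap slot 4.
graph_is_closed <- function(graph) {
  for (s in 1:4) {
    for (a in graph$affordances[[as.character(s)]]) {
      if (((s - 1 + a) %% graph$period) > 3) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.state_action_graph <- function(x, ...) {
  rng <- graph_numbers(x)
  cat("<state_action_graph>\n")
  cat(sprintf("  offset %d, %d module(s), period %d; numbers %d..%d (%d state-bearing)\n",
              x$offset, x$n_modules, x$period, min(rng), max(rng), length(rng)))
  for (s in 1:4) {
    cat(sprintf("  state %d affords %s\n", s,
                paste(sprintf("%+d", x$affordances[[as.character(s)]]), collapse = ", ")))
  }
  invisible(x)
}

#' All state-bearing numbers of a graph
#'
#' @param graph A [build_graph()] object.
#' @return Sorted integer vector of the `4 * n_modules` state-bearing numbers.
#' @export
graph_numbers <- function(graph) {
  as.integer(outer(0:3, graph$offset + graph$period * (seq_len(graph$n_modules) - 1L), `+`))
}

#' State identity of a number
#'
#' @param number Integer vector of numbers.
#' @param graph A [build_graph()] object.
#' @return Integer vector: state id 1..4 for state-bearing numbers, `NA` for
#'   gap numbers and numbers outside the graph's range.
#' @export
state_of <- function(number, graph) {
  number <- as.integer(number)
  rel <- number - graph$offset
  slot <- rel %% graph$period
  in_range <- rel >= 0L & rel < graph$period * graph$n_modules
  out <- ifelse(in_range & slot <= 3L, slot + 1L, NA_integer_)
  as.integer(out)
}

#' Successor numbers afforded by a state-bearing number
#'
#' Applies the two actions afforded by the number's state and returns the two
#' reachable numbers in ascending order. For example, with default
#' affordances a state-2 number 49 affords +1/+2, so its successors are 50
#' and 51.
#'
#' @param number A single state-bearing number.
#' @param graph A [build_graph()] object.
#' @return Integer vector of length 2, sorted ascending.
#' @export
successors <- function(number, graph) {
  s <- state_of(number, graph)
  if (is.na(s)) {
    stop("not-a-state: ", number, " is a gap number or outside the graph", call. = FALSE)
  }
  sort(as.integer(number) + graph$affordances[[as.character(s)]])
}

#' State-level transition targets
#'
#' @param graph A [build_graph()] object.
#' @return Named list: element `s` holds the state ids reachable from state
#'   `s` in one afforded action (under period-5 tiling).
#' @export
state_transitions <- function(graph) {
  out <- lapply(1:4, function(s) {
    slots <- (s - 1 + graph$affordances[[as.character(s)]]) %% graph$period
    sort(unique(as.integer(slots + 1L)))
  })
  names(out) <- as.character(1:4)
  out
}

#' Link-distance matrix between states
#'
#' Minimum number of afforded-action steps between any two states, computed
#' by breadth-first search over the 4-node state-transition graph. Edges are
#' treated as undirected; under the default affordances every transition is
#' reciprocated so the directed and undirected readings coincide.
#'
#' @param graph A [build_graph()] object.
#' @return 4x4 symmetric integer matrix with zero diagonal; unreachable
#'   pairs (possible only under overridden affordances) are `Inf`.
#' @export
link_distance_matrix <- function(graph) {
  trans <- state_transitions(graph)
  # undirected adjacency
  adj <- matrix(FALSE, 4, 4)
  for (s in 1:4) for (t in trans[[s]]) {
    adj[s, t] <- TRUE
    adj[t, s] <- TRUE
  }
  d <- matrix(Inf, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  for (s in 1:4) {
    dist <- rep(Inf, 4)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ])) {
          if (dist[w] > dist[v] + 1) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
  }
  d
}

#' Serialize / read a graph as JSON
#'
#' @param graph A [build_graph()] object.
#' @param path File path.
#' @return `write_graph_json` returns `path` invisibly; `read_graph_json`
#'   returns the reconstructed graph.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(offset = graph$offset, n_modules = graph$n_modules,
         period = graph$period, affordances = graph$affordances),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_graph(x$offset, x$n_modules, affordances = as.list(x$affordances))
}
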