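#' Build a promoter-state architecture
#'
#' A promoter architecture is a continuous-time Markov chain over the
#' binding states of the promoter together with a transcription-initiation
#' rate for each state. It is stored as the generator matrix `K` in the
#' column convention, `dP/dt = K P`: entry `K[i, j]` (`i != j`) is the rate
#' of the jump from state `j` to state `i`, and each diagonal entry is
#' minus the total outflux of its column, so columns sum to zero. The
#' transpose (row) convention is equally common in the Markov-chain
#' literature; this package uses the column convention throughout, so the
#' stationary state-occupancy vector `p` satisfies `K p = 0`.
#'
#' State order is the declaration order of `states` and is preserved in
#' every downstream vector and matrix.
#'
#' @param states character vector of distinct state labels (length N >= 1).
#' @param transitions transitions between states: a data frame with columns
#'   `from`, `to`, `rate` (s^-1), or a list of `list(from, to, rate)`
#'   triplets. May be empty for a one-state promoter.
#' @param transcription_rates numeric vector, one nonnegative
#'   transcription-initiation rate (mRNA s^-1) per state.
#' @param name free-form name/provenance text.
#' @return An object of class `promoter_architecture` with elements
#'   `states`, `generator`, `transcription_rates`, `transitions`, `name`.
#' @export
#' @examples
#' arch <- promoter_architecture(
#'   states = c("free", "bound"),
#'   transitions = data.frame(from = c("free", "bound"),
#'                            to   = c("bound", "free"),
#'                            rate = c(0.02, 0.01)),
#'   transcription_rates = c(0.33, 0))
#' arch$generator
promoter_architecture <- function(states, transitions = NULL,
                                  transcription_rates, name = "") {
  if (!is.character(states) || length(states) < 1L)
    stop("'states' must be a character vector of length >= 1", call. = FALSE)
  if (anyDuplicated(states))
    stop("duplicate state label(s): ",
         paste(unique(states[duplicated(states)]), collapse = ", "),
         call. = FALSE)
  N <- length(states)
  if (!is.numeric(transcription_rates) || length(transcription_rates) != N)
    stop("'transcription_rates' must be numeric of length ", N, call. = FALSE)
  if (any(!is.finite(transcription_rates)) || any(transcription_rates < 0))
    stop("transcription rates must be finite and >= 0", call. = FALSE)

  tr <- normalize_transitions(transitions)
  K <- matrix(0, N, N, dimnames = list(states, states))
  if (nrow(tr) > 0L) {
    for (i in seq_len(nrow(tr))) {
      from <- tr$from[i]; to <- tr$to[i]; rate <- tr$rate[i]
      if (!from %in% states)
        stop("transition references unknown state label '", from, "'",
             call. = FALSE)
      if (!to %in% states)
        stop("transition references unknown state label '", to, "'",
             call. = FALSE)
      if (!is.finite(rate) || rate < 0)
        stop("negative or non-finite rate for transition ", from, " -> ", to,
             call. = FALSE)
      if (from == to)
        stop("self-transition ", from, " -> ", to, " is not allowed",
             call. = FALSE)
      K[to, from] <- K[to, from] + rate
    }
  }
  diag(K) <- -colSums(K)

  arch <- structure(
    list(states = states, generator = K,
         transcription_rates = as.numeric(transcription_rates),
         transitions = tr, name = name),
    class = "promoter_architecture")
  bad <- validate_architecture(arch)
  if (length(bad))
    stop("invalid promoter architecture:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  arch
}

normalize_transitions <- function(transitions) {
  if (is.null(transitions) ||
      (is.data.frame(transitions) && nrow(transitions) == 0L) ||
      (is.list(transitions) && length(transitions) == 0L))
    return(data.frame(from = character(), to = character(),
                      rate = numeric(), stringsAsFactors = FALSE))
  if (is.data.frame(transitions)) {
    if (!all(c("from", "to", "rate") %in% names(transitions)))
      stop("'transitions' needs columns from, to, rate", call. = FALSE)
    return(data.frame(from = as.character(transitions$from),
                      to = as.character(transitions$to),
                      rate = as.numeric(transitions$rate),
                      stringsAsFactors = FALSE))
  }
  if (is.list(transitions)) {
    return(data.frame(
      from = vapply(transitions, function(t) as.character(t[[1]]), ""),
      to = vapply(transitions, function(t) as.character(t[[2]]), ""),
      rate = vapply(transitions, function(t) as.numeric(t[[3]]), 0),
      stringsAsFactors = FALSE))
  }
  stop("'transitions' must be a data frame or list of triplets",
       call. = FALSE)
}

#' Check the architecture invariants
#'
#' Reports, rather than raises, violations: nonnegative off-diagonal
#' generator entries, columns summing to zero (1e-12 relative),
#' nonnegative transcription rates, and uniqueness of the stationary
#' occupancy vector. The last is checked on the positive-rate digraph
#' (a rate counts as an edge only if strictly positive): the chain must
#' have exactly one closed communicating class. A fully irreducible graph
#' always qualifies; so does a titration endpoint such as `[TF] = 0`,
#' where bound states become transient but the stationary vector is still
#' unique. Two mutually unreachable closed sets of states are a
#' reducibility violation.
#'
#' @param arch a [promoter_architecture()] object.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_architecture <- function(arch) {
  out <- character()
  if (!is.list(arch) || is.null(arch$generator) || is.null(arch$states))
    return("not a promoter_architecture object")
  K <- arch$generator
  N <- length(arch$states)
  if (!is.matrix(K) || nrow(K) != N || ncol(K) != N)
    return(sprintf("generator is not an %d x %d matrix", N, N))
  off <- K; diag(off) <- 0
  if (any(off < 0))
    out <- c(out, "negative off-diagonal generator entry (jump rates must be >= 0)")
  scale <- max(abs(K), 1)
  cs <- colSums(K)
  bad_cols <- which(abs(cs) > 1e-12 * scale)
  for (j in bad_cols)
    out <- c(out, sprintf("column '%s' sums to %g, not 0",
                          arch$states[j], cs[j]))
  r <- arch$transcription_rates
  if (length(r) != N || any(!is.finite(r)) || any(r < 0))
    out <- c(out, "transcription_rates must be finite, >= 0, one per state")
  if (N > 1L && n_closed_classes(off > 0) != 1L)
    out <- c(out, "state graph is reducible: stationary occupancy is not unique (more than one closed communicating class)")
  out
}

# number of closed communicating classes of a directed adjacency matrix
# adj[i, j] TRUE means an edge j -> i (column convention, as the generator)
n_closed_classes <- function(adj) {
  N <- nrow(adj)
  # boolean transitive closure (reach[i, j]: i reachable from j)
  reach <- adj | diag(TRUE, N)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comm <- reach & t(reach)             # mutual reachability -> classes
  classes <- unique(lapply(seq_len(N), function(j) which(comm[, j])))
  closed <- vapply(classes, function(cl) {
    outside <- setdiff(seq_len(N), cl)
    length(outside) == 0L || !any(adj[outside, cl, drop = FALSE])
  }, logical(1))
  sum(closed)
}

#' @export
print.promoter_architecture <- function(x, ...) {
  cat(sprintf("Promoter architecture%s: %d state%s\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(x$states), if (length(x$states) > 1) "s" else ""))
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  transcription rates (s^-1):",
      paste(format(x$transcription_rates), collapse = ", "), "\n")
  if (nrow(x$transitions))
    cat(sprintf("  %d transitions; generator column convention dP/dt = K P\n",
                nrow(x$transitions)))
  invisible(x)
}

#' Summarize an architecture by its steady-state mRNA statistics
#'
#' @param object a [promoter_architecture()] object.
#' @param gamma_m mRNA decay rate, s^-1.
#' @param ... unused.
#' @return A list with the stationary state occupancies and the
#'   [mrna_moments()] result, invisibly; printed as a summary.
#' @export
summary.promoter_architecture <- function(object, gamma_m = 0.011, ...) {
  p <- steady_state_probabilities(object)
  mom <- mrna_moments(object, gamma_m)
  out <- list(occupancy = setNames(p, object$states), moments = mom,
              gamma_m = gamma_m)
  class(out) <- "summary.promoter_architecture"
  out
}

#' @export
print.summary.promoter_architecture <- function(x, ...) {
  cat("Stationary promoter-state occupancy:\n")
  print(round(x$occupancy, 6))
  cat(sprintf("mRNA steady state (gamma_m = %g s^-1):\n", x$gamma_m))
  print(x$moments)
  invisible(x)
}

# ---- JSON round trip ------------------------------------------------------

#' Write / read an architecture as JSON
#'
#' Schema: `{"states": [...], "transitions": [{"from":..,"to":..,"rate":..}],
#' "transcription_rates": [...], "gamma_m": ..., "name": ...}`. `gamma_m`
#' travels alongside the architecture because most downstream computations
#' need it; it is returned as the `"gamma_m"` attribute on read.
#'
#' @param arch a [promoter_architecture()] object.
#' @param path file path.
#' @param gamma_m optional mRNA decay rate to store alongside.
#' @return `write_architecture_json` returns `path` invisibly;
#'   `read_architecture_json` returns the architecture (with attribute
#'   `gamma_m` if present in the file).
#' @export
write_architecture_json <- function(arch, path, gamma_m = NULL) {
  stopifnot(inherits(arch, "promoter_architecture"))
  obj <- list(states = arch$states,
              transitions = arch$transitions,
              transcription_rates = arch$transcription_rates,
              name = arch$name)
  if (!is.null(gamma_m)) obj$gamma_m <- gamma_m
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_architecture_json
#' @export
read_architecture_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(obj),
                   c("states", "transitions", "transcription_rates",
                     "gamma_m", "name"))
  if (length(extra))
    stop("unknown field(s) in architecture JSON: ",
         paste(extra, collapse = ", "), call. = FALSE)
  arch <- promoter_architecture(
    states = as.character(obj$states),
    transitions = obj$transitions,
    transcription_rates = as.numeric(obj$transcription_rates),
    name = if (is.null(obj$name)) "" else obj$name)
  if (!is.null(obj$gamma_m)) attr(arch, "gamma_m") <- obj$gamma_m
  arch
}
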