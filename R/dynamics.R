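#' One asynchronous update step
#'
#' Exactly one node whose image differs from its current value, chosen
#' uniformly at random, moves one step toward its image (a node at -1 with
#' image +1 first passes through 0). External drives never move.
#'
#' @inheritParams image_vector
#' @return The successor state (named ternary vector).
#' @export
asynchronous_step <- function(state, net) {
  x <- as_state(state, net)
  img <- cpp_image(x, net_encode(net))
  disc <- which(img != x)
  if (!length(disc))
    stop("state is a fixed point; test stability before stepping",
         call. = FALSE)
  i <- if (length(disc) == 1L) disc else sample(disc, 1L)
  x[i] <- x[i] + as.integer(sign(img[i] - x[i]))
  names(x) <- net$nodes
  x
}

#' Simulate asynchronously until an attractor (or a step cap)
#'
#' Repeats [asynchronous_step()] until the state equals its image vector or
#' `max_steps` updates have been spent. Cap exhaustion is a valid, flagged
#' outcome (it is how limit cycles surface; only fixed points count as
#' stable states).
#'
#' @inheritParams image_vector
#' @param max_steps maximum number of single-node updates (default 1000).
#' @param record keep the full trajectory (matrix of states) or only the
#'   final state.
#' @return An object of class `ternet_trajectory`: list with `final`,
#'   `steps`, `terminated`, and (if recorded) `states`, a matrix with one
#'   row per visited state. Consecutive recorded states differ in exactly
#'   one node by exactly one step.
#' @export
simulate_to_attractor <- function(state, net, max_steps = 1000,
                                  record = FALSE) {
  stopifnot(max_steps >= 1)
  x <- as_state(state, net)
  res <- cpp_simulate(x, net_encode(net), as.integer(max_steps), record)
  out <- list(final = stats::setNames(res$final, net$nodes),
              steps = res$steps, terminated = res$terminated)
  if (record) {
    colnames(res$trajectory) <- net$nodes
    out$states <- res$trajectory
  }
  structure(out, class = "ternet_trajectory")
}

#' @export
print.ternet_trajectory <- function(x, ...) {
  cat("ternet_trajectory:", x$steps, "step(s),",
      if (x$terminated) "reached a fixed point" else "step cap exhausted",
      "\n")
  invisible(x)
}

#' Monte Carlo attractor discovery
#'
#' Launches asynchronous simulations from uniformly random ternary start
#' states (external drives clamped) and collects the distinct fixed points
#' reached, with basin visit counts. Runs that exhaust the step cap without
#' settling are excluded from the fixed-point set and reported in
#' `n_unterminated`.
#'
#' @inheritParams simulate_to_attractor
#' @param n_starts number of random starts.
#' @return An object of class `ternet_attractors`: list with `fixed_points`
#'   (matrix, one row per distinct fixed point), `counts`, `n_starts`,
#'   `n_unterminated`.
#' @export
find_attractors <- function(net, n_starts = 10000, max_steps = 1000) {
  stopifnot(n_starts >= 1)
  res <- cpp_find_attractors(net_encode(net), as.integer(n_starts),
                             as.integer(max_steps))
  fp <- res$fixed_points
  colnames(fp) <- net$nodes
  o <- order(res$counts, decreasing = TRUE)
  structure(list(fixed_points = fp[o, , drop = FALSE],
                 counts = res$counts[o],
                 n_starts = n_starts,
                 n_unterminated = res$n_unterminated),
            class = "ternet_attractors")
}

#' @export
print.ternet_attractors <- function(x, ...) {
  cat("ternet_attractors:", nrow(x$fixed_points), "fixed point(s) from",
      x$n_starts, "random starts")
  if (x$n_unterminated > 0)
    cat(" (", x$n_unterminated, " run(s) hit the step cap)", sep = "")
  cat("\n")
  invisible(x)
}

#' Exhaustive fixed-point enumeration (small networks)
#'
#' Brute-force scan of all 3^N states of the non-external nodes (external
#' drives held at their clamp). Serves as the independent oracle for the
#' Monte Carlo search on toy networks.
#'
#' @inheritParams image_vector
#' @param cap refuse networks with more free nodes than this (3^N states).
#' @return Matrix with one row per fixed point, columns named by node.
#' @export
enumerate_fixed_points <- function(net, cap = 12) {
  nfree <- sum(!net$external)
  if (nfree > cap)
    stop("network has ", nfree, " free nodes (> cap = ", cap,
         "); use find_attractors() instead", call. = FALSE)
  m <- cpp_enumerate(net_encode(net))
  colnames(m) <- net$nodes
  m
}

# canonical string keys for state rows, used to compare attractor sets
state_keys <- function(m) {
  apply(m, 1L, function(r) paste(r, collapse = ","))
}
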