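#' Timed treatment courses
#'
#' A treatment course is an ordered set of single-target timed interventions.
#' Each intervention either supplements (+1) or inhibits (-1) one node over
#' an inclusive window of timesteps. While a window is active the targeted
#' node is set to the clipped sum of its value and the effect at every step
#' (so it is driven to, and held at, the corresponding extreme) and is pinned
#' against the asynchronous scheduler; untargeted nodes keep evolving one
#' asynchronous update per step. Time is counted in asynchronous update
#' steps.
#'
#' @param target character vector of targeted node ids.
#' @param effect +1 (supplement) or -1 (inhibit), one per intervention.
#' @param t_start,t_stop inclusive window bounds (integer steps,
#'   `t_start <= t_stop`).
#' @param allowed optional character vector restricting admissible targets.
#' @return An object of class `ternet_course` (a data.frame).
#' @export
treatment_course <- function(target = character(), effect = integer(),
                             t_start = integer(), t_stop = integer(),
                             allowed = NULL) {
  n <- length(target)
  if (length(effect) != n || length(t_start) != n || length(t_stop) != n)
    stop("target, effect, t_start, t_stop must have equal length",
         call. = FALSE)
  effect <- as.integer(effect)
  t_start <- as.integer(t_start); t_stop <- as.integer(t_stop)
  if (n) {
    if (!all(effect %in% c(-1L, 1L)))
      stop("effect must be -1 (inhibit) or +1 (supplement)", call. = FALSE)
    if (any(t_start < 1L) || any(t_stop < t_start))
      stop("windows need 1 <= t_start <= t_stop", call. = FALSE)
    if (!is.null(allowed) && !all(target %in% allowed))
      stop("target(s) outside the allowed set: ",
           paste(setdiff(target, allowed), collapse = ", "), call. = FALSE)
  }
  structure(data.frame(target = as.character(target), effect = effect,
                       t_start = t_start, t_stop = t_stop,
                       stringsAsFactors = FALSE),
            class = c("ternet_course", "data.frame"))
}

#' @export
print.ternet_course <- function(x, ...) {
  cat("ternet_course:", nrow(x), "intervention(s)\n")
  if (nrow(x)) {
    lab <- ifelse(x$effect > 0, "increase", "inhibit")
    cat(sprintf("  %s %s  t = %d-%d\n", lab, x$target, x$t_start, x$t_stop),
        sep = "")
  }
  invisible(x)
}

#' Read a treatment course from TSV
#'
#' Columns `target`, `effect`, `t_start`, `t_stop`; `effect` may be given
#' as -1/1 or as `inhibit`/`increase`/`supplement`.
#' @param path file path.
#' @return A `ternet_course`.
#' @export
read_course <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  eff <- d$effect
  if (is.character(eff))
    eff <- ifelse(eff %in% c("increase", "supplement"), 1L,
                  ifelse(eff == "inhibit", -1L, NA_integer_))
  treatment_course(d$target, eff, d$t_start, d$t_stop)
}

# validate a course against a network; overlapping windows may not share a
# target (two active vectors on one node would be ill-formed)
check_course <- function(course, net, horizon) {
  if (!nrow(course)) return(invisible(course))
  bad <- setdiff(course$target, net$nodes)
  if (length(bad))
    stop("course targets unknown node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(course$t_stop > horizon))
    stop("treatment window ends after the simulation horizon", call. = FALSE)
  if (nrow(course) > 1) {
    for (i in seq_len(nrow(course) - 1)) for (j in (i + 1):nrow(course)) {
      if (course$target[i] == course$target[j] &&
          course$t_start[i] <= course$t_stop[j] &&
          course$t_start[j] <= course$t_stop[i])
        stop("two interventions target '", course$target[i],
             "' in overlapping windows", call. = FALSE)
    }
  }
  invisible(course)
}

#' Apply active treatment vectors to a state
#'
#' The targeted nodes move to the clipped sum of their value and the effect
#' (values beyond the ternary range are rounded back into it); all other
#' nodes are unchanged.
#'
#' @inheritParams image_vector
#' @param active a `ternet_course` (or data.frame) of currently active
#'   interventions.
#' @return The treated state.
#' @export
apply_treatment <- function(state, net, active) {
  x <- as_state(state, net)
  if (nrow(active)) {
    if (anyDuplicated(active$target))
      stop("two active treatment vectors on node '",
           active$target[anyDuplicated(active$target)],
           "': ill-formed course", call. = FALSE)
    bad <- setdiff(active$target, net$nodes)
    if (length(bad))
      stop("unknown target node: ", paste(bad, collapse = ", "),
           call. = FALSE)
    i <- match(active$target, net$nodes)
    x[i] <- pmax(-1L, pmin(1L, x[i] + as.integer(active$effect)))
  }
  names(x) <- net$nodes
  x
}

#' Monte Carlo evaluation of a treatment course
#'
#' Simulates `n_runs` asynchronous trajectories from `start`. During each
#' step of an active window the targeted nodes are treated (clipped
#' addition, pinned for the step) while one untreated discrepant node moves;
#' after the last window the run continues untreated until a fixed point or
#' the step cap. The outcome is the percentage of runs that terminate in
#' the healthy state (%HHM).
#'
#' @param course a `ternet_course`.
#' @param start named ternary start state (typically an ill attractor).
#' @param net a [ternet_network].
#' @param n_runs Monte Carlo repetitions (default 1000).
#' @param max_steps step cap per run (default 1000).
#' @param healthy the healthy reference state (default: all-zero).
#' @return An object of class `ternet_outcome`: list with `pct_hhm`,
#'   `n_runs`, `n_healthy`, `n_unterminated`.
#' @export
simulate_course <- function(course, start, net, n_runs = 1000,
                            max_steps = 1000, healthy = NULL) {
  stopifnot(n_runs >= 1, max_steps >= 1)
  check_course(course, net, max_steps)
  x0 <- as_state(start, net)
  if (is.null(healthy)) healthy <- rep(0L, length(net$nodes))
  else healthy <- as_state(healthy, net)
  res <- cpp_simulate_course(
    x0, net_encode(net),
    match(course$target, net$nodes) - 1L,
    as.integer(course$effect),
    as.integer(course$t_start), as.integer(course$t_stop),
    as.integer(max_steps), as.integer(n_runs), healthy)
  fin <- res$final_states
  colnames(fin) <- net$nodes
  o <- order(res$final_counts, decreasing = TRUE)
  structure(list(pct_hhm = 100 * res$n_healthy / res$n_runs,
                 n_runs = res$n_runs, n_healthy = res$n_healthy,
                 n_unterminated = res$n_unterminated,
                 final_states = fin[o, , drop = FALSE],
                 final_counts = res$final_counts[o]),
            class = "ternet_outcome")
}

#' @export
print.ternet_outcome <- function(x, ...) {
  cat(sprintf("ternet_outcome: %.1f%% return to health (%d/%d runs",
              x$pct_hhm, x$n_healthy, x$n_runs))
  if (x$n_unterminated) cat(",", x$n_unterminated, "hit the step cap")
  cat(")\n")
  invisible(x)
}

#' The printed minimal treatment courses
#'
#' The three course schedules reported for the ill start states: from SS5,
#' increase testosterone (t 1-43), inhibit CK1 (21-83), inhibit GRD (75-99);
#' from SS4, inhibit MK6 (1-100), CK1 (8-40), GRD (77-99); from SS2,
#' inhibit MK6 (1-96) and GRD (7-93).
#'
#' @param which `"SS5"`, `"SS4"` or `"SS2"` (the start state).
#' @return A `ternet_course`.
#' @export
published_course <- function(which = c("SS5", "SS4", "SS2")) {
  switch(match.arg(which),
    SS5 = treatment_course(c("TEST", "CK1", "GRD"), c(1L, -1L, -1L),
                           c(1L, 21L, 75L), c(43L, 83L, 99L)),
    SS4 = treatment_course(c("MK6", "CK1", "GRD"), c(-1L, -1L, -1L),
                           c(1L, 8L, 77L), c(100L, 40L, 99L)),
    SS2 = treatment_course(c("MK6", "GRD"), c(-1L, -1L),
                           c(1L, 7L), c(96L, 93L)))
}
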