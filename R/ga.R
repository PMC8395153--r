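#' Genetic-algorithm configuration for treatment-course search
#'
#' @param allowed_targets named list: one entry per admissible target node,
#'   each an integer vector of admissible effects (+1 supplement, -1
#'   inhibit, or both).
#' @param n_interventions number of interventions M per course.
#' @param population courses per generation.
#' @param generations generational iterations.
#' @param elite_fraction fraction retained unchanged each generation.
#' @param eval_runs Monte Carlo repetitions per fitness evaluation.
#' @param horizon last admissible treatment timestep (windows live in
#'   `[1, horizon]`).
#' @param max_steps step cap per simulated run.
#' @param runs independent GA repetitions for [multi_run_best()].
#' @param frozen_eval memoize fitness by course (elites keep their recorded
#'   fitness instead of being re-executed); the default `FALSE` re-executes
#'   and re-evaluates elites every generation.
#' @return A `ternet_ga_config` list.
#' @export
ga_config <- function(allowed_targets, n_interventions = 3,
                      population = 100, generations = 100,
                      elite_fraction = 0.10, eval_runs = 100,
                      horizon = 100, max_steps = 1000, runs = 10,
                      frozen_eval = FALSE) {
  stopifnot(population >= 2, generations >= 0,
            elite_fraction > 0, elite_fraction < 1,
            n_interventions >= 0, eval_runs >= 1, horizon >= 1,
            runs >= 1)
  if (!length(allowed_targets) && n_interventions > 0)
    stop("allowed_targets is empty", call. = FALSE)
  if (length(allowed_targets) &&
      (is.null(names(allowed_targets)) ||
       !all(vapply(allowed_targets,
                   function(e) all(e %in% c(-1L, 1L)), TRUE))))
    stop("allowed_targets must be named, with effects in {-1, 1}",
         call. = FALSE)
  structure(list(allowed_targets = allowed_targets,
                 n_interventions = as.integer(n_interventions),
                 population = as.integer(population),
                 generations = as.integer(generations),
                 elite_fraction = elite_fraction,
                 eval_runs = as.integer(eval_runs),
                 horizon = as.integer(horizon),
                 max_steps = as.integer(max_steps),
                 runs = as.integer(runs),
                 frozen_eval = isTRUE(frozen_eval)),
            class = "ternet_ga_config")
}

#' Admissible interventions for the packaged network
#'
#' Increases of cortisol, ACTH and testosterone, inhibition of the
#' glucocorticoid receptor (both forms), and bidirectional modulation of all
#' peripheral cytokine groups.
#'
#' @return Named list suitable for [ga_config()]'s `allowed_targets`.
#' @export
gwi_allowed_targets <- function() {
  cyt <- c("CK1", "CK2", "CK17", "MK1", "MK2", "MK6", "MK15", "MK21",
           "MK23", "MK27", "TGFb")
  c(list(CORT = 1L, ACTH = 1L, TEST = 1L, GR = -1L, GRD = -1L),
    stats::setNames(rep(list(c(-1L, 1L)), length(cyt)), cyt))
}

#' Draw a random treatment course
#'
#' M interventions with uniformly random admissible targets and directions
#' and uniformly random windows within the horizon: the start is uniform on
#' the timesteps not already occupied by a same-target window, and the stop
#' uniform between the start and the next obstruction (so windows of a
#' shared target never overlap).
#'
#' @param cfg a [ga_config()].
#' @return A `ternet_course`.
#' @export
random_course <- function(cfg) {
  M <- cfg$n_interventions
  if (M == 0) return(treatment_course())
  tnames <- names(cfg$allowed_targets)
  target <- character(M); effect <- integer(M)
  t_start <- integer(M); t_stop <- integer(M)
  for (j in seq_len(M)) {
    placed <- FALSE
    for (tg in sample(tnames)) {       # first viable of a shuffled order
      same <- which(target[seq_len(j - 1)] == tg)
      covered <- unlist(lapply(same, function(i) t_start[i]:t_stop[i]))
      free <- setdiff(seq_len(cfg$horizon), covered)
      if (!length(free)) next
      a <- free[sample.int(length(free), 1)]
      nxt <- covered[covered > a]
      b_max <- if (length(nxt)) min(nxt) - 1L else cfg$horizon
      b <- a + sample.int(b_max - a + 1L, 1) - 1L
      eff <- cfg$allowed_targets[[tg]]
      eff <- if (length(eff) == 1) eff else eff[sample.int(length(eff), 1)]
      target[j] <- tg; effect[j] <- eff; t_start[j] <- a; t_stop[j] <- b
      placed <- TRUE
      break
    }
    if (!placed)
      stop("cannot place ", M, " non-overlapping interventions within ",
           "the horizon", call. = FALSE)
  }
  treatment_course(target, effect, t_start, t_stop,
                   allowed = tnames)
}

#' Single-splice crossover of two courses
#'
#' The child inherits every intervention of `a` starting before the splice
#' timepoint `s` and every intervention of `b` starting at or after `s`.
#' Inherited `b`-side interventions whose window would overlap a same-target
#' `a`-side window are dropped (the course would otherwise be ill-formed).
#'
#' @param a,b `ternet_course` objects.
#' @param s splice timestep.
#' @return A `ternet_course`.
#' @export
crossover_courses <- function(a, b, s) {
  keep_a <- a[a$t_start < s, , drop = FALSE]
  keep_b <- b[b$t_start >= s, , drop = FALSE]
  if (nrow(keep_a) && nrow(keep_b)) {
    ok <- vapply(seq_len(nrow(keep_b)), function(j) {
      same <- keep_a$target == keep_b$target[j]
      !any(same & keep_a$t_start <= keep_b$t_stop[j] &
             keep_b$t_start[j] <= keep_a$t_stop)
    }, TRUE)
    keep_b <- keep_b[ok, , drop = FALSE]
  }
  child <- rbind(as.data.frame(keep_a), as.data.frame(keep_b))
  treatment_course(child$target, child$effect, child$t_start, child$t_stop)
}

course_key <- function(course) {
  paste0("c:", paste(course$target, course$effect, course$t_start,
                     course$t_stop, sep = ":", collapse = ";"))
}

#' Evolve treatment courses by genetic algorithm
#'
#' Generational loop: every course's %HHM is estimated by Monte Carlo
#' simulation; the elite fraction is carried unchanged; the remainder of the
#' next generation is produced by single-splice crossover of uniformly
#' chosen pairs from the whole generation (elite included). No mutation
#' operator is applied.
#'
#' @param net a [ternet_network].
#' @param start named ternary start state (an ill attractor).
#' @param cfg a [ga_config()].
#' @param healthy healthy reference state (default all-zero).
#' @return A `ternet_ga_run`: list with `best_course`, `best_fitness`,
#'   `trace` (best %HHM per generation) and `evaluations`.
#' @export
evolve_course <- function(net, start, cfg, healthy = NULL) {
  memo <- new.env(parent = emptyenv())
  evals <- 0L
  fitness <- function(course) {
    key <- course_key(course)
    if (cfg$frozen_eval && !is.null(memo[[key]])) return(memo[[key]])
    out <- simulate_course(course, start, net, n_runs = cfg$eval_runs,
                           max_steps = cfg$max_steps, healthy = healthy)
    evals <<- evals + 1L
    if (cfg$frozen_eval) memo[[key]] <- out$pct_hhm
    out$pct_hhm
  }
  pop <- replicate(cfg$population, random_course(cfg), simplify = FALSE)
  fit <- vapply(pop, fitness, 0)
  n_elite <- max(1L, floor(cfg$elite_fraction * cfg$population))
  trace <- numeric(cfg$generations)
  for (g in seq_len(cfg$generations)) {
    o <- order(fit, decreasing = TRUE)
    elite <- pop[o[seq_len(n_elite)]]
    children <- replicate(cfg$population - n_elite, {
      pair <- sample.int(cfg$population, 2, replace = FALSE)
      crossover_courses(pop[[pair[1]]], pop[[pair[2]]],
                        sample.int(cfg$horizon, 1))
    }, simplify = FALSE)
    pop <- c(elite, children)
    fit <- vapply(pop, fitness, 0)
    trace[g] <- max(fit)
  }
  best <- which.max(fit)
  structure(list(best_course = pop[[best]], best_fitness = fit[best],
                 trace = trace, evaluations = evals),
            class = "ternet_ga_run")
}

#' @export
print.ternet_ga_run <- function(x, ...) {
  cat(sprintf("ternet_ga_run: best %%HHM = %.1f after %d generation(s)\n",
              x$best_fitness, length(x$trace)))
  print(x$best_course)
  invisible(x)
}

#' Best course over repeated GA runs
#'
#' Repeats [evolve_course()] `cfg$runs` times and returns the run whose
#' final course has the highest %HHM (ties broken by earliest run).
#'
#' @inheritParams evolve_course
#' @return The winning `ternet_ga_run`, with `run_fitness` attribute
#'   holding every run's final %HHM.
#' @export
multi_run_best <- function(net, start, cfg, healthy = NULL) {
  runs <- lapply(seq_len(cfg$runs), function(r)
    evolve_course(net, start, cfg, healthy = healthy))
  fits <- vapply(runs, `[[`, 0, "best_fitness")
  best <- runs[[which.max(fits)]]
  attr(best, "run_fitness") <- fits
  best
}
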