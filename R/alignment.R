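#' Cohort tables
#'
#' A cohort table couples a subjects-by-variables matrix of non-negative
#' measurements with group labels (`"condition"` / `"control"`), a
#' variable-to-node mapping into the network, and a panel tag used by the
#' multiplex harmonization step.
#'
#' @param values numeric matrix, one row per subject, named columns.
#' @param group character/factor of `"condition"`/`"control"`, one per row.
#' @param map named character vector: names are variable (column) names,
#'   values are node ids. Unmapped variables are allowed and skipped with a
#'   warning during alignment. A variable may map to at most one node.
#' @param panel free-text assay tag (e.g. `"16plex"`, `"18plex"`).
#' @return An object of class `ternet_cohort`.
#' @export
cohort_table <- function(values, group, map, panel = "panel") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values needs column names")
  group <- as.character(group)
  if (length(group) != nrow(values))
    stop("one group label per subject row is required")
  if (!all(group %in% c("condition", "control")))
    stop("group labels must be 'condition' or 'control'")
  if (is.null(names(map)) || anyDuplicated(names(map)))
    stop("map must be uniquely named by variable")
  structure(list(values = values, group = group, map = map, panel = panel),
            class = "ternet_cohort")
}

#' @export
print.ternet_cohort <- function(x, ...) {
  cat("ternet_cohort:", nrow(x$values), "subjects x", ncol(x$values),
      sprintf("variables (%d condition / %d control), panel '%s'\n",
              sum(x$group == "condition"), sum(x$group == "control"),
              x$panel))
  invisible(x)
}

cohort_group <- function(cohort, which) {
  cohort$values[cohort$group == which, , drop = FALSE]
}

#' Harmonize two multiplex panels
#'
#' Standardizes each panel per variable by z-scoring, maps the first panel's
#' z-scores back through the second panel's mean and standard deviation (so
#' the first panel is rescaled onto the second), then min-max normalizes the
#' combined data per variable to the unit interval.
#'
#' @param table16,table18 two [cohort_table]s sharing variable names;
#'   `table16` is rescaled onto `table18`'s location and spread.
#' @return A combined `ternet_cohort` with values in `[0, 1]`.
#' @export
harmonize_panels <- function(table16, table18) {
  shared <- intersect(colnames(table16$values), colnames(table18$values))
  if (!length(shared)) stop("panels share no variables")
  v16 <- table16$values[, shared, drop = FALSE]
  v18 <- table18$values[, shared, drop = FALSE]
  zscore <- function(m, tag) {
    mu <- colMeans(m); s <- apply(m, 2, stats::sd)
    if (any(s == 0 | is.na(s)))
      stop("zero variance in panel variable(s): ",
           paste(colnames(m)[s == 0 | is.na(s)], collapse = ", "),
           call. = FALSE)
    list(z = sweep(sweep(m, 2, mu), 2, s, "/"), mu = mu, s = s)
  }
  z16 <- zscore(v16)
  z18 <- zscore(v18)
  # reverse z-score the 16-plex through the 18-plex moments
  v16on18 <- sweep(sweep(z16$z, 2, z18$s, "*"), 2, z18$mu, "+")
  comb <- rbind(v16on18, v18)
  rng <- apply(comb, 2, range)
  comb <- sweep(sweep(comb, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
  cohort_table(comb, c(table16$group, table18$group),
               table18$map, panel = "harmonized")
}

#' Directional per-variable p-value against a model prediction
#'
#' Welch two-sample t-test of condition versus control measurements. A
#' predicted +1 uses the right tail (evidence the condition is elevated)
#' and -1 the left tail. For a predicted 0 two handlings are available:
#' the default `"equivalence"` is a Welch TOST (two one-sided tests against
#' a standardized equivalence margin), a valid p-value that is small
#' exactly when the data demonstrably sit at nominal; `"complement"` is
#' `1 - p_two-tail`, the probability of the observed agreement with nominal
#' expression under the null. The complement is uniformly distributed on
#' null data and therefore cannot separate a confirmed nominal prediction
#' from an unconfirmed directional one, which is why the equivalence form
#' is the default wherever profiles are ranked against several states.
#'
#' @param ill,ctrl numeric vectors of condition and control measurements
#'   (at least 2 each).
#' @param predicted ternary model prediction for the variable's node.
#' @param zero_mode handling of predicted-0 variables (see above).
#' @param equiv_margin equivalence margin for the TOST, in pooled standard
#'   deviations (default 0.75, half the moderate effect size the cohort
#'   generator imprints).
#' @return p-value in (0, 1]. Degenerate comparisons (zero variance in both
#'   groups) return 1 with a warning.
#' @export
per_variable_pvalue <- function(ill, ctrl, predicted,
                                zero_mode = c("equivalence", "complement"),
                                equiv_margin = 0.75) {
  predicted <- check_ternary(predicted, "prediction")
  zero_mode <- match.arg(zero_mode)
  if (length(ill) < 2 || length(ctrl) < 2)
    stop("need at least 2 observations per group", call. = FALSE)
  if (stats::sd(ill) == 0 && stats::sd(ctrl) == 0) {
    warning("zero variance in both groups; returning p = 1")
    return(1)
  }
  p <- if (predicted != 0L) {
    alt <- if (predicted > 0L) "greater" else "less"
    stats::t.test(ill, ctrl, alternative = alt, var.equal = FALSE)$p.value
  } else if (zero_mode == "complement") {
    1 - stats::t.test(ill, ctrl, var.equal = FALSE)$p.value
  } else {
    tt <- stats::t.test(ill, ctrl, var.equal = FALSE)
    se <- tt$stderr
    df <- unname(tt$parameter)
    delta <- equiv_margin * sqrt((stats::var(ill) + stats::var(ctrl)) / 2)
    mdiff <- unname(diff(rev(tt$estimate)))
    p1 <- stats::pt((mdiff + delta) / se, df, lower.tail = FALSE)
    p2 <- stats::pt((mdiff - delta) / se, df, lower.tail = TRUE)
    max(p1, p2)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Combine dependent p-values by Brown's method
#'
#' Fisher's statistic T0 = -2 sum log(p) has a chi-square distribution with
#' 2N degrees of freedom only under independence. Brown's approximation
#' rescales it for correlated tests: the variance picks up pairwise
#' covariance terms approximated from the inter-variable correlations
#' (rho >= 0: rho (3.25 + 0.75 rho); -0.5 <= rho < 0: rho (3.27 + 0.71 rho)),
#' and the aggregate p comes from the central chi-square with 2N/c degrees
#' of freedom evaluated at T0/c, where c = sigma^2 / (4N). With rho = 0
#' everywhere this reduces exactly to Fisher's method.
#'
#' @param p numeric vector of per-variable p-values.
#' @param rho correlation matrix of the variables (computed in the control
#'   group); entries below -0.5 (outside the approximation's domain) are
#'   clamped to -0.5 with a warning.
#' @param p_floor lower clip applied to the p-values before taking logs
#'   (default 0.05, the standard minimum significance used to avoid
#'   numerical instability); set to 0 to disable.
#' @return Object of class `ternet_brown`: list with `T0`, `sigma2`, `c`,
#'   `df`, `p` (the aggregate p-value), `log_p` (its natural log, exact in
#'   the deep tail where `p` underflows) and `n`.
#' @export
brown_combine <- function(p, rho = NULL, p_floor = 0.05) {
  n <- length(p)
  if (n < 1) stop("need at least one p-value", call. = FALSE)
  if (any(p <= 0 | p > 1 | is.na(p)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p <- pmin(pmax(p, p_floor), 1)
  if (is.null(rho)) rho <- diag(n)
  rho <- as.matrix(rho)
  if (!all(dim(rho) == n)) stop("rho must be n x n", call. = FALSE)
  if (any(rho < -0.5)) {
    warning("correlation(s) below -0.5 clamped to -0.5")
    rho[rho < -0.5] <- -0.5
  }
  T0 <- -2 * sum(log(p))
  covsum <- 0
  if (n > 1) {
    ut <- rho[upper.tri(rho)]
    cv <- ifelse(ut >= 0, ut * (3.25 + 0.75 * ut), ut * (3.27 + 0.71 * ut))
    covsum <- sum(cv)
  }
  sigma2 <- 4 * n + 2 * covsum
  c_ <- sigma2 / (4 * n)
  df <- 2 * n / c_
  if (df < 1) {
    warning("degrees of freedom below 1; flooring at 1")
    df <- 1
  }
  log_p <- stats::pchisq(T0 / c_, df = df, lower.tail = FALSE,
                         log.p = TRUE)
  structure(list(T0 = T0, sigma2 = sigma2, c = c_, df = df,
                 p = min(max(exp(log_p), .Machine$double.xmin), 1),
                 log_p = log_p, n = n),
            class = "ternet_brown")
}

#' @export
print.ternet_brown <- function(x, ...) {
  cat(sprintf(
    "ternet_brown: T0 = %.3f, c = %.3f, df = %.2f, aggregate p = %.4g (n = %d)\n",
    x$T0, x$c, x$df, x$p, x$n))
  invisible(x)
}

# correlation of mapped variables computed in the control group
control_correlation <- function(cohort, vars = NULL) {
  ctrl <- cohort_group(cohort, "control")
  if (is.null(vars)) vars <- intersect(colnames(ctrl), names(cohort$map))
  stats::cor(ctrl[, vars, drop = FALSE])
}

#' Dissimilarity between a measured condition profile and a predicted state
#'
#' Per mapped variable, a directional Welch t-test of condition versus
#' control against the state's predicted sign, combined across variables by
#' Brown's method using the control-group correlations. Small aggregate p
#' means the profile aligns with the state.
#'
#' @param cohort a [cohort_table] containing condition and control subjects.
#' @param state named ternary state vector (or a catalogue column).
#' @param rho optional correlation matrix over the mapped variables
#'   (defaults to the control-group Pearson correlations).
#' @param log return the log aggregate p (used for ranking states whose
#'   aggregate p underflows double precision).
#' @param p_floor lower clip on the per-variable p-values (default 0: the
#'   0.05 minimum-significance floor is only prescribed for state-state
#'   agreement values; flooring measured p-values erases the contrast
#'   between a confirmed nominal prediction, whose p is typically small,
#'   and an unconfirmed directional one, whose p hovers near 0.5).
#' @param ... passed on to [per_variable_pvalue()] (`zero_mode`,
#'   `equiv_margin`).
#' @return Aggregate p-value in (0, 1].
#' @export
condition_state_dissimilarity <- function(cohort, state, rho = NULL,
                                          p_floor = 0, log = FALSE, ...) {
  vars <- colnames(cohort$values)
  unmapped <- setdiff(vars, names(cohort$map))
  if (length(unmapped))
    warning("unmapped variable(s) skipped: ",
            paste(unmapped, collapse = ", "))
  vars <- intersect(vars, names(cohort$map))
  nodes <- cohort$map[vars]
  if (!all(nodes %in% names(state)))
    stop("state lacks predicted values for node(s): ",
         paste(setdiff(nodes, names(state)), collapse = ", "), call. = FALSE)
  ill <- cohort_group(cohort, "condition")
  ctrl <- cohort_group(cohort, "control")
  p <- vapply(seq_along(vars), function(i) {
    per_variable_pvalue(ill[, vars[i]], ctrl[, vars[i]],
                        as.integer(state[nodes[i]]), ...)
  }, 0)
  if (is.null(rho)) rho <- control_correlation(cohort, vars)
  b <- brown_combine(p, rho[vars, vars], p_floor = p_floor)
  if (log) b$log_p else b$p
}

#' Dissimilarity between two predicted states
#'
#' Variables where the two states agree contribute the standard minimum
#' significance p = 0.05; variables where they disagree contribute p = 1.
#' The per-variable values are combined by Brown's method under the
#' control-data correlations.
#'
#' @param a,b named ternary state vectors.
#' @param map named character vector mapping measured variables to nodes
#'   (the restriction to a measurable subset).
#' @param rho correlation matrix over the mapped variables.
#' @return Aggregate p-value in (0, 1].
#' @export
state_state_dissimilarity <- function(a, b, map, rho = NULL) {
  if (!length(map)) stop("variable subset is empty", call. = FALSE)
  nodes <- unname(map)
  p <- ifelse(a[nodes] == b[nodes], 0.05, 1)
  if (!is.null(rho)) rho <- rho[names(map), names(map)]
  brown_combine(p, rho, p_floor = 0.05)$p
}

#' Dissimilarity matrix of the catalogued states over a measured subset
#'
#' @param catalogue nodes x states matrix (see [gwi_states()]).
#' @param map variable-to-node mapping of the measured panel.
#' @param rho correlation matrix over the mapped variables.
#' @param merge merge states indistinguishable on the measured subset into
#'   single anchors (labelled e.g. `"SS0/SS1"`).
#' @return Symmetric matrix of aggregate p-values with zero diagonal.
#' @export
state_dissim_matrix <- function(catalogue, map, rho = NULL, merge = TRUE) {
  if (merge) catalogue <- merge_indistinguishable_states(catalogue, unname(map))
  k <- ncol(catalogue)
  d <- matrix(0, k, k, dimnames = list(colnames(catalogue),
                                       colnames(catalogue)))
  if (k > 1)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- state_state_dissimilarity(
        catalogue[, i], catalogue[, j], map, rho)
    }
  d
}

#' Align a cohort's condition profile to the catalogued states
#'
#' Computes the condition-versus-state dissimilarity for every (merged)
#' anchor and reports the closest one.
#'
#' @inheritParams condition_state_dissimilarity
#' @param catalogue nodes x states matrix.
#' @param merge see [state_dissim_matrix()].
#' @param ... passed on to [per_variable_pvalue()].
#' @return List with `dissimilarity` (named vector over anchors),
#'   `log_dissimilarity` (its exact log, on which the ranking is done) and
#'   `best` (anchor label of the minimum; ties broken by catalogue order).
#' @export
align_cohort <- function(cohort, catalogue, rho = NULL, p_floor = 0,
                         merge = TRUE, ...) {
  if (merge)
    catalogue <- merge_indistinguishable_states(
      catalogue, unname(cohort$map[colnames(cohort$values)]))
  if (is.null(rho)) rho <- control_correlation(cohort)
  lp <- vapply(colnames(catalogue), function(k) {
    condition_state_dissimilarity(cohort, catalogue[, k], rho = rho,
                                  p_floor = p_floor, log = TRUE, ...)
  }, 0)
  d <- pmin(pmax(exp(lp), .Machine$double.xmin), 1)
  list(dissimilarity = d, log_dissimilarity = lp,
       best = names(d)[which.min(lp)])
}

#' Hold-out cross-validation of the healthy alignment
#'
#' Randomly splits the control subjects evenly in two, treats one half as a
#' pseudo-condition group against the other half, aligns it to the
#' catalogue, and repeats. Returns the fraction of repeats in which the
#' anchor containing the healthy state SS0 is the closest.
#'
#' @param cohort a [cohort_table]; only its control subjects are used.
#' @param catalogue nodes x states matrix.
#' @param n_repeats number of random splits (default 100).
#' @param p_floor,... see [condition_state_dissimilarity()].
#' @return List with `fraction` (of repeats aligning SS0), `assignments`
#'   (anchor label per repeat).
#' @export
holdout_cv <- function(cohort, catalogue, n_repeats = 100, p_floor = 0,
                       ...) {
  ctrl_idx <- which(cohort$group == "control")
  if (length(ctrl_idx) < 4)
    stop("need at least 4 control subjects for an even split", call. = FALSE)
  half <- floor(length(ctrl_idx) / 2)
  assignments <- character(n_repeats)
  for (r in seq_len(n_repeats)) {
    test <- sample(ctrl_idx, half)
    rest <- setdiff(ctrl_idx, test)
    pseudo <- cohort_table(
      cohort$values[c(test, rest), , drop = FALSE],
      c(rep("condition", length(test)), rep("control", length(rest))),
      cohort$map, cohort$panel)
    assignments[r] <- align_cohort(pseudo, catalogue,
                                   p_floor = p_floor, ...)$best
  }
  healthy <- grepl("(^|/)SS0($|/)", assignments)
  list(fraction = mean(healthy), assignments = assignments)
}
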