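#' Specification of a synthetic two-group cohort
#'
#' Emulates the structure of the study's condition-versus-control panels:
#' group sizes default to the human cohort (51 ill, 38 sedentary controls),
#' measurements are non-negative and right-skewed (correlated Gaussian on a
#' latent log scale, exponentiated), inter-variable dependence is
#' equicorrelation on the latent scale, and the condition group is
#' mean-shifted per variable by `effect_size` times the target state's sign
#' for the variable's node.
#'
#' @param n_condition,n_control group sizes (>= 2).
#' @param target_state catalogue state whose signs the condition group
#'   carries (e.g. `"SS3"`).
#' @param effect_size standardized latent mean shift per non-zero node
#'   (default 1.5, a moderate panel effect).
#' @param correlation latent equicorrelation between variables (default
#'   0.3).
#' @param noise_sd latent standard deviation (default 1).
#' @param measured `"blood"` or `"blood+brain"` (which nodes are visible).
#' @param seed optional integer; if given, the generator seeds the RNG
#'   itself so the cohort is fully reproducible.
#' @return A `ternet_cohort_spec` list.
#' @export
cohort_spec <- function(n_condition = 51, n_control = 38,
                        target_state = "SS0", effect_size = 1.5,
                        correlation = 0.3, noise_sd = 1,
                        measured = c("blood", "blood+brain"), seed = NULL) {
  stopifnot(n_condition >= 2, n_control >= 2, effect_size >= 0,
            abs(correlation) < 1, noise_sd > 0)
  structure(list(n_condition = as.integer(n_condition),
                 n_control = as.integer(n_control),
                 target_state = target_state,
                 effect_size = effect_size, correlation = correlation,
                 noise_sd = noise_sd, measured = match.arg(measured),
                 seed = seed),
            class = "ternet_cohort_spec")
}

synthetic_map <- function(measured) {
  map <- blood_panel_map()
  if (measured == "blood+brain")
    map <- c(map, ProInflam_b = "ProInflam_b", Microglia = "Microglia")
  map
}

#' Generate a synthetic cohort around a catalogued state
#'
#' @param spec a [cohort_spec()].
#' @param catalogue nodes x states matrix (default [gwi_states()]).
#' @return A [cohort_table] whose condition group is shifted along the
#'   target state's blood-visible signs.
#' @export
gen_cohort <- function(spec, catalogue = gwi_states()) {
  if (!spec$target_state %in% colnames(catalogue))
    stop("target_state not in catalogue", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  map <- synthetic_map(spec$measured)
  p <- length(map)
  if (spec$correlation < -1 / (p - 1))
    stop("equicorrelation infeasible for ", p, " variables", call. = FALSE)
  sigma <- matrix(spec$correlation, p, p); diag(sigma) <- 1
  L <- chol(sigma)
  n <- spec$n_condition + spec$n_control
  latent <- (matrix(stats::rnorm(n * p), n, p) %*% L) * spec$noise_sd
  shift <- spec$effect_size * spec$noise_sd *
    as.numeric(catalogue[unname(map), spec$target_state])
  latent[seq_len(spec$n_condition), ] <-
    sweep(latent[seq_len(spec$n_condition), , drop = FALSE], 2, shift, "+")
  values <- exp(latent)
  colnames(values) <- names(map)
  cohort_table(values,
               c(rep("condition", spec$n_condition),
                 rep("control", spec$n_control)),
               map, panel = paste0("synthetic-", spec$target_state))
}

#' Split a cohort into two distorted multiplex panels
#'
#' Partitions the subjects into a "16-plex" and an "18-plex" half and
#' applies a fixed affine distortion per variable to the first half's
#' values, emulating two assay platforms that [harmonize_panels()] must
#' reconcile.
#'
#' @param cohort a [cohort_table].
#' @param scale,offset distortion applied to the 16-plex half.
#' @return List with elements `table16` and `table18`.
#' @export
split_panels <- function(cohort, scale = 1.8, offset = 0.7) {
  n <- nrow(cohort$values)
  half <- seq_len(floor(n / 2))
  v16 <- cohort$values[half, , drop = FALSE] * scale + offset
  v18 <- cohort$values[-half, , drop = FALSE]
  list(table16 = cohort_table(v16, cohort$group[half], cohort$map, "16plex"),
       table18 = cohort_table(v18, cohort$group[-half], cohort$map,
                              "18plex"))
}

#' Generate a random toy network
#'
#' Random signed digraph over `n_nodes`, each ordered pair carrying an edge
#' with probability `edge_density` (mode uniform), and each edge upgraded
#' to a conditional edge with probability `conditional_fraction` (gate on a
#' random third node being -1).
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edge_density probability of each directed edge.
#' @param conditional_fraction probability an edge is gated.
#' @param seed optional integer seed.
#' @return A [ternet_network].
#' @export
gen_toy_network <- function(n_nodes, edge_density = 0.3,
                            conditional_fraction = 0, seed = NULL) {
  stopifnot(n_nodes >= 1, edge_density >= 0, edge_density <= 1)
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("N", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < edge_density
  e <- pairs[keep, , drop = FALSE]
  if (!nrow(e))
    return(ternet_network(nodes,
                          data.frame(source = character(),
                                     target = character(),
                                     mode = character())))
  e$mode <- sample(c("activate", "inhibit"), nrow(e), replace = TRUE)
  e$gate_node <- NA_character_; e$gate_value <- NA_integer_
  if (n_nodes >= 2 && conditional_fraction > 0) {
    gated <- stats::runif(nrow(e)) < conditional_fraction
    for (i in which(gated)) {
      cand <- setdiff(nodes, e$target[i])
      e$gate_node[i] <- cand[sample.int(length(cand), 1)]
      e$gate_value[i] <- -1L
    }
  }
  ternet_network(nodes, e)
}

#' Generate a mouse counterpart of a human topology
#'
#' The cross-species analysis rests on the mouse anchor distances being a
#' (noisy) linear transform of the human ones. Since the Brown-method
#' dissimilarities are a nonlinear functional of cohort values, the mouse
#' counterpart is emulated at the level where the linear relation is
#' defined: the human anchor dissimilarity matrix is rescaled by
#' `distance_scale` and perturbed with symmetric Gaussian noise.
#'
#' @param human_d symmetric human dissimilarity (or distance) matrix.
#' @param distance_scale multiplicative species factor (> 0).
#' @param noise_sd standard deviation of the entrywise perturbation.
#' @param seed optional integer seed.
#' @return Symmetric non-negative matrix with zero diagonal ("mouse"
#'   dissimilarities).
#' @export
gen_mouse_counterpart <- function(human_d, distance_scale, noise_sd = 0,
                                  seed = NULL) {
  stopifnot(distance_scale > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  d <- as.matrix(human_d) * distance_scale
  if (noise_sd > 0) {
    eps <- matrix(stats::rnorm(length(d), sd = noise_sd), nrow(d))
    eps <- (eps + t(eps)) / 2
    d <- d + eps
  }
  diag(d) <- 0
  d[d < 0] <- 0
  (d + t(d)) / 2
}
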