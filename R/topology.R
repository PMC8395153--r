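#' Merge states indistinguishable on a measured subset
#'
#' States whose predicted values coincide on every measured node collapse
#' into a single anchor; with blood-only panels SS0/SS1 and SS4/SS5 merge,
#' while adding the brain measures separates SS4 from SS5.
#'
#' @param catalogue nodes x states ternary matrix.
#' @param subset character vector of measurable node ids.
#' @return Matrix with one column per distinguishable anchor; merged anchors
#'   are labelled like `"SS0/SS1"`.
#' @export
merge_indistinguishable_states <- function(catalogue, subset) {
  subset <- unique(subset)
  if (!length(subset)) stop("measured subset is empty", call. = FALSE)
  if (!all(subset %in% rownames(catalogue)))
    stop("subset contains unknown node(s)", call. = FALSE)
  sig <- apply(catalogue[subset, , drop = FALSE], 2, paste, collapse = ",")
  groups <- split(colnames(catalogue), factor(sig, levels = unique(sig)))
  merged <- vapply(groups, function(g) catalogue[, g[1]],
                   integer(nrow(catalogue)))
  colnames(merged) <- vapply(groups, paste, "", collapse = "/")
  rownames(merged) <- rownames(catalogue)
  merged[, order(match(vapply(groups, `[`, "", 1L), colnames(catalogue))),
         drop = FALSE]
}

#' 2-D layouts
#'
#' A layout holds 2-D coordinates for a set of points, a subset of which are
#' anchors (the model-predicted stable states); the rest are measured
#' condition profiles.
#'
#' @param points numeric matrix with 2 columns and row names.
#' @param anchors character vector of anchor point ids.
#' @return An object of class `ternet_layout`.
#' @export
ternet_layout <- function(points, anchors) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || is.null(rownames(points)))
    stop("points must be a 2-column matrix with row names", call. = FALSE)
  if (!all(anchors %in% rownames(points)))
    stop("anchors must name rows of points", call. = FALSE)
  if (!all(is.finite(points))) stop("non-finite coordinates", call. = FALSE)
  colnames(points) <- c("x", "y")
  structure(list(points = points, anchors = anchors),
            class = "ternet_layout")
}

#' @export
print.ternet_layout <- function(x, ...) {
  cat("ternet_layout:", nrow(x$points), "points (",
      length(x$anchors), "anchors )\n")
  invisible(x)
}

layout_dist <- function(layout) as.matrix(stats::dist(layout$points))

#' Weighted metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix into two dimensions by minimizing the
#' weighted metric stress criterion normalized by the (weighted) sum of
#' squares of the dissimilarities, via SMACOF majorization with seeded
#' random restarts. Entries involving condition (non-anchor) points are
#' down-weighted to 10% of the anchor-anchor weight by default, so added
#' conditions do not disturb the stable-state geometry.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal and row names.
#' @param anchors anchor point ids (default: all points).
#' @param condition_weight weight of entries involving a non-anchor point,
#'   relative to anchor-anchor entries (default 0.1).
#' @param weights optional full weight matrix overriding the scheme above.
#' @param n_starts random restarts (best final stress kept, default 20).
#' @param max_iter,tol majorization iteration controls.
#' @return A [ternet_layout] with attributes `stress` (normalized Kruskal
#'   stress) and `condition_weight`.
#' @export
mds_embed <- function(d, anchors = rownames(d), condition_weight = 0.1,
                      weights = NULL, n_starts = 20, max_iter = 500,
                      tol = 1e-10) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("p", 1:n)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
      any(abs(diag(d)) > 1e-12))
    stop("dissimilarity matrix must be symmetric with zero diagonal",
         call. = FALSE)
  if (is.null(weights)) {
    is_anchor <- rownames(d) %in% anchors
    w <- outer(is_anchor, is_anchor, function(a, b) {
      ifelse(a & b, 1, condition_weight)
    })
  } else w <- as.matrix(weights)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  diag(w) <- 0

  # SMACOF: X <- V^+ B(X) X with V from the weights
  V <- -w; diag(V) <- rowSums(w)
  Vinv <- solve(V + 1 / n) - 1 / n   # Moore-Penrose under centering
  denom <- sum(w * d^2) / 2
  stress_of <- function(X) {
    dx <- as.matrix(stats::dist(X))
    sqrt(sum(w * (dx - d)^2) / 2 / denom)
  }
  best <- NULL; best_stress <- Inf
  for (s in seq_len(n_starts)) {
    X <- matrix(stats::rnorm(2 * n), n, 2)
    last <- Inf
    for (it in seq_len(max_iter)) {
      dx <- as.matrix(stats::dist(X))
      ratio <- ifelse(dx > 0, d / dx, 0)
      B <- -w * ratio; diag(B) <- -rowSums(B)
      X <- Vinv %*% (B %*% X)
      st <- stress_of(X)
      if (last - st < tol) break
      last <- st
    }
    st <- stress_of(X)
    if (st < best_stress) { best_stress <- st; best <- X }
  }
  rownames(best) <- rownames(d)
  out <- ternet_layout(best, intersect(anchors, rownames(d)))
  attr(out, "stress") <- best_stress
  attr(out, "condition_weight") <- condition_weight
  out
}

#' Affine registration of one layout onto another
#'
#' Fits the least-squares affine map (rotation, scaling, shear, reflection,
#' translation) carrying the moving layout's anchors onto the reference
#' layout's anchors, and applies it to every point of the moving layout.
#'
#' @param moving,reference [ternet_layout]s sharing at least 3 non-collinear
#'   anchors.
#' @return The transformed moving layout.
#' @export
affine_align <- function(moving, reference) {
  shared <- intersect(moving$anchors, reference$anchors)
  if (length(shared) < 3)
    stop("need at least 3 shared anchors", call. = FALSE)
  A <- moving$points[shared, , drop = FALSE]
  B <- reference$points[shared, , drop = FALSE]
  if (qr(cbind(1, A))$rank < 3)
    stop("anchors are collinear; affine map is not identifiable",
         call. = FALSE)
  fit <- stats::lsfit(A, B)
  M <- cbind(1, moving$points) %*% fit$coefficients  # row 1 = intercept
  rownames(M) <- rownames(moving$points)
  ternet_layout(M, moving$anchors)
}

#' Root mean square deviation between two layouts
#'
#' Square root of the mean squared pointwise Euclidean deviation over the
#' shared (identically named) points.
#'
#' @param a,b [ternet_layout]s (or 2-column matrices) with identical point
#'   id sets.
#' @return RMSD (non-negative scalar).
#' @export
rmsd <- function(a, b) {
  pa <- if (inherits(a, "ternet_layout")) a$points else as.matrix(a)
  pb <- if (inherits(b, "ternet_layout")) b$points else as.matrix(b)
  if (!setequal(rownames(pa), rownames(pb)))
    stop("layouts have mismatched point ids", call. = FALSE)
  pb <- pb[rownames(pa), , drop = FALSE]
  sqrt(mean(rowSums((pa - pb)^2)))
}

#' Scale a mouse topology onto the human distance scale
#'
#' Regresses the human anchor pairwise distances on the corresponding mouse
#' distances (the strong linear relation between the species' topologies),
#' passes every mouse dissimilarity through the fit, and re-embeds.
#'
#' @param mouse,human [ternet_layout]s sharing their anchor set.
#' @param n_starts restarts for the re-embedding.
#' @return List with `layout` (rescaled, re-embedded mouse layout) and
#'   `regression` (`slope`, `intercept`, `r`).
#' @export
cross_species_scale <- function(mouse, human, n_starts = 20) {
  shared <- intersect(mouse$anchors, human$anchors)
  if (length(shared) < 3 || choose(length(shared), 2) < 2)
    stop("need at least 2 shared anchor pairs", call. = FALSE)
  dm <- layout_dist(mouse)[shared, shared]
  dh <- layout_dist(human)[shared, shared]
  xm <- dm[upper.tri(dm)]; xh <- dh[upper.tri(dh)]
  fit <- stats::lm(xh ~ xm)
  reg <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r = stats::cor(xm, xh))
  dall <- layout_dist(mouse)
  dscaled <- reg$intercept + reg$slope * dall
  dscaled[dall == 0] <- 0
  dscaled[dscaled < 0] <- 0
  dscaled <- (dscaled + t(dscaled)) / 2
  layout <- mds_embed(dscaled, anchors = mouse$anchors, n_starts = n_starts)
  list(layout = layout, regression = reg)
}
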