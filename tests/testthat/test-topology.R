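layout_of <- function(m, anchors = rownames(m)) ternet_layout(m, anchors)

test_that("rmsd matches hand computations and is a metric", {
  a <- layout_of(matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE,
                        dimnames = list(c("p", "q", "r"), NULL)))
  expect_equal(rmsd(a, a), 0)
  shifted <- layout_of(a$points + rep(c(3, 4), each = 3))
  expect_equal(rmsd(a, shifted), 5)
  two <- layout_of(matrix(c(0, 0, 0, 0), 2, 2,
                          dimnames = list(c("p", "q"), NULL)))
  dev <- layout_of(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
                          dimnames = list(c("p", "q"), NULL)))
  expect_equal(rmsd(two, dev), 1)  # deviations 0 and sqrt(2)
  bad <- layout_of(matrix(0, 2, 2, dimnames = list(c("p", "z"), NULL)))
  expect_error(rmsd(a, bad), "mismatched")
  set.seed(10)
  for (r in 1:10) {
    mk <- function() layout_of(matrix(rnorm(8), 4, 2,
                                      dimnames = list(letters[1:4], NULL)))
    x <- mk(); y <- mk(); z <- mk()
    expect_equal(rmsd(x, y), rmsd(y, x))
    expect_lte(rmsd(x, z), rmsd(x, y) + rmsd(y, z) + 1e-12)
  }
})

test_that("the embedding recovers planar configurations", {
  set.seed(21)
  # equal dissimilarities embed as an equilateral triangle
  d3 <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(d3) <- 0
  lay <- mds_embed(d3, n_starts = 5)
  expect_lt(attr(lay, "stress"), 1e-6)
  side <- as.matrix(dist(lay$points))
  expect_equal(unname(side[upper.tri(side)]), rep(1, 3), tolerance = 1e-4)
  # generate-then-embed round trip on a known configuration
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  d <- as.matrix(dist(pts))
  lay2 <- mds_embed(d, n_starts = 10)
  expect_lt(attr(lay2, "stress"), 1e-6)
  expect_equal(as.matrix(dist(lay2$points)), d, tolerance = 1e-3)
  # malformed input is rejected
  dbad <- d; dbad[1, 2] <- dbad[1, 2] + 1
  expect_error(mds_embed(dbad), "symmetric")
})

test_that("10%-weighted condition points barely perturb the anchors", {
  set.seed(31)
  anchors <- paste0("SS", 1:4)
  pts <- matrix(rnorm(8), 4, 2, dimnames = list(anchors, NULL))
  d <- as.matrix(dist(pts))
  base <- mds_embed(d, anchors = anchors, n_starts = 10)
  dfull <- rbind(cbind(d, cond = runif(4, 0.3, 1)),
                 cond = c(runif(4, 0.3, 1), 0))
  dfull[upper.tri(dfull)] <- t(dfull)[upper.tri(dfull)]  # symmetrize
  colnames(dfull) <- rownames(dfull) <- c(anchors, "cond")
  with_cond <- mds_embed(dfull, anchors = anchors, condition_weight = 0.1,
                         n_starts = 10)
  aligned <- affine_align(with_cond, base)
  anchor_only <- ternet_layout(aligned$points[anchors, ], anchors)
  expect_lt(rmsd(anchor_only, base), 0.01)
})

test_that("affine registration recovers similarity transforms exactly", {
  set.seed(41)
  pts <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("A", 1:5), NULL))
  ref <- layout_of(pts)
  th <- pi / 7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- layout_of(pts %*% rot * 1.7 + rep(c(2, -3), each = 5))
  expect_lt(rmsd(affine_align(moved, ref), ref), 1e-8)
  # identity in, identity out
  expect_lt(rmsd(affine_align(ref, ref), ref), 1e-10)
  # reflections are inside the affine family
  refl <- layout_of(pts %*% diag(c(-1, 1)))
  expect_lt(rmsd(affine_align(refl, ref), ref), 1e-8)
  # degenerate anchor sets are refused
  two <- layout_of(pts[1:2, , drop = FALSE])
  expect_error(affine_align(two, two), "3 shared anchors")
  lp <- matrix(c(1:4, 2 * (1:4)), 4, 2,
               dimnames = list(paste0("L", 1:4), NULL))
  line <- ternet_layout(lp, paste0("L", 1:4))
  expect_error(affine_align(line, line), "collinear")
})

test_that("cross-species scaling recovers the species distance factor", {
  set.seed(51)
  anchors <- c("SS0/SS1", "SS2", "SS3", "SS4/SS5")
  pts <- matrix(rnorm(8, sd = 2), 4, 2, dimnames = list(anchors, NULL))
  human <- ternet_layout(pts, anchors)
  # mouse distances exactly twice the human ones: slope 1/2, intercept 0
  md <- gen_mouse_counterpart(as.matrix(dist(pts)), distance_scale = 2)
  mouse <- mds_embed(md, anchors = anchors, n_starts = 10)
  res <- cross_species_scale(mouse, human, n_starts = 10)
  expect_equal(res$regression$slope, 0.5, tolerance = 1e-3)
  expect_equal(res$regression$intercept, 0, tolerance = 1e-3)
  expect_equal(res$regression$r, 1, tolerance = 1e-6)
  # identical topologies: slope 1, intercept 0
  res1 <- cross_species_scale(human, human, n_starts = 5)
  expect_equal(res1$regression$slope, 1, tolerance = 1e-6)
  # noisy linear relation: slope recovered within simulation error
  slopes <- replicate(10, {
    mdn <- gen_mouse_counterpart(as.matrix(dist(pts)), 2, noise_sd = 0.1)
    mn <- mds_embed(mdn, anchors = anchors, n_starts = 5)
    cross_species_scale(mn, human, n_starts = 5)$regression$slope
  })
  expect_lt(abs(mean(slopes) - 0.5), 0.1)
})
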