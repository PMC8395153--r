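test_that("Brown combination reproduces its closed forms", {
  # independence: exact Fisher
  b <- brown_combine(c(0.05, 0.05), diag(2), p_floor = 0)
  expect_equal(b$p, pchisq(-4 * log(0.05), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(b$c, 1); expect_equal(b$df, 4)
  # perfectly correlated duplicates collapse to a single test
  b1 <- brown_combine(c(0.05, 0.05), matrix(1, 2, 2), p_floor = 0)
  expect_equal(b1$df, 2)
  expect_equal(b1$c, 2)
  expect_equal(b1$p, 0.05, tolerance = 1e-6)
  # single test passes through
  expect_equal(brown_combine(0.17, p_floor = 0)$p, 0.17, tolerance = 1e-12)
  # total disagreement: T0 = 0, aggregate p = 1
  expect_equal(brown_combine(c(1, 1, 1))$T0, 0)
  expect_equal(brown_combine(c(1, 1, 1))$p, 1)
})

test_that("Brown combination over random inputs stays in the Fisher limit", {
  set.seed(4)
  for (r in 1:20) {
    p <- runif(sample(2:8, 1))
    b <- brown_combine(p, p_floor = 0)
    expect_equal(b$p,
                 pchisq(-2 * sum(log(p)), 2 * length(p), lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("smaller per-variable p-values never increase the aggregate", {
  set.seed(8)
  rho <- matrix(0.4, 4, 4); diag(rho) <- 1
  p <- c(0.3, 0.6, 0.2, 0.9)
  base <- brown_combine(p, rho, p_floor = 0)$p
  for (i in 1:4) {
    p2 <- p; p2[i] <- p[i] / 3
    expect_lte(brown_combine(p2, rho, p_floor = 0)$p, base)
  }
})

test_that("out-of-domain correlations and tiny dfs are handled", {
  rho <- matrix(c(1, -0.9, -0.9, 1), 2)
  expect_warning(b <- brown_combine(c(0.1, 0.1), rho), "clamped")
  expect_gt(b$p, 0); expect_lte(b$p, 1)
  expect_error(brown_combine(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("directional p-values follow the predicted tail", {
  set.seed(2)
  ctrl <- rnorm(30)
  ill <- rnorm(30, mean = 3)
  expect_lt(per_variable_pvalue(ill, ctrl, 1L), 0.05)
  expect_gt(per_variable_pvalue(ill, ctrl, -1L), 0.95)
  # matched groups confirm a nominal prediction under both handlings
  same <- rnorm(30)
  expect_lt(per_variable_pvalue(same, same, 0L, zero_mode = "complement"),
            1e-6)
  expect_lt(per_variable_pvalue(same, same + rnorm(30, sd = 0.05), 0L),
            0.05)
  # and a strongly shifted group refutes it
  expect_gt(per_variable_pvalue(ill, ctrl, 0L), 0.95)
  expect_warning(p <- per_variable_pvalue(rep(1, 5), rep(1, 5), 1L),
                 "zero variance")
  expect_equal(p, 1)
})

test_that("panel harmonization rescales onto the reference panel", {
  set.seed(6)
  co <- gen_cohort(cohort_spec(n_condition = 20, n_control = 20,
                               target_state = "SS2"))
  sp <- split_panels(co)          # affine distortion on the 16-plex half
  h <- harmonize_panels(sp$table16, sp$table18)
  expect_true(all(h$values >= 0 & h$values <= 1))
  expect_equal(unname(apply(h$values, 2, min)), rep(0, ncol(h$values)))
  expect_equal(unname(apply(h$values, 2, max)), rep(1, ncol(h$values)))
  # identical panels: harmonization is the identity up to min-max scaling
  t18 <- sp$table18
  t16 <- cohort_table(t18$values * 2 + 5, t18$group, t18$map, "16plex")
  hh <- harmonize_panels(t16, t18)
  top <- hh$values[seq_len(nrow(t18$values)), ]
  bottom <- hh$values[-seq_len(nrow(t18$values)), ]
  expect_equal(top, bottom, ignore_attr = TRUE, tolerance = 1e-10)
  # zero variance is reported by variable name
  t16$values[, "IL6"] <- 1
  expect_error(harmonize_panels(t16, t18), "IL6")
})

test_that("state-state dissimilarity uses the 0.05/1 agreement coding", {
  ss <- gwi_states()
  map <- blood_panel_map()
  agree <- state_state_dissimilarity(ss[, "SS3"], ss[, "SS3"], map)
  expect_lt(agree, 0.01)
  # SS0 and SS1 agree everywhere measurable in blood
  expect_equal(state_state_dissimilarity(ss[, "SS0"], ss[, "SS1"], map),
               agree)
  # total disagreement gives p = 1
  a <- setNames(rep(1L, length(map)), unname(map))
  b <- setNames(rep(-1L, length(map)), unname(map))
  expect_equal(state_state_dissimilarity(a, b, map), 1)
  d <- state_dissim_matrix(ss, map)
  expect_identical(colnames(d), c("SS0/SS1", "SS2", "SS3", "SS4/SS5"))
  expect_true(isSymmetric(d) && all(diag(d) == 0))
})

test_that("synthetic cohorts align to their generating state", {
  ss <- gwi_states()
  for (k in c("SS0", "SS2", "SS3", "SS5")) {
    co <- gen_cohort(cohort_spec(target_state = k, seed = 101 + match(k, colnames(ss))))
    al <- align_cohort(co, ss)
    expect_true(grepl(paste0("(^|/)", k, "($|/)"), al$best),
                label = paste("cohort at", k, "assigned", al$best))
    expect_true(all(al$dissimilarity > 0 & al$dissimilarity <= 1))
  }
  # control-vs-control favours health over a heavily signed state
  co0 <- gen_cohort(cohort_spec(target_state = "SS0", effect_size = 0,
                                seed = 77))
  al0 <- align_cohort(co0, ss)
  expect_lt(al0$dissimilarity["SS0/SS1"], al0$dissimilarity["SS4/SS5"])
})

test_that("hold-out cross-validation behaves at its edges", {
  co <- gen_cohort(cohort_spec(target_state = "SS0", seed = 13))
  set.seed(1)
  one <- holdout_cv(co, gwi_states(), n_repeats = 1)
  expect_true(one$fraction %in% c(0, 1))
  tiny <- cohort_table(matrix(runif(6), 3,
                              dimnames = list(NULL, c("a", "b"))),
                       rep("control", 3), c(a = "CK1", b = "MK6"))
  expect_error(holdout_cv(tiny, gwi_states()), "at least 4")
})
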