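test_that("treatment application clips to the ternary range", {
  net <- gwi_network()
  ill <- gwi_state("SS5")
  up <- apply_treatment(ill, net, treatment_course("MK6", 1L, 1L, 10L))
  expect_identical(up[["MK6"]], 1L)   # 1 + 1 rounds back to 1
  dn <- apply_treatment(ill, net, treatment_course("TEST", 1L, 1L, 10L))
  expect_identical(dn[["TEST"]], 0L)  # -1 + 1 stays in range
  expect_identical(apply_treatment(ill, net, treatment_course()), ill)
  dup <- rbind(as.data.frame(treatment_course("MK6", 1L, 1L, 5L)),
               as.data.frame(treatment_course("MK6", -1L, 2L, 6L)))
  expect_error(apply_treatment(ill, net, dup), "ill-formed")
})

test_that("courses are validated against the network and horizon", {
  net <- gwi_network()
  expect_error(treatment_course("MK6", 2L, 1L, 5L), "effect")
  expect_error(treatment_course("MK6", 1L, 5L, 4L), "t_start")
  expect_error(treatment_course("MK6", 1L, 1L, 5L, allowed = "CK1"),
               "allowed")
  overlap <- treatment_course(c("MK6", "MK6"), c(-1L, -1L),
                              c(1L, 5L), c(10L, 12L))
  expect_error(simulate_course(overlap, gwi_state("SS5"), net, n_runs = 1),
               "overlapping")
  long <- treatment_course("MK6", -1L, 1L, 2000L)
  expect_error(simulate_course(long, gwi_state("SS5"), net, n_runs = 1),
               "horizon")
  ghost <- treatment_course("NOPE", -1L, 1L, 5L)
  expect_error(simulate_course(ghost, gwi_state("SS5"), net, n_runs = 1),
               "unknown")
})

test_that("attractors are absorbing under the empty course", {
  net <- gwi_network()
  set.seed(2)
  healthy <- simulate_course(treatment_course(), gwi_state("SS0"), net,
                             n_runs = 50, max_steps = 200)
  expect_equal(healthy$pct_hhm, 100)
  stuck <- simulate_course(treatment_course(), gwi_state("SS5"), net,
                           n_runs = 50, max_steps = 200)
  expect_equal(stuck$pct_hhm, 0)
})

test_that("course outcomes are seed-reproducible and ternary-closed", {
  net <- gwi_network()
  course <- published_course("SS5")
  set.seed(5)
  a <- simulate_course(course, gwi_state("SS5"), net, n_runs = 100)
  set.seed(5)
  b <- simulate_course(course, gwi_state("SS5"), net, n_runs = 100)
  expect_identical(a$pct_hhm, b$pct_hhm)
  expect_identical(a$final_states, b$final_states)
  expect_true(all(a$final_states %in% c(-1L, 0L, 1L)))
  expect_equal(sum(a$final_counts), 100)
})

test_that("%HHM noise shrinks roughly as 1/sqrt(runs) on a toy search", {
  net <- planted_cure_net()
  start <- c(A = 1L, B = 1L)
  # a 1-step inhibition window cures about half the time when a second,
  # useless window competes for the schedule: use a stochastic 3-node case
  net3 <- ternet_network(c("A", "B", "C"),
                         data.frame(source = c("A", "B", "A"),
                                    target = c("B", "A", "C"),
                                    mode = "activate"))
  s3 <- c(A = 1L, B = 1L, C = 1L)
  course <- treatment_course("A", -1L, 1L, 1L)
  est <- function(n) replicate(25, {
    simulate_course(course, s3, net3, n_runs = n, max_steps = 60)$pct_hhm
  })
  set.seed(6)
  sd_small <- sd(est(20)); sd_big <- sd(est(180))
  expect_gt(sd_small / sd_big, 1.6)  # expect about 3 under root-n scaling
})

test_that("published course fixtures load and beat the untreated baseline", {
  net <- gwi_network()
  for (k in c("SS5", "SS4", "SS2")) {
    f <- system.file("extdata", paste0("course_", tolower(k), ".tsv"),
                     package = "ternet")
    expect_identical(as.data.frame(read_course(f)),
                     as.data.frame(published_course(k)))
  }
  set.seed(9)
  out <- simulate_course(published_course("SS2"), gwi_state("SS2"), net,
                         n_runs = 100)
  expect_gt(out$pct_hhm, 0)
})
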