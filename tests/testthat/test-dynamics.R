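test_that("asynchronous steps move one node one increment toward its image", {
  net <- mutual_activation_net()
  expect_error(asynchronous_step(c(A = 1L, B = 1L), net), "fixed point")
  chain <- ternet_network(c("A", "B"),
                          data.frame(source = "A", target = "B",
                                     mode = "activate"))
  s <- c(A = 1L, B = -1L)  # only B is discrepant; its image is 1
  expect_identical(asynchronous_step(s, chain), c(A = 1L, B = 0L))
  # two discrepant nodes: each chosen about half the time
  set.seed(1)
  s2 <- c(A = 1L, B = 0L)  # images: A -> 0, B -> 1
  picks <- replicate(1000, which(asynchronous_step(s2, net) != s2))
  expect_gt(mean(picks == 1), 0.42)
  expect_lt(mean(picks == 1), 0.58)
})

test_that("trajectories have unit Hamming steps and reach absorbing states", {
  set.seed(7)
  net <- gen_toy_network(6, 0.4, conditional_fraction = 0.2)
  start <- setNames(sample(c(-1L, 0L, 1L), 6, replace = TRUE), net$nodes)
  traj <- simulate_to_attractor(start, net, max_steps = 200, record = TRUE)
  if (nrow(traj$states) > 1) {
    diffs <- abs(traj$states[-1, , drop = FALSE] -
                   traj$states[-nrow(traj$states), , drop = FALSE])
    expect_true(all(rowSums(diffs) == 1))
    expect_true(all(diffs <= 1))
  }
  if (traj$terminated)
    expect_true(is_fixed_point(traj$final, net))
  # a fixed point simulates to itself in zero steps
  fp <- c(A = 1L, B = 1L)
  out <- simulate_to_attractor(fp, mutual_activation_net())
  expect_identical(out$final, fp)
  expect_identical(out$steps, 0L)
  expect_true(out$terminated)
})

test_that("identical seeds give identical trajectories", {
  net <- gwi_network()
  start <- gwi_state("SS2")
  start["CORT"] <- 0L  # perturb off the attractor
  set.seed(11)
  a <- simulate_to_attractor(start, net, record = TRUE)
  set.seed(11)
  b <- simulate_to_attractor(start, net, record = TRUE)
  expect_identical(a$states, b$states)
})

test_that("exhaustive enumeration matches hand-derived fixed points", {
  iso <- ternet_network("A", data.frame(source = character(),
                                        target = character(),
                                        mode = character()))
  expect_identical(nrow(enumerate_fixed_points(iso)), 3L)
  act <- enumerate_fixed_points(mutual_activation_net())
  expect_setequal(state_keys(act), c("-1,-1", "0,0", "1,1"))
  inh <- enumerate_fixed_points(mutual_inhibition_net())
  expect_setequal(state_keys(inh), c("0,0", "1,-1", "-1,1"))
  big <- gen_toy_network(14, 0.2, seed = 2)
  expect_error(enumerate_fixed_points(big), "cap")
})

test_that("Monte Carlo attractor search agrees with the exhaustive oracle", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    net <- gen_toy_network(n, 0.35, conditional_fraction = 0.15)
    oracle <- state_keys(enumerate_fixed_points(net))
    att <- find_attractors(net, n_starts = 10 * 3^n, max_steps = 300)
    found <- state_keys(att$fixed_points)
    expect_true(all(found %in% oracle))       # never invents fixed points
    expect_setequal(found, oracle)            # and recovers all of them
    expect_lte(sum(att$counts), att$n_starts)
  }
})

test_that("one start yields at most one fixed point", {
  set.seed(3)
  att <- find_attractors(mutual_inhibition_net(), n_starts = 1)
  expect_lte(nrow(att$fixed_points), 1L)
})
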