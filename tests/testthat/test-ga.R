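test_that("random courses respect the allowed-target constraint set", {
  cfg <- planted_cure_config()
  expect_identical(nrow(random_course(ga_config(list(A = -1L),
                                                n_interventions = 0))), 0L)
  set.seed(1)
  forced <- random_course(ga_config(list(GRD = -1L), n_interventions = 1,
                                    horizon = 50))
  expect_identical(forced$target, "GRD")
  expect_identical(forced$effect, -1L)
  expect_true(forced$t_start >= 1 && forced$t_stop <= 50)
  # target draws are uniform within binomial error
  set.seed(2)
  draws <- replicate(2000, random_course(cfg)$target)
  expect_gt(mean(draws == "A"), 0.45)
  expect_lt(mean(draws == "A"), 0.55)
  # windows of a shared target never overlap
  set.seed(3)
  for (r in 1:50) {
    co <- random_course(ga_config(list(A = -1L), n_interventions = 3,
                                  horizon = 30))
    o <- order(co$t_start)
    expect_true(all(co$t_start[o][-1] > co$t_stop[o][-3]))
  }
})

test_that("single-splice crossover keeps a's early and b's late interventions", {
  a <- treatment_course("A", -1L, 1L, 10L)
  b <- treatment_course("B", -1L, 50L, 60L)
  child <- crossover_courses(a, b, 30)
  expect_setequal(child$target, c("A", "B"))
  expect_identical(as.data.frame(crossover_courses(a, b, 1)),
                   as.data.frame(b))   # nothing precedes timestep 1
  expect_identical(as.data.frame(crossover_courses(a, b, 1000)),
                   as.data.frame(a))   # splice beyond the horizon
  # same-target overlaps from the b side are dropped
  b2 <- treatment_course("A", -1L, 5L, 20L)
  child2 <- crossover_courses(a, b2, 3)
  expect_identical(nrow(child2), 1L)
  expect_identical(child2$t_start, 1L)
})

test_that("a zero-generation run returns the best of the random population", {
  net <- planted_cure_net()
  cfg <- planted_cure_config(population = 10, generations = 0,
                             eval_runs = 3)
  set.seed(4)
  run <- evolve_course(net, c(A = 1L, B = 1L), cfg)
  expect_identical(length(run$trace), 0L)
  expect_true(run$best_fitness >= 0)
})

test_that("GA matches the exhaustive optimum on the planted-cure space", {
  net <- planted_cure_net()
  start <- c(A = 1L, B = 1L)
  brute <- planted_cure_bruteforce(net, start)
  expect_equal(brute, 100)  # a length-1 window cures deterministically
  cfg <- planted_cure_config(population = 20, generations = 5,
                             eval_runs = 3)
  set.seed(5)
  wins <- replicate(20, {
    evolve_course(net, start, cfg)$best_fitness == brute
  })
  expect_gte(mean(wins), 0.95)
})

test_that("elite fitness is non-decreasing under frozen evaluation", {
  net <- planted_cure_net()
  cfg <- planted_cure_config(population = 12, generations = 8,
                             eval_runs = 4, frozen_eval = TRUE)
  set.seed(6)
  run <- evolve_course(net, c(A = 1L, B = 1L), cfg)
  expect_true(all(diff(run$trace) >= 0))
})

test_that("multi-run best dominates its individual runs", {
  net <- planted_cure_net()
  cfg <- planted_cure_config(population = 8, generations = 2,
                             eval_runs = 3, runs = 4)
  set.seed(7)
  best <- multi_run_best(net, c(A = 1L, B = 1L), cfg)
  fits <- attr(best, "run_fitness")
  expect_identical(length(fits), 4L)
  expect_equal(best$best_fitness, max(fits))
  cfg1 <- planted_cure_config(population = 8, generations = 2,
                              eval_runs = 3, runs = 1)
  set.seed(8)
  one <- multi_run_best(net, c(A = 1L, B = 1L), cfg1)
  set.seed(8)
  solo <- evolve_course(net, c(A = 1L, B = 1L), cfg1)
  expect_identical(one$best_fitness, solo$best_fitness)
})
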