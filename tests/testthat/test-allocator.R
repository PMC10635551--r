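test_that("greedy construction reproduces the worked-example traces", {
  inst <- fixture("toy_4_3")
  cl <- caseload_from_N(17, inst$mix, inst$catalog)
  # pathway order (a1, a2): a1 fills s1 then s2, a2 is forced onto s1
  al <- greedy_allocate(cl, inst)
  expect_equal(unname(al["a1", c("s1", "s2")]), c(8, 2))
  expect_equal(unname(al["a2", "s1"]), 7)
  expect_equal(slv(al, inst, "deterministic")$total, 315)
  # reversed order finds the feasible allocation
  al2 <- greedy_allocate(cl, inst, ordering = c("a2", "a1"))
  expect_equal(unname(al2["a2", "s1"]), 7)
  expect_equal(unname(al2["a1", c("s1", "s2")]), c(2, 8))
  expect_equal(slv(al2, inst, "deterministic")$total, 0)
})

test_that("a single-candidate activity is fully assigned there", {
  inst <- one_activity_instance(avail = 480)
  cl <- caseload_from_N(5, inst$mix, inst$catalog)
  al <- greedy_allocate(cl, inst)
  expect_equal(unname(al["a", "s1"]), 5)
})

test_that("greedy allocations conserve the caseload", {
  for (seed in 1:5) {
    inst <- generate_instance(n_areas = 2, spaces_per_area = 2, n_types = 3,
                              acts_per_path = 2, seed = seed)
    N <- runif(1, 0.3, 1.5) * upper_bound_N(inst)$N_hat
    cl <- caseload_from_N(N, inst$mix, inst$catalog)
    al <- greedy_allocate(cl, inst)
    expect_equal(unname(rowSums(al)), unname(cl$n3), tolerance = 1e-9)
  }
})

test_that("acceptance rules implement TA thresholds and SA probabilities", {
  expect_true(accept_move(-5, 10, "ta"))
  expect_true(accept_move(-5, 10, "sa"))
  expect_true(accept_move(5, 10, "ta"))
  expect_false(accept_move(15, 10, "ta"))
  # SA acceptance probability vanishes as the temperature goes to zero
  set.seed(1)
  expect_false(any(replicate(200, accept_move(1, 1e-8, "sa"))))
  # and approaches exp(-delta/control) at moderate temperature
  set.seed(2)
  acc <- mean(replicate(2000, accept_move(1, 1, "sa")))
  expect_lt(abs(acc - exp(-1)), 0.05)
})

test_that("perturbation moves load off the worst resource and conserves totals", {
  inst <- fixture("toy_4_3")
  cl <- caseload_from_N(17, inst$mix, inst$catalog)
  al <- greedy_allocate(cl, inst)  # SLV 315, worst space s1
  set.seed(3)
  mv <- perturb_allocation(al, inst, "deterministic")
  expect_equal(mv$from, "s1")
  expect_equal(mv$to, "s2")
  expect_equal(mv$activity, "a1")  # a2 has no alternative space
  al2 <- al
  al2[mv$activity, mv$from] <- al2[mv$activity, mv$from] - mv$amount
  al2[mv$activity, mv$to] <- al2[mv$activity, mv$to] + mv$amount
  expect_equal(rowSums(al2), rowSums(al), tolerance = 1e-12)
  # amount follows min(O_obs / E[t], beta): (795-480)/60 = 5.25
  expect_equal(mv$amount, 315 / 60)
})

test_that("no valid move exists on a single-space instance", {
  inst <- one_activity_instance(avail = 480)
  cl <- caseload_from_N(20, inst$mix, inst$catalog)  # over capacity
  al <- greedy_allocate(cl, inst)
  expect_null(perturb_allocation(al, inst, "deterministic"))
})

test_that("the metaheuristic repairs the infeasible greedy start", {
  inst <- fixture("toy_4_3")
  cl <- caseload_from_N(17, inst$mix, inst$catalog)
  al <- greedy_allocate(cl, inst)
  res <- run_metaheuristic(al, inst, "deterministic",
                           control = quiet_mh(seed = 5))
  expect_equal(res$slv, 0)
  expect_equal(rowSums(res$allocation), rowSums(al), tolerance = 1e-9)
  expect_equal(unname(occupancy_det(res$allocation, inst) <= 480 + 1e-9),
               c(TRUE, TRUE))
})

test_that("a zero-SLV start returns immediately", {
  inst <- fixture("toy_4_3")
  cl <- caseload_from_N(17, inst$mix, inst$catalog)
  al <- greedy_allocate(cl, inst, ordering = c("a2", "a1"))
  res <- run_metaheuristic(al, inst, "deterministic",
                           control = quiet_mh(seed = 1))
  expect_identical(res$perturbations, 0L)
  expect_identical(unclass(res$allocation), unclass(al))
})

test_that("an infeasible caseload exits with positive SLV", {
  inst <- fixture("toy_4_3")
  cl <- caseload_from_N(170, inst$mix, inst$catalog)  # 10x the toy counts
  al <- greedy_allocate(cl, inst)
  res <- run_metaheuristic(al, inst, "deterministic",
                           control = quiet_mh(steps = 30, n_controls = 10,
                                              seed = 2))
  expect_gt(res$slv, 0)
  # workload 10*(10*60 + 7*45) = 9150 over 960 available: SLV at least
  # the aggregate overshoot
  expect_gte(sum(pmax(occupancy_det(res$allocation, inst) - 480, 0)),
             9150 - 960)
})

test_that("the metaheuristic is deterministic given a seed", {
  inst <- fixture("toy_4_3")
  cl <- caseload_from_N(17, inst$mix, inst$catalog)
  al <- greedy_allocate(cl, inst)
  pool <- scenario_pool(inst, 30, seed = 7)
  st <- lookup_state(pool, al, inst)
  r1 <- run_metaheuristic(al, inst, "stochastic", st, quiet_mh(seed = 11))
  st2 <- lookup_state(pool, al, inst)
  r2 <- run_metaheuristic(al, inst, "stochastic", st2, quiet_mh(seed = 11))
  expect_identical(unclass(r1$allocation), unclass(r2$allocation))
  expect_identical(r1$slv, r2$slv)
})

test_that("incremental stochastic evaluation equals a full recomputation", {
  inst <- generate_instance(n_areas = 1, spaces_per_area = 3, n_types = 2,
                            acts_per_path = 2, seed = 13)
  N <- 0.95 * upper_bound_N(inst)$N_hat
  cl <- caseload_from_N(N, inst$mix, inst$catalog)
  al <- greedy_allocate(cl, inst)
  pool <- scenario_pool(inst, 40, seed = 3)
  st <- lookup_state(pool, al, inst)
  env <- shcapacity:::mh_env_init(al, inst, "stochastic", st)
  set.seed(21)
  for (k in 1:300) {
    mv <- shcapacity:::propose_move(env$alloc, env$view, env$stats$metric,
                                    env$stats$maxO, env$emean)
    if (is.null(mv)) break
    shcapacity:::mh_env_apply(env, mv)
    if (k %% 60 == 0) {
      full <- slv(env$alloc, inst, "stochastic", env$state)$total
      expect_identical(shcapacity:::mh_env_slv(env), full)
      expect_true(shcapacity:::lookup_state_check(env$state, env$alloc))
    }
  }
  expect_equal(unname(rowSums(env$alloc)), unname(cl$n3), tolerance = 1e-8)
})

test_that("with point masses the stochastic search succeeds iff DET does", {
  for (seed in 1:10) {
    inst <- point_mass_instance(seed)
    N <- runif(1, 0.6, 1.1) * upper_bound_N(inst)$N_hat
    cl <- caseload_from_N(N, inst$mix, inst$catalog)
    al <- greedy_allocate(cl, inst)
    rd <- run_metaheuristic(al, inst, "deterministic",
                            control = quiet_mh(steps = 40, n_controls = 15,
                                               seed = seed))
    pool <- scenario_pool(inst, 4, seed = seed)
    st <- lookup_state(pool, al, inst)
    rs <- run_metaheuristic(al, inst, "stochastic", st,
                            control = quiet_mh(steps = 40, n_controls = 15,
                                               seed = seed))
    expect_identical(rd$slv == 0, rs$slv == 0)
  }
})
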