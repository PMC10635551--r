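test_that("the deterministic LP reproduces hand-solved optima", {
  expect_equal(solve_det_lp(fixture("toy_4_3_path"))$N, 960 / 105,
               tolerance = 1e-9)
  expect_equal(solve_det_lp(one_activity_instance(avail = 480))$N, 8,
               tolerance = 1e-9)
  # two-type toy: the mix (10/17, 7/17) binds through the total workload
  # 915/17 per patient over 960 available
  r <- solve_det_lp(fixture("toy_4_3"))
  expect_equal(r$N, 960 * 17 / 915, tolerance = 1e-9)
})

test_that("the LP text export is well-formed", {
  f <- tempfile(fileext = ".lp")
  write_lp_file(fixture("toy_4_3_path"), f)
  txt <- readLines(f)
  expect_true(any(grepl("Maximize", txt)))
  expect_true(any(grepl("alloc_a1", txt)))
  expect_true(any(grepl("cap_s1.*<=.*480", txt)))
  expect_identical(tail(txt, 1), "End")
  unlink(f)
})

test_that("the LP and the transportation cut condition agree", {
  # dual routes to the same exact optimum
  for (inst in list(fixture("toy_4_3_path"), fixture("toy_4_3"),
                    one_activity_instance())) {
    expect_equal(solve_det_lp(inst)$N,
                 shcapacity:::mincut_det_capacity(inst), tolerance = 1e-9)
  }
})

test_that("heuristic deterministic capacity never beats the LP optimum", {
  for (seed in 1:8) {
    inst <- generate_instance(n_areas = 1, spaces_per_area = sample(2:3, 1),
                              n_types = sample(2:3, 1), acts_per_path = 1,
                              seed = seed)
    lp <- solve_det_lp(inst)
    fit <- assess_capacity(inst, "deterministic", tol = 0.25,
                           control = quiet_mh(seed = seed))
    expect_lte(fit$N_opt, lp$N + 1e-6)
    expect_gte(fit$N_opt, lp$N - 0.5)
  }
})

test_that("the tiny SAA optimum is exact on the two-scenario instance", {
  ts <- two_scenario_instance(service_level = 0.5)
  r <- solve_saa_mip_tiny(ts$instance, ts$pool)
  expect_equal(r$N, 12, tolerance = 1e-9)  # the 80-duration scenario may violate
  r2 <- solve_saa_mip_tiny(set_service_level(ts$instance, 1), ts$pool)
  expect_equal(r2$N, 6, tolerance = 1e-9)  # 480 / 80
})

test_that("with point masses at SL = 1 the SAA optimum equals the LP", {
  hosp <- hospital(list(treatment_area("w", list(
    treatment_space("s1", 120, 1), treatment_space("s2", 120, 1)))))
  cat_ <- pathway_catalog(list(pathway("g", "p", list(
    activity("a1", dist_point(60), c("s1", "s2")),
    activity("a2", dist_point(45), "s1")))))
  inst <- shca_instance(hosp, cat_, case_mix(c(g = 1), list(g = c(p = 1))))
  pool <- scenario_pool_from_samples(list(
    a1 = matrix(60, 2, 8), a2 = matrix(45, 2, 8)))
  lp <- solve_det_lp(inst)
  mip <- solve_saa_mip_tiny(inst, pool)
  expect_equal(mip$N, lp$N, tolerance = 1e-6)
})

test_that("SAA occupancy inside the oracle matches the scenario evaluator", {
  ts <- two_scenario_instance(service_level = 0.5)
  r <- solve_saa_mip_tiny(ts$instance, ts$pool)
  beta <- r$beta["a", "s1"]
  al <- shcapacity:::new_allocation(ts$instance)
  al["a", "s1"] <- beta
  # oracle block convention: first ceiling(beta) pool columns
  st <- structure(list(pool = ts$pool, instance = ts$instance,
                       lists = list(a = list(
                         s1 = seq_len(ceiling(beta - 1e-9)))),
                       unused = list(a = integer(0))),
                  class = "shca_lookups")
  U <- occupancy_scenario(al, st, "s1")
  # hand evaluation of the sample-sum with fractional tail
  manual <- vapply(1:2, function(i) {
    v <- ts$pool$samples$a[i, ]
    fl <- floor(beta + 1e-9)
    sum(v[seq_len(fl)]) + (beta - fl) * v[fl + 1]
  }, numeric(1))
  expect_equal(U, manual, tolerance = 1e-9)
  # the non-violating scenario is exactly at availability
  expect_equal(min(U), 480, tolerance = 1e-6)
})

test_that("the oracle refuses instances beyond its size guards", {
  inst <- generate_instance(n_areas = 1, spaces_per_area = 2, n_types = 3,
                            acts_per_path = 1, families = "point", seed = 1)
  pool <- scenario_pool(inst, 4, seed = 1)
  expect_error(solve_saa_mip_tiny(inst, pool), "2 activities")
  ts <- two_scenario_instance()
  expect_error(solve_saa_mip_tiny(ts$instance, ts$pool, max_lps = 3),
               "intractable")
})
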