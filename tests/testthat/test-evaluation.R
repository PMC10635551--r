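toy_alloc <- function(inst, a1s1, a1s2, a2s1) {
  al <- shcapacity:::new_allocation(inst)
  al["a1", "s1"] <- a1s1
  al["a1", "s2"] <- a1s2
  al["a2", "s1"] <- a2s1
  al
}

test_that("fractional indicator weights follow the floor/ceiling rule", {
  expect_equal(fractional_weight(4.2, 1:7), c(1, 1, 1, 1, 0.2, 0, 0))
  expect_equal(fractional_weight(3, 3:4), c(1, 0))
  expect_equal(fractional_weight(0, 1:3), c(0, 0, 0))
})

test_that("deterministic occupancy matches the worked example", {
  inst <- fixture("toy_4_3")
  al <- toy_alloc(inst, 8, 2, 7)
  expect_equal(unname(occupancy_det(al, inst)), c(795, 120))
  expect_equal(unname(occupancy_det(
    shcapacity:::new_allocation(inst), inst)), c(0, 0))
  # linearity: beta = 2.5 at E[t] = 10
  inst2 <- one_activity_instance(dur = dist_point(10))
  al2 <- shcapacity:::new_allocation(inst2)
  al2["a", "s1"] <- 2.5
  expect_equal(unname(occupancy_det(al2, inst2, "s1")), 25)
})

test_that("scenario occupancy realises floor + fractional samples", {
  inst <- one_activity_instance(avail = 480)
  samples <- matrix(0, nrow = 1, ncol = 8)
  samples[1, c(2, 6, 7)] <- c(5, 7, 10)
  pool <- scenario_pool_from_samples(list(a = samples))
  al <- shcapacity:::new_allocation(inst)
  al["a", "s1"] <- 2.73
  st <- structure(list(pool = pool, instance = inst,
                       lists = list(a = list(s1 = c(2L, 6L, 7L))),
                       unused = list(a = c(1L, 3:5, 8L))),
                  class = "shca_lookups")
  expect_equal(occupancy_scenario(al, st, "s1", 1), 5 + 7 + 0.73 * 10)
  # integer allocation uses whole samples only
  al["a", "s1"] <- 3
  st$lists$a$s1 <- c(1L, 3L, 4L)
  pool2 <- scenario_pool_from_samples(list(a = matrix(4, 1, 8)))
  st$pool <- pool2
  expect_equal(occupancy_scenario(al, st, "s1", 1), 12)
  al["a", "s1"] <- 0
  expect_equal(occupancy_scenario(al, st, "s1", 1), 0)
})

test_that("lookup lists out of sync raise a consistency error", {
  inst <- one_activity_instance(avail = 480)
  pool <- scenario_pool_from_samples(list(a = matrix(4, 1, 8)))
  al <- shcapacity:::new_allocation(inst)
  al["a", "s1"] <- 2.5
  st <- structure(list(pool = pool, instance = inst,
                       lists = list(a = list(s1 = 1:2)),
                       unused = list(a = 3:8)),
                  class = "shca_lookups")
  expect_error(occupancy_scenario(al, st, "s1"), "out of sync")
})

test_that("per-space statistics follow the violation-count identities", {
  ev <- evaluate_space(c(500, 490, 470, 460, 450, 440, 430, 420), 480)
  expect_equal(ev$pr_gt, 0.25)
  expect_equal(ev$pr_le, 0.75)
  expect_identical(ev$pr_le + ev$pr_gt, 1)
  ev2 <- evaluate_space(c(500, 470), 480)
  expect_equal(ev2$E_O, 20)  # conditional on the one violating scenario
  ev3 <- evaluate_space(c(470, 460), 480)
  expect_equal(ev3$E_O, 0)
  expect_equal(ev3$n_violations, 0)
})

test_that("SLV reproduces both printed allocations of the worked example", {
  inst <- fixture("toy_4_3")
  s1 <- slv(toy_alloc(inst, 8, 2, 7), inst, "deterministic")
  expect_equal(s1$total, 315)
  s2 <- slv(toy_alloc(inst, 2.75, 7.25, 7), inst, "deterministic")
  expect_equal(s2$total, 0)
  expect_equal(unname(occupancy_det(toy_alloc(inst, 2.75, 7.25, 7), inst)),
               c(480, 435))
  empty <- shcapacity:::new_allocation(inst)
  expect_equal(slv(empty, inst, "deterministic")$total, 0)
  pool <- scenario_pool(inst, 5, seed = 1)
  st <- lookup_state(pool, empty, inst)
  expect_equal(slv(empty, inst, "stochastic", st)$total, 0)
})

test_that("buffering statistics follow from the expected occupancy", {
  inst <- fixture("toy_4_3")
  al <- toy_alloc(inst, 2.75, 7.25, 7)
  b <- buffering(al, inst, "s2")
  expect_equal(unname(b), c(45, 90.625, 9.375))
  al_full <- toy_alloc(inst, 8, 0, 0)
  expect_equal(unname(buffering(al_full, inst, "s1")), c(0, 100, 0))
  expect_equal(unname(buffering(shcapacity:::new_allocation(inst),
                                inst, "s1")), c(480, 0, 100))
})

test_that("area availability pools spaces linearly", {
  w <- treatment_area("w", list(treatment_space("s1", 480),
                                treatment_space("s2", 480),
                                treatment_space("s3", 480)))
  expect_equal(area_availability(w), 1440)
  expect_equal(area_availability(treatment_area("empty")), 0)
  w2 <- treatment_area("w", w$spaces[1:2])
  expect_equal(area_availability(w) - area_availability(w2), 480)
})

test_that("area mode pools the chance constraint over the area", {
  hosp <- hospital(list(treatment_area("ward", list(
    treatment_space("s1", 480), treatment_space("s2", 480)))))
  cat_ <- pathway_catalog(list(pathway("g", "p", list(
    activity("a", dist_point(60), c("s1", "s2"))))))
  inst <- shca_instance(hosp, cat_, case_mix(c(g = 1), list(g = c(p = 1))),
                        mode = "area")
  view <- shcapacity:::resource_view(inst)
  expect_equal(unname(view$availability), 960)
  expect_identical(view$candidates$a, "ward")
  fit <- assess_capacity(inst, "deterministic", tol = 0.05)
  expect_equal(fit$N_opt, 16, tolerance = 0.05 / 16)
})

test_that("point-mass degeneracy: stochastic SLV vanishes iff DET does", {
  for (seed in 1:6) {
    inst <- point_mass_instance(seed)
    N <- runif(1, 1, 2) * upper_bound_N(inst)$N_hat * 0.7
    cl <- caseload_from_N(N, inst$mix, inst$catalog)
    al <- greedy_allocate(cl, inst)
    det <- slv(al, inst, "deterministic")$total
    pool <- scenario_pool(inst, 4, seed = seed)
    st <- lookup_state(pool, al, inst)
    sto <- slv(al, inst, "stochastic", st)$total
    expect_identical(det == 0, sto == 0)
  }
})

test_that("SAA probabilities agree with the normal convolution CDF", {
  hosp <- hospital(list(treatment_area("w", list(
    treatment_space("s1", 520)))))
  cat_ <- pathway_catalog(list(pathway("g", "p", list(
    activity("a", dist_normal(50, 5), "s1")))))
  inst <- shca_instance(hosp, cat_, case_mix(c(g = 1), list(g = c(p = 1))))
  al <- shcapacity:::new_allocation(inst)
  al["a", "s1"] <- 10
  p_true <- closed_form_service_level(10, list(dist_normal(50, 5)), 520)
  for (nI in c(500, 2000)) {
    pool <- scenario_pool(inst, nI, seed = 31)
    st <- lookup_state(pool, al, inst)
    ev <- slv(al, inst, "stochastic", st)$evaluations$s1
    se <- sqrt(p_true * (1 - p_true) / nI)
    expect_lt(abs(ev$pr_le - p_true), 3 * se)
  }
})

test_that("optional managerial limits add penalty terms", {
  inst <- fixture("toy_4_3")
  al <- toy_alloc(inst, 2.75, 7.25, 7)  # E[U] = (480, 435)
  base <- slv(al, inst, "deterministic")$total
  expect_equal(base, 0)
  lim <- slv(al, inst, "deterministic", limits = list(eu_max = 450))$total
  expect_equal(lim, 30)  # only s1 exceeds the usage cap
})
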