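# Instances built in code for the tests.

# single-type, single-activity instance: capacity T_s1 (+ T_s2) / E[t]
one_activity_instance <- function(avail = c(480, 480), dur = dist_point(60),
                                  service_level = 0.95) {
  spaces <- lapply(seq_along(avail), function(i)
    treatment_space(paste0("s", i), avail[i], service_level))
  hosp <- hospital(list(treatment_area("main", spaces)))
  cat_ <- pathway_catalog(list(pathway("g", "p", list(
    activity("a", dur, paste0("s", seq_along(avail)))))))
  shca_instance(hosp, cat_, case_mix(c(g = 1), list(g = c(p = 1))))
}

# the two-scenario certification instance: one activity, durations 40/80
# equiprobable across scenarios, one space of 480
two_scenario_instance <- function(service_level = 0.5) {
  inst <- one_activity_instance(avail = 480, service_level = service_level)
  pool <- scenario_pool_from_samples(list(a = rbind(rep(40, 16), rep(80, 16))))
  list(instance = inst, pool = pool)
}

# random small instance with point-mass durations only (for degeneracy
# properties)
point_mass_instance <- function(seed, n_spaces = 3, n_acts = 3) {
  generate_instance(n_areas = 1, spaces_per_area = n_spaces,
                    n_types = n_acts, paths_per_type = 1, acts_per_path = 1,
                    families = "point", seed = seed)
}

# a catalogue matching the 21-specialty mix: one unit-duration activity per
# pathway, all usable in a single space (for caseload arithmetic only)
table2_catalog <- function(mix) {
  pws <- list()
  for (g in names(mix$mu1))
    for (p in names(mix$mu2[[g]]))
      pws[[length(pws) + 1L]] <- pathway(g, p, list(
        activity(paste0(gsub("[^A-Za-z]", "", g), "_", p),
                 dist_point(1), "s1")))
  pathway_catalog(pws)
}

quiet_mh <- function(steps = 60, n_controls = 25, alg = "ta", seed = NULL,
                     lambda = 1e6)
  mh_control(alg = alg, lambda = lambda, steps = steps,
             n_controls = n_controls, seed = seed)
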