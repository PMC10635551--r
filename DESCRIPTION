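Package: shcapacity
Title: Stochastic Hospital Capacity Assessment and Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strategic assessment of hospital capacity under uncertain
    treatment durations and lengths of stay. Given a hospital's treatment
    areas and spaces, patient-type care pathways with stochastic activity
    durations, and a fixed case mix, the package estimates the maximum
    caseload treatable over a planning horizon subject to per-space chance
    constraints on time-availability over-usage. Chance constraints are
    handled by sample average approximation over a pre-generated scenario
    pool; feasible resource allocations are constructed greedily and
    refined by simulated annealing or threshold accepting, and the maximum
    caseload is located by an outer binary search over feasibility. Exact
    linear-programming and enumeration oracles certify the heuristic stack
    on tiny instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
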