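## Synthetic instances with controllable structure, and the small named
## fixtures used throughout the documentation and tests: the two-activity
## worked example, the 21-specialty case mix, and a large hospital-shaped
## template with placeholder (synthetic, NOT empirical) duration models.

#' Generate a random problem instance
#'
#' Builds a reproducible synthetic hospital, pathway catalogue and case
#' mix.  Durations are drawn from a configurable mix of families; with
#' `tail_heaviness` near one, piecewise-constant durations carry the heavy
#' right tails typical of empirical treatment-time data (99th percentile
#' at least three times the median).
#'
#' @param n_areas,spaces_per_area Hospital shape.
#' @param n_types,paths_per_type,acts_per_path Demand shape.
#' @param avail_range Range the per-space availabilities are drawn from.
#' @param service_level Uniform service level for every space.
#' @param families Duration families to draw from (subset of
#'   `"piecewise"`, `"point"`, `"normal"`, `"uniform"`).
#' @param tail_heaviness In `[0, 1]`: probability that a piecewise duration
#'   is given a heavy right tail.
#' @param mix_concentration Dirichlet-style concentration of the case mix
#'   (small values give lopsided mixes).
#' @param mean_range Range of expected activity durations.
#' @param max_candidates Upper bound on candidate spaces per activity.
#' @param seed Integer seed; the same seed reproduces the instance exactly.
#' @return An [shca_instance()] object.
#' @export
generate_instance <- function(n_areas = 2, spaces_per_area = 2,
                              n_types = 2, paths_per_type = 1,
                              acts_per_path = 2,
                              avail_range = c(300, 600),
                              service_level = 0.95,
                              families = c("piecewise", "point",
                                           "normal", "uniform"),
                              tail_heaviness = 0,
                              mix_concentration = 1,
                              mean_range = c(20, 90),
                              max_candidates = 3, seed = 1) {
  stopifnot(n_areas >= 1, spaces_per_area >= 0, n_types >= 1,
            paths_per_type >= 1, acts_per_path >= 1,
            tail_heaviness >= 0, tail_heaviness <= 1)
  if (n_areas * spaces_per_area == 0 && n_types * acts_per_path > 0)
    stop("cannot generate activities for a hospital with no spaces")
  families <- match.arg(families, several.ok = TRUE)
  set.seed(as.integer(seed))
  areas <- lapply(seq_len(n_areas), function(w)
    treatment_area(sprintf("w%02d", w),
                   lapply(seq_len(spaces_per_area), function(s)
                     treatment_space(sprintf("w%02d_s%02d", w, s),
                                     runif(1, avail_range[1L], avail_range[2L]),
                                     service_level))))
  hosp <- hospital(areas)
  sids <- names(hospital_spaces(hosp))
  rand_dist <- function(mu) {
    fam <- sample(families, 1L)
    if (fam == "piecewise") {
      heavy <- runif(1) < tail_heaviness
      if (heavy)
        dist_piecewise(mu * c(0.5, 1, 1.5, 12), c(0.45, 0.45, 0.1))
      else
        dist_piecewise(mu * c(0.6, 0.9, 1.1, 1.4), c(0.25, 0.5, 0.25))
    } else if (fam == "point") dist_point(mu)
    else if (fam == "normal") dist_normal(mu, mu / 8)
    else dist_uniform(0.7 * mu, 1.3 * mu)
  }
  pws <- list()
  mu1 <- numeric(0)
  mu2 <- list()
  for (g in seq_len(n_types)) {
    gid <- sprintf("type%02d", g)
    v2 <- rgamma(paths_per_type, shape = mix_concentration) + 1e-6
    v2 <- v2 / sum(v2)
    names(v2) <- sprintf("path%02d", seq_len(paths_per_type))
    mu2[[gid]] <- v2
    for (p in seq_len(paths_per_type)) {
      acts <- lapply(seq_len(acts_per_path), function(k) {
        mu <- runif(1, mean_range[1L], mean_range[2L])
        nc <- sample(seq_len(min(max_candidates, length(sids))), 1L)
        activity(sprintf("%s_p%02d_a%02d", gid, p, k),
                 duration = rand_dist(mu),
                 spaces = sample(sids, nc),
                 type = sample(c("preop", "sur", "pac", "ic", "postop"), 1L))
      })
      pws[[length(pws) + 1L]] <- pathway(gid, sprintf("path%02d", p), acts)
    }
  }
  v1 <- rgamma(n_types, shape = mix_concentration) + 1e-6
  mu1 <- setNames(v1 / sum(v1), sprintf("type%02d", seq_len(n_types)))
  shca_instance(hosp, pathway_catalog(pws), case_mix(mu1, mu2))
}

## Table of the 21-specialty case and path mix used throughout the
## numerical examples.  Sub-type vectors map, in listed order, to the
## pathway variants (dosa, dosa_icu, acute, acute_icu) truncated to the
## number of entries; this position-to-pathway mapping is an assumption
## documented in the methods vignette.
table2_data <- function() {
  list(
    "Acute Surgical"          = list(0.036,   c(0.95, 0.05)),
    "Breast and Endocrine"    = list(0.033,   c(0.8455, 0.0445, 0.1045, 0.0055)),
    "Colorectal"              = list(0.027,   c(0.6365, 0.0335, 0.3135, 0.0165)),
    "Cardia Surgery"          = list(0.056,   c(0.7695, 0.0405, 0.1805, 0.0095)),
    "Dental"                  = list(0.0,     c(1.0)),
    "Ear, Nose & Throat"      = list(0.036,   c(0.7695, 0.0405, 0.1805, 0.0095)),
    "Faciomaxillary"          = list(0.028,   c(0.513, 0.027, 0.437, 0.023)),
    "Gastroenterology"        = list(0.012,   c(0.95, 0.05)),
    "Gynaecology"             = list(0.0,     c(1.0)),
    "Hepatobiliary"           = list(0.027,   c(0.703, 0.037, 0.247, 0.013)),
    "Liver Transplant"        = list(0.00489, c(0.1616, 0.0085, 0.7885, 0.0415)),
    "Neurosurgery"            = list(0.043,   c(0.6745, 0.0355, 0.2755, 0.0145)),
    "Ophthalmology"           = list(0.163,   c(0.9025, 0.0975)),
    "Orthopaedic"             = list(0.216,   c(0.4085, 0.0215, 0.5415, 0.0285)),
    "Plastics"                = list(0.109,   c(0.7695, 0.0405, 0.1805, 0.0095)),
    "Respiratory"             = list(0.0,     c(0.95, 0.05)),
    "Renal Transplant"        = list(0.041,   c(0.608, 0.032, 0.342, 0.018)),
    "Trauma"                  = list(0.003,   c(0.95, 0.05)),
    "Upper Gastro-Intestinal" = list(0.03811, c(0.836, 0.044, 0.114, 0.006)),
    "Urology"                 = list(0.086,   c(0.8265, 0.0435, 0.1235, 0.0065)),
    "Vascular"                = list(0.041,   c(0.532, 0.028, 0.418, 0.022)))
}

path_variant_names <- c("dosa", "dosa_icu", "acute", "acute_icu")

#' Named fixtures
#'
#' Small reference objects used in examples and tests:
#' \describe{
#'   \item{`toy_4_3`}{The two-activity/two-space worked example as an
#'     instance: activities `a1` (duration 60, usable in `s1` and `s2`)
#'     and `a2` (duration 45, usable only in `s1`), both spaces with
#'     availability 480.  The counts `[10, 7]` arise at `N = 17` from the
#'     two one-activity patient types with mix `(10/17, 7/17)`.}
#'   \item{`toy_4_3_path`}{The same hospital with a single patient type
#'     whose one pathway is `(a1, a2)`, the natural re-pose for capacity
#'     questions (deterministic capacity `960/105`).}
#'   \item{`table2_mix`}{The 21-specialty case mix with sub-type vectors,
#'     as a [case_mix()] object.}
#'   \item{`table3_totals`}{Named vector of reference annual capacity
#'     totals by risk column (`deterministic`, `risk20` ... `risk1`), used
#'     for internal-consistency arithmetic.}
#'   \item{`large_template`}{A hospital-shaped large instance (65 ward
#'     areas, preop/pac care areas, 19 theatres, 21 specialties with up to
#'     four pathway variants) carrying synthetic placeholder duration
#'     models; its shape, not its durations, is the point.}
#' }
#'
#' @param name Fixture name.
#' @return The fixture object (an instance, case mix, or named vector).
#' @export
fixture <- function(name = c("toy_4_3", "toy_4_3_path", "table2_mix",
                             "table3_totals", "large_template")) {
  name <- match.arg(name)
  switch(name,
    toy_4_3 = {
      hosp <- hospital(list(treatment_area("main", list(
        treatment_space("s1", 480), treatment_space("s2", 480)))))
      cat_ <- pathway_catalog(list(
        pathway("g1", "p1", list(activity("a1", dist_point(60), c("s1", "s2")))),
        pathway("g2", "p1", list(activity("a2", dist_point(45), "s1")))))
      mix <- case_mix(c(g1 = 10 / 17, g2 = 7 / 17),
                      list(g1 = c(p1 = 1), g2 = c(p1 = 1)))
      shca_instance(hosp, cat_, mix)
    },
    toy_4_3_path = {
      hosp <- hospital(list(treatment_area("main", list(
        treatment_space("s1", 480), treatment_space("s2", 480)))))
      cat_ <- pathway_catalog(list(
        pathway("g1", "p1", list(
          activity("a1", dist_point(60), c("s1", "s2")),
          activity("a2", dist_point(45), "s1")))))
      mix <- case_mix(c(g1 = 1), list(g1 = c(p1 = 1)))
      shca_instance(hosp, cat_, mix)
    },
    table2_mix = {
      tab <- table2_data()
      mu1 <- vapply(tab, `[[`, numeric(1), 1L)
      mu2 <- lapply(tab, function(row)
        setNames(row[[2L]], path_variant_names[seq_along(row[[2L]])]))
      ## one printed sub-type vector sums to 1.0001; values are kept
      ## verbatim, so the fixture relaxes the validation tolerance
      case_mix(mu1, mu2, tol = 2e-4)
    },
    table3_totals = c(deterministic = 12444.44, risk20 = 10946.6,
                      risk15 = 10558.5, risk10 = 10093.9, risk5 = 9412.77,
                      risk2.5 = 8831.46, risk1 = 8163.18),
    large_template = large_template_instance())
}

## 65 ward areas plus surgical-care and theatre areas; 21 specialties with
## up to four pathway variants.  Duration models are synthetic placeholders
## (plausible scale, not fitted to any hospital's records).
large_template_instance <- function() {
  set.seed(20231109L)
  wards <- lapply(seq_len(65), function(w)
    treatment_area(sprintf("ward%02d", w),
                   lapply(seq_len(14), function(s)
                     treatment_space(sprintf("ward%02d_bed%02d", w, s),
                                     10080))))  # minutes per week
  theatres <- treatment_area("theatres",
    lapply(seq_len(19), function(s)
      treatment_space(sprintf("theatre%02d", s), 2400)))
  preop <- treatment_area("surgical_care",
    lapply(seq_len(30), function(s)
      treatment_space(sprintf("sc%02d", s), 10080)))
  icu <- treatment_area("icu",
    lapply(seq_len(20), function(s)
      treatment_space(sprintf("icu%02d", s), 10080)))
  hosp <- hospital(c(wards, list(preop, theatres, icu)))
  theatre_ids <- sprintf("theatre%02d", seq_len(19))
  sc_ids <- sprintf("sc%02d", seq_len(30))
  icu_ids <- sprintf("icu%02d", seq_len(20))
  tab <- table2_data()
  pws <- list()
  gi <- 0L
  for (g in names(tab)) {
    gi <- gi + 1L
    ward_block <- sprintf("ward%02d_bed%02d",
                          rep(((gi - 1L) %% 65L) + c(1L, 2L), each = 14L),
                          rep(seq_len(14), 2L))
    sub <- tab[[g]][[2L]]
    for (pi in seq_along(sub)) {
      variant <- path_variant_names[pi]
      icu_stay <- grepl("icu", variant)
      mk <- function(stage, dist, cand)
        activity(sprintf("g%02d_%s_%s", gi, variant, stage), dist, cand,
                 type = stage)
      acts <- list(
        mk("preop", dist_piecewise(c(20, 45, 90), c(0.7, 0.3)), sc_ids),
        mk("sur", dist_piecewise(c(30, 90, 180, 600), c(0.5, 0.4, 0.1)),
           theatre_ids))
      acts <- c(acts, if (icu_stay)
        list(mk("ic", dist_piecewise(c(720, 1440, 5760), c(0.6, 0.4)),
                icu_ids))
        else
          list(mk("pac", dist_piecewise(c(15, 60, 240), c(0.8, 0.2)),
                  sc_ids)))
      acts <- c(acts, list(
        mk("postop", dist_piecewise(c(360, 1440, 10080), c(0.55, 0.45)),
           ward_block)))
      pws[[length(pws) + 1L]] <- pathway(g, path_variant_names[pi], acts)
    }
  }
  mu1 <- vapply(tab, `[[`, numeric(1), 1L)
  mu2 <- lapply(tab, function(row)
    setNames(row[[2L]], path_variant_names[seq_along(row[[2L]])]))
  shca_instance(hosp, pathway_catalog(pws), case_mix(mu1, mu2, tol = 2e-4))
}
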