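## Model entities: hospitals (areas partitioned into treatment spaces),
## patient pathways (ordered activities with candidate spaces), case mixes,
## and the deterministic caseload arithmetic linking the total caseload N to
## per-type, per-path and per-activity counts.

#' Treatment space
#'
#' A single bed or operating theatre with a time availability over the
#' planning horizon and a service (reliability) level for its chance
#' constraint `Pr(U_s <= T_s) >= SL_s`.
#'
#' @param id Unique identifier (character).
#' @param availability Time availability `T_s` over the horizon (> 0).
#' @param service_level `SL_s` in `[0, 1]`; the risk level is `1 - SL_s`.
#' @param o_max Cap on per-scenario over-usage `O_s^max` (time units);
#'   `Inf` (default) leaves the extent of over-usage unrestricted.
#' @return An object of class `shca_space`.
#' @export
treatment_space <- function(id, availability, service_level = 0.95,
                            o_max = Inf) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.finite(availability), availability > 0,
            service_level >= 0, service_level <= 1, o_max >= 0)
  structure(list(id = id, availability = as.numeric(availability),
                 service_level = as.numeric(service_level),
                 risk_level = 1 - as.numeric(service_level),
                 o_max = as.numeric(o_max)),
            class = "shca_space")
}

#' Treatment area
#'
#' A ward or theatre suite partitioned into treatment spaces.  In
#' area-level mode the area is the resource, with pooled availability
#' `sum_s T_s` (equal to `T_w |S_w|` for homogeneous spaces).
#'
#' @param id Unique identifier (character).
#' @param spaces List of [treatment_space()] objects (may be empty: an
#'   area with no spaces is unusable).
#' @return An object of class `shca_area`.
#' @export
treatment_area <- function(id, spaces = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id), is.list(spaces))
  for (s in spaces) stopifnot(inherits(s, "shca_space"))
  structure(list(id = id, spaces = spaces), class = "shca_area")
}

#' Area availability
#'
#' Pooled time availability of a treatment area: the sum of its spaces'
#' availabilities (`T_w |S_w|` when spaces are homogeneous).  Removing a
#' space from the area reduces availability by exactly that space's
#' availability, which is the basic what-if lever of area-level analyses.
#'
#' @param area An [treatment_area()] object.
#' @return Pooled availability in time units (0 for an empty area).
#' @export
area_availability <- function(area) {
  stopifnot(inherits(area, "shca_area"))
  if (length(area$spaces) == 0L) return(0)
  sum(vapply(area$spaces, `[[`, numeric(1), "availability"))
}

#' Hospital
#'
#' @param areas List of [treatment_area()] objects; area and space
#'   identifiers must be unique and every space belongs to exactly one area.
#' @param horizon Planning horizon `T` (> 0); defaults to the largest space
#'   availability. Every space availability must satisfy `T_s <= T`.
#' @return An object of class `shca_hospital`.
#' @export
hospital <- function(areas, horizon = NULL) {
  stopifnot(is.list(areas))
  for (w in areas) stopifnot(inherits(w, "shca_area"))
  aid <- vapply(areas, `[[`, character(1), "id")
  if (anyDuplicated(aid)) stop("area identifiers must be unique")
  sid <- unlist(lapply(areas, function(w)
    vapply(w$spaces, `[[`, character(1), "id")), use.names = FALSE)
  if (anyDuplicated(sid)) stop("space identifiers must be unique")
  avail <- unlist(lapply(areas, function(w)
    vapply(w$spaces, `[[`, numeric(1), "availability")), use.names = FALSE)
  if (is.null(horizon)) horizon <- if (length(avail)) max(avail) else 1
  stopifnot(is.finite(horizon), horizon > 0)
  if (length(avail) && any(avail > horizon + 1e-9))
    stop("space availability exceeds the planning horizon")
  structure(list(horizon = as.numeric(horizon), areas = areas),
            class = "shca_hospital")
}

hospital_spaces <- function(hosp) {
  out <- list()
  for (w in hosp$areas) for (s in w$spaces) out[[s$id]] <- s
  out
}

space_area_map <- function(hosp) {
  out <- character(0)
  for (w in hosp$areas)
    for (s in w$spaces) out[s$id] <- w$id
  out
}

#' Activity within a patient pathway
#'
#' @param id Unique identifier (character); an activity belongs to exactly
#'   one pathway.
#' @param duration An `shca_dist` duration model.
#' @param spaces Character vector of candidate space identifiers `S_a`
#'   (non-empty).
#' @param type Activity type from the usual vocabulary (e.g. `"preop"`,
#'   `"sur"`, `"pac"`, `"ic"`, `"postop"`); free-form but recorded.
#' @param unit Optional specialty unit label.
#' @return An object of class `shca_activity`.
#' @export
activity <- function(id, duration, spaces, type = "generic", unit = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            inherits(duration, "shca_dist"),
            is.character(spaces), length(spaces) >= 1L)
  structure(list(id = id, type = type, unit = unit, duration = duration,
                 spaces = unique(spaces)),
            class = "shca_activity")
}

#' Patient pathway
#'
#' Ordered care plan of one patient sub-type.
#'
#' @param type Patient type identifier `g`.
#' @param path Sub-type (pathway) identifier `p`.
#' @param activities Ordered list of [activity()] objects.
#' @return An object of class `shca_pathway`.
#' @export
pathway <- function(type, path, activities) {
  stopifnot(is.character(type), is.character(path), is.list(activities),
            length(activities) >= 1L)
  for (a in activities) stopifnot(inherits(a, "shca_activity"))
  structure(list(type = type, path = path, activities = activities),
            class = "shca_pathway")
}

#' Pathway catalogue
#'
#' All pathways of all patient types, with a flattened activity index.
#' Every activity must appear in exactly one pathway.
#'
#' @param pathways List of [pathway()] objects.
#' @return An object of class `shca_catalog` with components `pathways`,
#'   `activities` (named list) and `index` (a data frame with one row per
#'   activity: activity, type, path, position).
#' @export
pathway_catalog <- function(pathways) {
  stopifnot(is.list(pathways), length(pathways) >= 1L)
  for (p in pathways) stopifnot(inherits(p, "shca_pathway"))
  key <- vapply(pathways, function(p) paste(p$type, p$path, sep = "\r"),
                character(1))
  if (anyDuplicated(key)) stop("duplicate (type, path) pair in catalogue")
  acts <- list()
  idx <- list()
  for (p in pathways) {
    for (k in seq_along(p$activities)) {
      a <- p$activities[[k]]
      if (!is.null(acts[[a$id]]))
        stop("activity '", a$id, "' appears in more than one pathway")
      acts[[a$id]] <- a
      idx[[length(idx) + 1L]] <- data.frame(
        activity = a$id, type = p$type, path = p$path, position = k,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(pathways = pathways, activities = acts,
                 index = do.call(rbind, idx)),
            class = "shca_catalog")
}

#' Case mix
#'
#' Proportional composition of patient types (`mu1`) and, within each type,
#' of its sub-types (`mu2`).
#'
#' @param mu1 Named numeric vector of patient-type proportions, summing
#'   to one within `tol`.
#' @param mu2 Named list (by type) of named numeric vectors (by path), each
#'   summing to one within `tol`.
#' @param tol Validation tolerance on each sum (default `1e-9`).
#' @param renormalise If `TRUE`, proportions are rescaled to sum exactly to
#'   one after the tolerance check; off by default so that user data summing
#'   imperfectly is surfaced rather than silently adjusted.
#' @return An object of class `shca_mix`.
#' @export
case_mix <- function(mu1, mu2, tol = 1e-9, renormalise = FALSE) {
  stopifnot(is.numeric(mu1), !is.null(names(mu1)),
            is.list(mu2), !is.null(names(mu2)))
  if (any(mu1 < 0)) stop("case-mix proportions must be non-negative")
  if (abs(sum(mu1) - 1) > tol)
    stop("patient-type mix sums to ", format(sum(mu1), digits = 12),
         ", not 1 (tolerance ", tol, ")")
  if (renormalise) mu1 <- mu1 / sum(mu1)
  if (!setequal(names(mu2), names(mu1)))
    stop("mu2 must provide a sub-type mix for exactly the types in mu1")
  for (g in names(mu2)) {
    v <- mu2[[g]]
    if (any(v < 0)) stop("sub-type mix for '", g, "' has negative entries")
    if (abs(sum(v) - 1) > tol)
      stop("sub-type mix for '", g, "' sums to ",
           format(sum(v), digits = 12), ", not 1 (tolerance ", tol, ")")
    if (renormalise) mu2[[g]] <- v / sum(v)
  }
  structure(list(mu1 = mu1, mu2 = mu2[names(mu1)]), class = "shca_mix")
}

#' Assemble a problem instance
#'
#' Bundles a hospital, a pathway catalogue and a case mix, and
#' cross-validates them: every activity's candidate spaces must exist in
#' the hospital, and the case mix must cover exactly the catalogue's types
#' and paths.
#'
#' @param hospital An [hospital()] object.
#' @param catalog A [pathway_catalog()] object.
#' @param mix A [case_mix()] object.
#' @param mode `"space"` (chance constraint per treatment space) or
#'   `"area"` (pooled per treatment area).
#' @return An object of class `shca_instance`.
#' @export
shca_instance <- function(hospital, catalog, mix, mode = c("space", "area")) {
  mode <- match.arg(mode)
  stopifnot(inherits(hospital, "shca_hospital"),
            inherits(catalog, "shca_catalog"),
            inherits(mix, "shca_mix"))
  sp <- hospital_spaces(hospital)
  for (a in catalog$activities) {
    bad <- setdiff(a$spaces, names(sp))
    if (length(bad))
      stop("activity '", a$id, "' names unknown space(s): ",
           paste(bad, collapse = ", "))
  }
  types <- unique(catalog$index$type)
  if (!setequal(types, names(mix$mu1)))
    stop("case mix types do not match catalogue types")
  for (g in types) {
    paths <- unique(catalog$index$path[catalog$index$type == g])
    if (!setequal(paths, names(mix$mu2[[g]])))
      stop("sub-type mix for '", g, "' does not match catalogue paths")
  }
  structure(list(hospital = hospital, catalog = catalog, mix = mix,
                 mode = mode),
            class = "shca_instance")
}

#' @export
print.shca_instance <- function(x, ...) {
  ns <- length(hospital_spaces(x$hospital))
  cat("<shca_instance> (", x$mode, " mode)\n", sep = "")
  cat("  areas:", length(x$hospital$areas), " spaces:", ns,
      " horizon:", x$hospital$horizon, "\n")
  cat("  patient types:", length(x$mix$mu1),
      " pathways:", length(x$catalog$pathways),
      " activities:", length(x$catalog$activities), "\n")
  invisible(x)
}

## Per-activity case-mix multiplier m_a = mu1_g * mu2_{g,p}, so that
## n3_a = m_a * N.  Named by activity id, in catalogue order.
activity_multipliers <- function(instance) {
  idx <- instance$catalog$index
  m <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx)))
    m[r] <- instance$mix$mu1[[idx$type[r]]] *
      instance$mix$mu2[[idx$type[r]]][[idx$path[r]]]
  setNames(m, idx$activity)
}

## Expected activity durations, named by activity id, catalogue order.
activity_means <- function(instance) {
  vapply(instance$catalog$activities, function(a) mean(a$duration),
         numeric(1))
}

#' Caseload implied by a total number of patients
#'
#' Applies the case-mix arithmetic `n1_g = mu1_g N`,
#' `n2_{g,p} = mu2_{g,p} n1_g`, `n3_a = n2_{g,p}` for every activity on the
#' pathway.  Counts are real-valued by default (a fractional patient is one
#' whose treatment completes in the next period); `integer = TRUE` floors
#' the per-path counts if whole patients are required.
#'
#' @param N Total caseload (>= 0).
#' @param mix A [case_mix()] object.
#' @param catalog A [pathway_catalog()] object.
#' @param integer Round per-path counts down to whole patients (default
#'   `FALSE`).
#' @return An object of class `shca_caseload` with components `N`, `n1`,
#'   `n2`, `n3`.
#' @examples
#' # a two-type mix at N = 100
#' @export
caseload_from_N <- function(N, mix, catalog, integer = FALSE) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 0)
    stop("N must be a single non-negative number")
  stopifnot(inherits(mix, "shca_mix"), inherits(catalog, "shca_catalog"))
  n1 <- mix$mu1 * N
  n2 <- lapply(names(mix$mu1), function(g) mix$mu2[[g]] * n1[[g]])
  names(n2) <- names(mix$mu1)
  if (integer) n2 <- lapply(n2, floor)
  idx <- catalog$index
  n3 <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx)))
    n3[r] <- n2[[idx$type[r]]][[idx$path[r]]]
  n3 <- setNames(n3, idx$activity)
  if (integer) n1 <- vapply(n2, sum, numeric(1))
  structure(list(N = if (integer) sum(n1) else N, n1 = n1, n2 = n2, n3 = n3),
            class = "shca_caseload")
}

#' @export
print.shca_caseload <- function(x, ...) {
  cat("<shca_caseload> N =", format(x$N), "over", length(x$n1), "types,",
      length(x$n3), "activities\n")
  invisible(x)
}

#' Pre-computed upper bounds for the capacity search
#'
#' A total-time relaxation: the caseload bound divides the hospital's total
#' availability by the expected workload per patient,
#' `Nhat = sum_s T_s / sum_g mu1_g sum_p mu2_{g,p} sum_a E[t_a]`.
#' Space compatibility is ignored, so `Nhat` is never below the true
#' deterministic optimum; it is used only to initialise the binary search,
#' where looseness costs iterations, not correctness.  Per-allocation
#' bounds are `betahat_{a,s} = min(ceiling(n3hat_a),
#' ceiling(T_s / min positive support of t_a))` (the second term is dropped
#' when the support reaches zero).
#'
#' @param instance An [shca_instance()] object.
#' @return An object of class `shca_bounds` with components `N_hat`,
#'   `n1_hat`, `n2_hat`, `n3_hat` and `beta_hat` (activity x space matrix).
#' @export
upper_bound_N <- function(instance) {
  stopifnot(inherits(instance, "shca_instance"))
  sp <- hospital_spaces(instance$hospital)
  total_avail <- if (length(sp)) sum(vapply(sp, `[[`, numeric(1), "availability")) else 0
  m <- activity_multipliers(instance)
  emean <- activity_means(instance)
  emean <- emean[names(m)]
  per_patient <- sum(m * emean)
  if (total_avail > 0 && per_patient <= 0)
    stop("expected workload per patient is zero; the caseload bound is undefined")
  N_hat <- if (total_avail == 0) 0 else total_avail / per_patient
  n1_hat <- instance$mix$mu1 * N_hat
  n2_hat <- lapply(names(instance$mix$mu1), function(g)
    instance$mix$mu2[[g]] * n1_hat[[g]])
  names(n2_hat) <- names(instance$mix$mu1)
  n3_hat <- m * N_hat
  beta_hat <- matrix(0, nrow = length(m), ncol = length(sp),
                     dimnames = list(names(m), names(sp)))
  for (aid in names(m)) {
    a <- instance$catalog$activities[[aid]]
    smin <- dist_support_min(a$duration)
    for (sid in a$spaces) {
      cap_n <- ceiling(n3_hat[[aid]])
      cap_t <- if (is.finite(smin) && smin > 0)
        ceiling(sp[[sid]]$availability / smin) else Inf
      beta_hat[aid, sid] <- min(cap_n, cap_t)
    }
  }
  structure(list(N_hat = N_hat, n1_hat = n1_hat, n2_hat = n2_hat,
                 n3_hat = n3_hat, beta_hat = beta_hat),
            class = "shca_bounds")
}

## ---- resource view -------------------------------------------------------
## The evaluation, allocation and search layers operate on "resources":
## the treatment spaces themselves (space mode) or whole areas with pooled
## availability (area mode).  Candidate sets are mapped accordingly
## (W_a = areas containing any candidate space of a).

resource_view <- function(instance) {
  hosp <- instance$hospital
  sp <- hospital_spaces(hosp)
  if (instance$mode == "space") {
    ids <- names(sp)
    avail <- vapply(sp, `[[`, numeric(1), "availability")
    sl <- vapply(sp, `[[`, numeric(1), "service_level")
    omax <- vapply(sp, `[[`, numeric(1), "o_max")
    cand <- lapply(instance$catalog$activities, `[[`, "spaces")
  } else {
    keep <- vapply(hosp$areas, function(w) length(w$spaces) > 0, logical(1))
    areas <- hosp$areas[keep]
    ids <- vapply(areas, `[[`, character(1), "id")
    avail <- setNames(vapply(areas, area_availability, numeric(1)), ids)
    sl <- setNames(vapply(areas, function(w) {
      v <- vapply(w$spaces, `[[`, numeric(1), "service_level")
      if (length(unique(v)) > 1L)
        stop("area '", w$id, "' has mixed service levels; area mode needs one")
      v[1L]
    }, numeric(1)), ids)
    omax <- setNames(vapply(areas, function(w)
      min(vapply(w$spaces, `[[`, numeric(1), "o_max")), numeric(1)), ids)
    s2w <- space_area_map(hosp)
    cand <- lapply(instance$catalog$activities, function(a)
      intersect(ids, unique(unname(s2w[a$spaces]))))
  }
  names(avail) <- ids
  names(sl) <- ids
  names(omax) <- ids
  list(ids = ids, availability = avail, service_level = sl, o_max = omax,
       candidates = cand)
}
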