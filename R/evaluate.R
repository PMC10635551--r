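## Occupancy and service-level evaluation.
##
## Deterministic occupancy is E[U_s] = sum_a beta_{a,s} E[t_a].  Scenario
## occupancy realises floor(beta) full sampled durations plus the
## fractional remainder times one further sample, the samples being fixed
## by the lookup lists.  The service-level violation (SLV) score is the
## quantity the lower-level search drives to zero:
##   DET:   sum_s max(E[U_s] - T_s, 0)
##   STOCH: sum_s max(SL_s - Pr(U_s <= T_s), 0).

#' Fractional indicator weight of a pool realisation
#'
#' The weight with which realisation `n` of an activity counts towards a
#' space's occupancy under allocation value `beta`: 1 for
#' `n <= floor(beta)`, the fractional part at `n = ceiling(beta)` when
#' `beta` is non-integer, and 0 beyond.
#'
#' @param beta Allocation value (>= 0).
#' @param n Realisation index (>= 1); vectorised.
#' @return Weights in `[0, 1]`.
#' @examples
#' fractional_weight(4.2, 1:6)  # 1 1 1 1 0.2 0
#' @export
fractional_weight <- function(beta, n) {
  stopifnot(length(beta) == 1L, beta >= 0, all(n >= 1))
  fl <- beta_floor(beta)
  fr <- beta - fl
  if (fr < 1e-9) fr <- 0
  ifelse(n <= fl, 1, ifelse(n == fl + 1L & fr > 0, fr, 0))
}

## Empty allocation matrix (activities x resources) for an instance.
new_allocation <- function(instance, view = resource_view(instance)) {
  aids <- names(instance$catalog$activities)
  m <- matrix(0, nrow = length(aids), ncol = length(view$ids),
              dimnames = list(aids, view$ids))
  structure(m, class = c("shca_allocation", "matrix", "array"),
            mode = instance$mode)
}

#' @export
print.shca_allocation <- function(x, ...) {
  nz <- which(x > 0, arr.ind = TRUE)
  cat("<shca_allocation> (", attr(x, "mode"), " mode) ",
      nrow(nz), " positive entries\n", sep = "")
  if (nrow(nz)) {
    df <- data.frame(activity = rownames(x)[nz[, 1L]],
                     resource = colnames(x)[nz[, 2L]],
                     beta = x[nz])
    print(df[order(df$activity, df$resource), ], row.names = FALSE)
  }
  invisible(x)
}

#' Deterministic occupancy of a resource
#'
#' `E[U_s] = sum_a beta_{a,s} E[t_a]`.
#'
#' @param allocation Allocation matrix.
#' @param instance The instance.
#' @param resource Resource (space or area) identifier; all resources if
#'   omitted.
#' @return Named numeric vector of expected occupancies.
#' @export
occupancy_det <- function(allocation, instance, resource = NULL) {
  emean <- activity_means(instance)
  emean <- emean[rownames(allocation)]
  out <- as.numeric(crossprod(allocation, emean))
  names(out) <- colnames(allocation)
  if (is.null(resource)) out else out[resource]
}

## Occupancy contribution of one (activity, resource) pair across all
## scenarios, per the lookup-list semantics.
contribution_vector <- function(state, beta, aid, rid) {
  ns <- state$pool$n_scenarios
  if (beta <= 0) return(numeric(ns))
  L <- state$lists[[aid]][[rid]]
  fl <- beta_floor(beta)
  fr <- beta - fl
  if (fr < 1e-9) fr <- 0
  if (is.null(L) || length(L) != (if (fr > 0) fl + 1L else fl))
    stop("lookup list for (", aid, ", ", rid, ") is out of sync with the ",
         "allocation (|L| = ", length(L), ", ceiling(beta) = ",
         beta_ceil(beta), ")")
  M <- state$pool$samples[[aid]]
  v <- if (fl > 0) rowSums(M[, L[seq_len(fl)], drop = FALSE]) else numeric(ns)
  if (fr > 0) v <- v + fr * M[, L[fl + 1L]]
  v
}

#' Scenario occupancy of a resource
#'
#' Realises the allocation against the scenario pool: for each activity on
#' the resource, `floor(beta)` full sampled durations plus the fractional
#' part times the ceiling-indexed sample, the sample indices being fixed by
#' the lookup lists.
#'
#' @param allocation Allocation matrix.
#' @param state A synchronised [lookup_state()] object.
#' @param resource Resource identifier.
#' @param scenario Scenario index, or `NULL` (default) for all scenarios.
#' @return Occupancy `U_s^i` (vector over scenarios if `scenario` is NULL).
#' @export
occupancy_scenario <- function(allocation, state, resource, scenario = NULL) {
  v <- numeric(state$pool$n_scenarios)
  for (aid in rownames(allocation)) {
    beta <- allocation[aid, resource]
    if (beta > 0) v <- v + contribution_vector(state, beta, aid, resource)
  }
  if (is.null(scenario)) v else v[scenario]
}

## Full resources x scenarios occupancy matrix.
occupancy_matrix <- function(allocation, state) {
  rids <- colnames(allocation)
  m <- matrix(0, nrow = length(rids), ncol = state$pool$n_scenarios,
              dimnames = list(rids, NULL))
  for (rid in rids) m[rid, ] <- occupancy_scenario(allocation, state, rid)
  m
}

#' Per-resource service-level statistics over scenarios
#'
#' From the scenario occupancies of one resource, computes the violation
#' flags (`e^i = 1` iff `U^i > T + delta`), the probability estimates
#' `Pr(U <= T) = 1 - sum_i e^i / |I|` and its complement, the expected
#' usage, the expected over-usage conditional on violating scenarios (zero
#' when no scenario violates), and the buffering statistics.
#'
#' @param U Numeric vector of scenario occupancies.
#' @param availability Time availability `T_s`.
#' @param service_level Required `SL_s`.
#' @param o_max Per-scenario over-usage cap (`Inf` if unrestricted).
#' @param delta Strict-inequality tolerance; defaults to
#'   `1e-9 * availability`.
#' @return A list of class `shca_space_eval` with components `e`, `pr_le`,
#'   `pr_gt`, `E_U`, `E_O`, `buffer`, `rho_util`, `rho_slack`,
#'   `n_violations`, `o_max_exceeded`.
#' @export
evaluate_space <- function(U, availability, service_level = 0.95,
                           o_max = Inf, delta = NULL) {
  if (is.null(delta)) delta <- 1e-9 * availability
  e <- as.integer(U > availability + delta)
  k <- sum(e)
  n <- length(U)
  pr_gt <- k / n
  pr_le <- 1 - pr_gt
  O <- pmax(U - availability, 0)
  E_U <- mean(U)
  E_O <- if (k >= 1) sum(O) / k else 0
  structure(list(
    e = e, pr_le = pr_le, pr_gt = pr_gt, E_U = E_U, E_O = E_O,
    buffer = availability - E_U,
    rho_util = 100 * E_U / availability,
    rho_slack = 100 * (availability - E_U) / availability,
    n_violations = k,
    o_max_exceeded = sum(O > o_max)),
    class = "shca_space_eval")
}

#' Service-level violation score of an allocation
#'
#' The lower-level objective.  In deterministic mode only expected
#' durations are needed; in stochastic mode a synchronised lookup state is
#' required and the probability estimates come from the scenario pool.
#' Scenarios whose over-usage exceeds a space's `o_max` cap are treated as
#' hard violations and add their frequency to the score.  Optional global
#' `limits` (`eu_max`, `eo_max`, `ratio_max`) add further
#' `max(., 0)` penalty terms on `E[U]`, `E[O]` and `E[O] <= ratio * E[U]`.
#'
#' @param allocation Allocation matrix.
#' @param instance The instance.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param state Lookup state (stochastic mode only).
#' @param limits Optional list of managerial limits (see Details).
#' @return An object of class `shca_slv`: `total`, `mode`, per-resource
#'   `contribution`, and (stochastic mode) the per-resource evaluations.
#' @export
slv <- function(allocation, instance,
                mode = c("deterministic", "stochastic"),
                state = NULL, limits = NULL) {
  mode <- match.arg(mode)
  view <- resource_view(instance)
  if (mode == "deterministic") {
    EU <- occupancy_det(allocation, instance)
    contrib <- pmax(EU - view$availability, 0)
    evals <- NULL
    EO <- NULL
  } else {
    if (is.null(state)) stop("stochastic SLV needs a lookup state")
    Umat <- occupancy_matrix(allocation, state)
    evals <- lapply(view$ids, function(rid)
      evaluate_space(Umat[rid, ], view$availability[[rid]],
                     view$service_level[[rid]], view$o_max[[rid]]))
    names(evals) <- view$ids
    pr_le <- vapply(evals, `[[`, numeric(1), "pr_le")
    contrib <- pmax(view$service_level - pr_le, 0)
    hard <- vapply(evals, `[[`, numeric(1), "o_max_exceeded") /
      state$pool$n_scenarios
    contrib <- contrib + hard
    EU <- vapply(evals, `[[`, numeric(1), "E_U")
    EO <- vapply(evals, `[[`, numeric(1), "E_O")
  }
  if (!is.null(limits)) {
    if (!is.null(limits$eu_max))
      contrib <- contrib + pmax(EU - limits$eu_max, 0)
    if (!is.null(limits$eo_max) && !is.null(EO))
      contrib <- contrib + pmax(EO - limits$eo_max, 0)
    if (!is.null(limits$ratio_max) && !is.null(EO))
      contrib <- contrib + pmax(EO - limits$ratio_max * EU, 0)
  }
  structure(list(total = sum(contrib), mode = mode, contribution = contrib,
                 evaluations = evals),
            class = "shca_slv")
}

#' @export
print.shca_slv <- function(x, ...) {
  cat("<shca_slv> mode =", x$mode, " SLV =", format(x$total), "\n")
  nz <- x$contribution[x$contribution > 0]
  if (length(nz)) {
    cat("  violating resources:\n")
    for (r in names(nz)) cat("   ", r, ":", format(nz[[r]]), "\n")
  }
  invisible(x)
}

#' Buffering and utilization of a resource
#'
#' `B_s = T_s - E[U_s]`, with the percentage utilisation
#' `100 E[U_s] / T_s` and slackness `100 B_s / T_s`.  With a lookup state,
#' `E[U_s]` is the scenario average; otherwise the deterministic expected
#' occupancy is used.
#'
#' @param allocation Allocation matrix.
#' @param instance The instance.
#' @param resource Resource identifier.
#' @param state Optional lookup state for the stochastic estimate.
#' @return Named numeric vector `c(buffer, rho_util, rho_slack)`.
#' @export
buffering <- function(allocation, instance, resource, state = NULL) {
  view <- resource_view(instance)
  EU <- if (is.null(state)) occupancy_det(allocation, instance, resource)
  else mean(occupancy_scenario(allocation, state, resource))
  Tr <- view$availability[[resource]]
  c(buffer = Tr - EU, rho_util = 100 * EU / Tr,
    rho_slack = 100 * (Tr - EU) / Tr)
}

#' Per-resource evaluation report
#'
#' One row per resource: availability, expected usage and over-usage,
#' service-level estimates and buffering statistics.  Suitable for
#' `write.csv()` or JSON export.
#'
#' @param allocation Allocation matrix.
#' @param instance The instance.
#' @param state Optional lookup state; without one the report is
#'   deterministic (probabilities are 0/1 indicators of `E[U] <= T`).
#' @return A data frame.
#' @export
space_report <- function(allocation, instance, state = NULL) {
  view <- resource_view(instance)
  if (is.null(state)) {
    EU <- occupancy_det(allocation, instance)
    data.frame(resource = view$ids,
               availability = unname(view$availability),
               service_level = unname(view$service_level),
               E_U = unname(EU),
               E_O = pmax(unname(EU - view$availability), 0),
               pr_le = as.numeric(EU <= view$availability +
                                    1e-9 * view$availability),
               buffer = unname(view$availability - EU),
               rho_util = unname(100 * EU / view$availability),
               rho_slack = unname(100 * (view$availability - EU) /
                                    view$availability),
               stringsAsFactors = FALSE)
  } else {
    ev <- slv(allocation, instance, "stochastic", state)$evaluations
    data.frame(resource = view$ids,
               availability = unname(view$availability),
               service_level = unname(view$service_level),
               E_U = vapply(ev, `[[`, numeric(1), "E_U"),
               E_O = vapply(ev, `[[`, numeric(1), "E_O"),
               pr_le = vapply(ev, `[[`, numeric(1), "pr_le"),
               buffer = vapply(ev, `[[`, numeric(1), "buffer"),
               rho_util = vapply(ev, `[[`, numeric(1), "rho_util"),
               rho_slack = vapply(ev, `[[`, numeric(1), "rho_slack"),
               stringsAsFactors = FALSE)
  }
}
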