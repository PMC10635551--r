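## The outer capacity search.  The bilevel decomposition maximises the
## caseload N subject to the lower-level allocation problem admitting a
## zero-SLV solution; since SLV = 0 holds for all N below the capacity and
## SLV > 0 above it, the frontier is located by bisection over
## feasibility.  The weighted upper-level objective (w1 N - w2 SLV, with
## w2 of the order of the caseload bound) is realised lexicographically:
## a probe counts as an improvement only when its SLV is exactly zero.

#' Bisection over caseload feasibility
#'
#' Each step probes `N' = N_left + scale * (N_right - N_left)`; if the
#' lower-level search certifies `SLV(N') = 0` the left bound moves up,
#' otherwise the right bound moves down, until the bracket is narrower
#' than `tol`.  If every probe up to the initial right bound is feasible
#' and the bound is below `N_hat`, the bracket is expanded (doubling,
#' capped at `N_hat`) with a warning.  A failed lower-level search is
#' treated as infeasible, which makes the returned capacity a one-sided
#' (conservative) estimate.
#'
#' @param feasible_fn Function of `N` returning a list with at least
#'   `slv` (number) and `allocation`; `slv == 0` certifies feasibility.
#' @param bracket Numeric `c(N_left, N_right)` with feasible left end
#'   (`N_left = 0` always qualifies: the empty caseload is feasible).
#' @param N_hat Upper bound on the caseload (bracket expansion cap).
#' @param scale Probe position in the bracket, in (0, 1).
#' @param tol Convergence tolerance on N (patients).
#' @return A list with `N_opt`, `trace` (a data frame), and `best` (the
#'   result of `feasible_fn` at the largest feasible probe, or `NULL` when
#'   no probe was feasible).
#' @export
binary_search_capacity <- function(feasible_fn, bracket, N_hat = bracket[2L],
                                   scale = 0.5, tol = 0.5) {
  stopifnot(scale > 0, scale < 1, tol > 0,
            length(bracket) == 2L, bracket[1L] <= bracket[2L])
  N_left <- bracket[1L]
  N_right <- bracket[2L]
  trace <- list()
  best <- NULL
  step <- 0L
  right_moved <- FALSE
  repeat {
    while (N_right - N_left > tol) {
      step <- step + 1L
      N_probe <- N_left + scale * (N_right - N_left)
      t0 <- proc.time()[["elapsed"]]
      res <- feasible_fn(N_probe)
      feasible <- res$slv <= 0
      trace[[step]] <- data.frame(
        step = step, N = N_probe, slv = res$slv, feasible = feasible,
        width = N_right - N_left,
        seconds = proc.time()[["elapsed"]] - t0)
      if (feasible) {
        N_left <- N_probe
        best <- res
      } else {
        N_right <- N_probe
        right_moved <- TRUE
      }
    }
    ## bracket top never disproven and below the caseload bound: expand
    if (!right_moved && N_right < N_hat - tol) {
      warning("caseload bracket [", format(bracket[1L]), ", ",
              format(bracket[2L]), "] feasible throughout; expanding")
      N_right <- min(2 * N_right, N_hat)
    } else break
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), N = numeric(), slv = numeric(),
               feasible = logical(), width = numeric(), seconds = numeric())
  list(N_opt = N_left, trace = trace, best = best)
}

#' Assess hospital capacity
#'
#' The main fitting function.  Estimates the maximum caseload `N` treatable
#' over the planning horizon subject to each resource's service-level
#' constraint, and returns the certifying allocation.  Deterministic mode
#' uses expected durations (`E[U_s] <= T_s`); stochastic mode estimates
#' `Pr(U_s <= T_s)` by sample average approximation over a pre-generated
#' scenario pool and brackets its search by the deterministic capacity
#' (expanding with a warning in the rare case the stochastic capacity
#' exceeds it).
#'
#' @param instance An [shca_instance()] object (or a path to a
#'   configuration file readable by [read_instance()]).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param n_scenarios Scenario-pool size `|I|` (stochastic mode).
#' @param seed Master seed governing the scenario pool and the search's
#'   random stream.
#' @param scale Bisection probe position in (0, 1); around 0.5 needs the
#'   fewest steps, smaller values spend less time on infeasible probes.
#' @param tol Convergence tolerance on N (patients).
#' @param control An [mh_control()] object for the lower-level search.
#' @param pool Optional pre-built [scenario_pool()] (overrides
#'   `n_scenarios`).
#' @param N_det Optional known deterministic capacity (skips the
#'   deterministic pre-solve in stochastic mode).
#' @param limits Optional managerial limits passed to [slv()].
#' @return An object of class `shca_capacity` with the estimate `N_opt`,
#'   the certifying `allocation`, the per-resource `report`, the search
#'   `trace`, and the implied `caseload`.
#' @examples
#' inst <- fixture("toy_4_3_path")
#' fit <- assess_capacity(inst, "deterministic")
#' fit$N_opt  # 960 / 105
#' @export
assess_capacity <- function(instance,
                            mode = c("deterministic", "stochastic"),
                            n_scenarios = 500, seed = 1, scale = 0.5,
                            tol = 0.5, control = mh_control(),
                            pool = NULL, N_det = NULL, limits = NULL) {
  if (is.character(instance)) instance <- read_instance(instance)
  stopifnot(inherits(instance, "shca_instance"))
  mode <- match.arg(mode)
  cl <- match.call()
  set.seed(as.integer(seed))
  bounds <- upper_bound_N(instance)
  t0 <- proc.time()[["elapsed"]]

  feasible_det <- function(N) {
    cload <- caseload_from_N(N, instance$mix, instance$catalog)
    alloc <- greedy_allocate(cload, instance)
    s <- slv(alloc, instance, "deterministic", limits = limits)$total
    if (s > 0) {
      mh <- run_metaheuristic(alloc, instance, "deterministic",
                              control = control)
      alloc <- mh$allocation
      s <- mh$slv
    }
    list(slv = s, allocation = alloc, caseload = cload, state = NULL)
  }

  if (mode == "deterministic") {
    sr <- binary_search_capacity(feasible_det, c(0, bounds$N_hat),
                                 N_hat = bounds$N_hat, scale = scale,
                                 tol = tol)
    pool_used <- NULL
  } else {
    if (is.null(N_det))
      N_det <- binary_search_capacity(feasible_det, c(0, bounds$N_hat),
                                      N_hat = bounds$N_hat, scale = scale,
                                      tol = tol)$N_opt
    if (is.null(pool))
      pool <- scenario_pool(instance, n_scenarios, seed, bounds = bounds)
    pool_used <- pool
    feasible_stoch <- function(N) {
      cload <- caseload_from_N(N, instance$mix, instance$catalog)
      alloc <- greedy_allocate(cload, instance)
      state <- lookup_state(pool_used, alloc, instance)
      s <- slv(alloc, instance, "stochastic", state, limits = limits)$total
      if (s > 0) {
        mh <- run_metaheuristic(alloc, instance, "stochastic", state,
                                control = control)
        list(slv = mh$slv, allocation = mh$allocation, caseload = cload,
             state = mh$state)
      } else {
        list(slv = s, allocation = alloc, caseload = cload, state = state)
      }
    }
    ## expansion cap: with low service levels the SAA capacity can exceed
    ## the mean-based bound, so allow growth up to a realisation-aware
    ## bound using the smallest sampled duration per activity
    m <- activity_multipliers(instance)
    tmin <- vapply(names(m), function(aid)
      min(pool_used$samples[[aid]]), numeric(1))
    denom <- sum(m * tmin)
    view <- resource_view(instance)
    N_hat_stoch <- if (denom > 0)
      min(sum(view$availability) / denom, 100 * max(bounds$N_hat, 1))
    else bounds$N_hat
    sr <- binary_search_capacity(feasible_stoch,
                                 c(0, max(N_det, tol)),
                                 N_hat = max(bounds$N_hat, N_hat_stoch),
                                 scale = scale, tol = tol)
  }

  best <- sr$best
  if (is.null(best)) {
    cload <- caseload_from_N(0, instance$mix, instance$catalog)
    best <- list(slv = 0, allocation = new_allocation(instance),
                 caseload = cload, state = NULL)
  }
  report <- space_report(best$allocation, instance, best$state)
  structure(list(
    N_opt = sr$N_opt, mode = mode, instance = instance,
    allocation = best$allocation, caseload = best$caseload,
    state = best$state, pool = pool_used, report = report,
    trace = sr$trace, bounds = bounds,
    N_det = if (mode == "stochastic") N_det else sr$N_opt,
    seed = seed, scale = scale, tol = tol, control = control,
    seconds = proc.time()[["elapsed"]] - t0, call = cl),
    class = "shca_capacity")
}

#' @export
print.shca_capacity <- function(x, ...) {
  cat("Hospital capacity assessment (", x$mode, ")\n", sep = "")
  cat("  capacity N_opt: ", format(x$N_opt, digits = 6),
      " patients (tolerance ", x$tol, ")\n", sep = "")
  if (x$mode == "stochastic")
    cat("  deterministic capacity:", format(x$N_det, digits = 6),
        " scenarios:", x$pool$n_scenarios, "\n")
  cat("  search steps:", nrow(x$trace),
      " elapsed:", round(x$seconds, 2), "s\n")
  invisible(x)
}

#' @export
summary.shca_capacity <- function(object, ...) {
  structure(list(fit = object,
                 caseload = data.frame(
                   type = names(object$caseload$n1),
                   n = unname(object$caseload$n1)),
                 report = object$report),
            class = "summary.shca_capacity")
}

#' @export
print.summary.shca_capacity <- function(x, ...) {
  print(x$fit)
  cat("\nCaseload by patient type:\n")
  print(x$caseload, row.names = FALSE, digits = 6)
  cat("\nPer-resource report:\n")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.shca_capacity <- function(object, ...) {
  c(N = object$N_opt)
}

#' @export
plot.shca_capacity <- function(x, ...) {
  tr <- x$trace
  if (!nrow(tr)) {
    plot(0, 0, type = "n", xlab = "step", ylab = "probe N",
         main = "capacity search (no steps)")
    return(invisible(x))
  }
  plot(tr$step, tr$N, type = "b", pch = ifelse(tr$feasible, 19, 4),
       xlab = "search step", ylab = "probe caseload N",
       main = sprintf("capacity search (%s mode)", x$mode), ...)
  abline(h = x$N_opt, lty = 2)
  legend("bottomright", pch = c(19, 4), bty = "n",
         legend = c("feasible (SLV = 0)", "infeasible"))
  invisible(x)
}

#' Override the service level of every treatment space
#'
#' Convenience for risk sweeps: returns a copy of the instance whose
#' spaces all carry the given service level.
#'
#' @param instance An [shca_instance()] object.
#' @param service_level New `SL` in `[0, 1]` applied uniformly.
#' @return The modified instance.
#' @export
set_service_level <- function(instance, service_level) {
  stopifnot(inherits(instance, "shca_instance"),
            service_level >= 0, service_level <= 1)
  for (wi in seq_along(instance$hospital$areas)) {
    for (si in seq_along(instance$hospital$areas[[wi]]$spaces)) {
      instance$hospital$areas[[wi]]$spaces[[si]]$service_level <- service_level
      instance$hospital$areas[[wi]]$spaces[[si]]$risk_level <- 1 - service_level
    }
  }
  instance
}

#' Capacity sweep over risk levels, scenario counts and replications
#'
#' Runs a stochastic capacity assessment for every combination of risk
#' level (`RL = 1 - SL`, applied uniformly to every space), scenario count
#' and replication, each replication with its own seed derived from
#' `seed`.  The deterministic capacity is computed once and re-used as the
#' search bracket.
#'
#' @param instance An [shca_instance()] object.
#' @param risk_levels Numeric vector of risk levels in `[0, 1]`.
#' @param scenario_counts Integer vector of scenario-pool sizes.
#' @param replications Replications per cell.
#' @param seed Master seed.
#' @param ... Further arguments passed to [assess_capacity()] (e.g.
#'   `control`, `scale`, `tol`).
#' @return A data frame of class `shca_sweep` with one row per run:
#'   `risk_level`, `scenarios`, `replication`, `seed`, `N_det`, `N`.
#' @seealso [summary.shca_sweep()], [caseload_table()]
#' @export
risk_sweep <- function(instance, risk_levels, scenario_counts = 500,
                       replications = 1, seed = 1, ...) {
  stopifnot(all(risk_levels >= 0), all(risk_levels <= 1))
  rows <- list()
  run <- 0L
  for (rl in risk_levels) {
    inst_rl <- set_service_level(instance, 1 - rl)
    N_det <- assess_capacity(inst_rl, "deterministic", seed = seed, ...)$N_opt
    for (ns in scenario_counts) {
      for (rep in seq_len(replications)) {
        run <- run + 1L
        seed_r <- substream_seed(seed, run, 1L)
        fit <- assess_capacity(inst_rl, "stochastic", n_scenarios = ns,
                               seed = seed_r, N_det = N_det, ...)
        rows[[run]] <- data.frame(
          risk_level = rl, scenarios = ns, replication = rep,
          seed = seed_r, N_det = N_det, N = fit$N_opt)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("shca_sweep", "data.frame"))
}

#' Summarise a capacity sweep
#'
#' Min/mean/max capacity per (risk level, scenario count) cell, plus the
#' overall capacity range `max - min` across risk levels.
#'
#' @param object An [risk_sweep()] result.
#' @param ... Ignored.
#' @return A list with `cells` (a data frame) and `capacity_range`.
#' @export
summary.shca_sweep <- function(object, ...) {
  df <- as.data.frame(object)
  cells <- aggregate(N ~ risk_level + scenarios, data = df, FUN = function(v)
    c(min = min(v), mean = mean(v), max = max(v)))
  cells <- cbind(cells[c("risk_level", "scenarios")],
                 as.data.frame(cells$N))
  totals <- aggregate(N ~ risk_level, data = df, FUN = mean)
  structure(list(cells = cells,
                 capacity_range = max(totals$N) - min(totals$N)),
            class = "summary.shca_sweep")
}

#' @export
print.summary.shca_sweep <- function(x, ...) {
  cat("Capacity sweep\n")
  print(x$cells, row.names = FALSE, digits = 6)
  cat("capacity range across risk levels (mean):",
      format(x$capacity_range, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.shca_sweep <- function(x, ...) {
  df <- as.data.frame(x)
  ag <- aggregate(N ~ risk_level + scenarios, data = df, FUN = mean)
  plot(range(ag$risk_level), range(ag$N), type = "n",
       xlab = "risk level (1 - SL)", ylab = "capacity N",
       main = "capacity vs risk", ...)
  for (ns in unique(ag$scenarios)) {
    sub <- ag[ag$scenarios == ns, ]
    sub <- sub[order(sub$risk_level), ]
    lines(sub$risk_level, sub$N, type = "b", pch = 19)
  }
  invisible(x)
}

#' Per-type caseload table for a set of capacity totals
#'
#' Applies the case-mix arithmetic `n1_g = mu1_g N` to each total, giving
#' the familiar rows-by-risk-column caseload table.
#'
#' @param totals Named numeric vector of capacities (names become columns).
#' @param mix A [case_mix()] object.
#' @param drop_zero Drop patient types with zero mix share (default TRUE).
#' @return A data frame with one row per patient type plus a `Total` row.
#' @export
caseload_table <- function(totals, mix, drop_zero = TRUE) {
  stopifnot(is.numeric(totals), !is.null(names(totals)),
            inherits(mix, "shca_mix"))
  mu <- mix$mu1
  if (drop_zero) mu <- mu[mu > 0]
  tab <- outer(mu, totals)
  out <- data.frame(type = names(mu), tab, check.names = FALSE,
                    row.names = NULL)
  total_row <- data.frame(type = "Total", t(colSums(tab)),
                          check.names = FALSE, row.names = NULL)
  names(total_row) <- names(out)
  rbind(out, total_row)
}
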