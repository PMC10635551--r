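## Allocation construction and improvement.
##
## The greedy constructor walks the activities in order and fills candidate
## resources from largest to smallest free time, forcing any remainder onto
## the least-loaded candidate when none has free time.  The metaheuristic
## (simulated annealing or threshold accepting) then repairs positive-SLV
## allocations by shifting load off the most over-committed resource, with
## incremental re-evaluation of only the two resources a move touches.

#' Greedy allocation of a caseload to resources
#'
#' Activities are handled in `ordering` (catalogue/pathway order by
#' default).  For each activity, candidate resources are ranked from
#' largest to smallest free time (ties broken by instance resource order,
#' i.e. lowest identifier first); the top candidate is filled with as many
#' occurrences as its free time admits (fractional fills allowed), removed,
#' and the process repeats.  When no remaining candidate has free time the
#' whole remainder is forced onto the least-loaded candidate, which is what
#' produces positive-SLV allocations for super-capacity caseloads.
#'
#' @param caseload A [caseload_from_N()] object.
#' @param instance The instance.
#' @param ordering Optional character vector permuting the activity ids.
#' @return An allocation matrix of class `shca_allocation` satisfying
#'   `rowSums(allocation) = n3`.
#' @export
greedy_allocate <- function(caseload, instance, ordering = NULL) {
  stopifnot(inherits(caseload, "shca_caseload"),
            inherits(instance, "shca_instance"))
  view <- resource_view(instance)
  aids <- names(instance$catalog$activities)
  if (is.null(ordering)) ordering <- aids
  if (!setequal(ordering, aids) || length(ordering) != length(aids))
    stop("ordering must be a permutation of the activity identifiers")
  alloc <- new_allocation(instance, view)
  emean <- activity_means(instance)
  free <- view$availability
  tol <- 1e-12
  for (aid in ordering) {
    rem <- caseload$n3[[aid]]
    if (rem <= tol) next
    cand_all <- view$candidates[[aid]]
    if (length(cand_all) == 0L)
      stop("activity '", aid, "' has no candidate resource; instance infeasible")
    E <- emean[[aid]]
    cand <- cand_all
    while (rem > tol && length(cand)) {
      ord <- order(-free[cand], match(cand, view$ids))
      top <- cand[ord[1L]]
      if (free[[top]] <= tol) {
        ## no free time anywhere: force remainder onto least-loaded candidate
        least <- cand_all[order(-free[cand_all], match(cand_all, view$ids))][1L]
        alloc[aid, least] <- alloc[aid, least] + rem
        free[[least]] <- free[[least]] - rem * E
        rem <- 0
        break
      }
      amt <- if (E > 0) min(rem, free[[top]] / E) else rem
      alloc[aid, top] <- alloc[aid, top] + amt
      free[[top]] <- free[[top]] - amt * E
      rem <- rem - amt
      cand <- setdiff(cand, top)
    }
    if (rem > tol) {
      least <- cand_all[order(-free[cand_all], match(cand_all, view$ids))][1L]
      alloc[aid, least] <- alloc[aid, least] + rem
      free[[least]] <- free[[least]] - rem * E
    }
  }
  attr(alloc, "caseload") <- caseload
  alloc
}

#' Metaheuristic control parameters
#'
#' Defaults follow the usual schedule for this search: the initial control
#' is `lambda` times the starting SLV, the final control `t_f`, and the
#' decay per iterate is `exp(log(t_f / t_i) / n_controls)` so the schedule
#' spans `n_controls` control updates with `steps` perturbations each.
#'
#' @param alg `"ta"` (threshold accepting) or `"sa"` (simulated annealing).
#' @param lambda Multiplier setting the initial control `t_i = lambda * SLV0`.
#' @param t_f Final control value.
#' @param steps Perturbations per iterate (between control updates).
#' @param n_controls Number of control updates the decay is calibrated to.
#' @param seed Optional integer seed for the search's random stream.
#' @return A list of class `shca_mh_control`.
#' @export
mh_control <- function(alg = c("ta", "sa"), lambda = 1e6, t_f = 0.001,
                       steps = 300, n_controls = 50, seed = NULL) {
  alg <- match.arg(alg)
  stopifnot(lambda > 0, t_f > 0, steps >= 1, n_controls >= 1)
  structure(list(alg = alg, lambda = lambda, t_f = t_f,
                 steps = as.integer(steps),
                 n_controls = as.integer(n_controls), seed = seed),
            class = "shca_mh_control")
}

#' Move acceptance rule
#'
#' Improving moves (`delta < 0`) are always accepted.  Threshold accepting
#' takes a worse move iff its deterioration is below the current control;
#' simulated annealing takes it with probability `exp(-delta / control)`.
#'
#' @param delta Change in SLV caused by the move.
#' @param control Current threshold/temperature (> 0).
#' @param alg `"ta"` or `"sa"`.
#' @return Logical.
#' @export
accept_move <- function(delta, control, alg = c("ta", "sa")) {
  alg <- match.arg(alg)
  stopifnot(control > 0)
  if (delta < 0) return(TRUE)
  if (alg == "ta") delta < control else runif(1) < exp(-delta / control)
}

## ---- incremental evaluation environment ---------------------------------

mh_env_init <- function(allocation, instance, mode, state = NULL) {
  env <- new.env(parent = emptyenv())
  env$view <- resource_view(instance)
  env$instance <- instance
  env$mode <- mode
  env$alloc <- allocation
  env$emean <- activity_means(instance)
  env$EU <- occupancy_det(allocation, instance)
  if (mode == "stochastic") {
    env$state <- state
    env$cache <- setNames(lapply(rownames(allocation), function(a) list()),
                          rownames(allocation))
    env$U <- matrix(0, nrow = length(env$view$ids),
                    ncol = state$pool$n_scenarios,
                    dimnames = list(env$view$ids, NULL))
    for (aid in rownames(allocation)) for (rid in env$view$ids) {
      b <- allocation[aid, rid]
      if (b > 0) {
        v <- contribution_vector(env$state, b, aid, rid)
        env$cache[[aid]][[rid]] <- v
        env$U[rid, ] <- env$U[rid, ] + v
      }
    }
  }
  mh_env_refresh_stats(env, env$view$ids)
  env
}

mh_env_refresh_stats <- function(env, rids) {
  view <- env$view
  if (is.null(env$stats)) {
    env$stats <- list(
      metric = setNames(numeric(length(view$ids)), view$ids),
      contrib = setNames(numeric(length(view$ids)), view$ids),
      maxO = setNames(numeric(length(view$ids)), view$ids))
  }
  for (rid in rids) {
    Tr <- view$availability[[rid]]
    if (env$mode == "deterministic") {
      over <- env$EU[[rid]] - Tr
      env$stats$metric[[rid]] <- over
      env$stats$contrib[[rid]] <- max(over, 0)
      env$stats$maxO[[rid]] <- over
    } else {
      U <- env$U[rid, ]
      k <- sum(U > Tr + 1e-9 * Tr)
      pr_gt <- k / length(U)
      hard <- if (is.finite(view$o_max[[rid]]))
        sum(pmax(U - Tr, 0) > view$o_max[[rid]]) / length(U) else 0
      env$stats$metric[[rid]] <- pr_gt
      env$stats$contrib[[rid]] <-
        max(view$service_level[[rid]] - (1 - pr_gt), 0) + hard
      env$stats$maxO[[rid]] <- max(U) - Tr
    }
  }
  invisible(env)
}

mh_env_slv <- function(env) sum(env$stats$contrib)

mh_env_apply <- function(env, move) {
  aid <- move$activity; from <- move$from; to <- move$to; amt <- move$amount
  env$alloc[aid, from] <- max(env$alloc[aid, from] - amt, 0)
  env$alloc[aid, to] <- env$alloc[aid, to] + amt
  dE <- amt * env$emean[[aid]]
  env$EU[[from]] <- env$EU[[from]] - dE
  env$EU[[to]] <- env$EU[[to]] + dE
  if (env$mode == "stochastic") {
    env$state <- sync_lookups(env$state, env$alloc,
                              pairs = list(c(aid, from), c(aid, to)))
    for (rid in c(from, to)) {
      old <- env$cache[[aid]][[rid]]
      if (is.null(old)) old <- numeric(ncol(env$U))
      b <- env$alloc[aid, rid]
      new <- if (b > 0) contribution_vector(env$state, b, aid, rid)
      else numeric(ncol(env$U))
      env$U[rid, ] <- env$U[rid, ] - old + new
      env$cache[[aid]][[rid]] <- new
    }
  }
  mh_env_refresh_stats(env, c(from, to))
  invisible(env)
}

## Propose a load-shifting move given per-resource metrics.
propose_move <- function(alloc, view, metric, maxO, emean) {
  ord <- names(sort(metric, decreasing = TRUE))
  for (rid in ord) {
    if (metric[[rid]] <= 0 && rid != ord[1L]) break
    on_r <- rownames(alloc)[alloc[, rid] > 0]
    movable <- on_r[vapply(on_r, function(a)
      length(setdiff(view$candidates[[a]], rid)) > 0, logical(1))]
    if (length(movable) == 0L) next
    aid <- if (length(movable) == 1L) movable else sample(movable, 1L)
    beta <- alloc[aid, rid]
    over <- maxO[[rid]]
    amt <- if (over > 0 && emean[[aid]] > 0)
      min(over / emean[[aid]], beta) else runif(1) * beta
    if (amt <= 0) next
    dest_cand <- setdiff(view$candidates[[aid]], rid)
    dm <- metric[dest_cand]
    best <- dest_cand[dm == min(dm)]
    dest <- if (length(best) == 1L) best else sample(best, 1L)
    return(list(activity = aid, from = rid, to = dest, amount = amt))
  }
  NULL
}

#' Propose a single re-allocation move
#'
#' Selects the resource with the highest probability of over-utilisation
#' (deterministic mode: the largest over-usage), picks a random assigned
#' activity there that has an alternative candidate, and proposes shifting
#' `min(O_obs / E[t_a], beta)` of it to the activity's least-risky
#' candidate (random tie-break), where `O_obs` is the largest observed
#' over-utilisation; when nothing is observed over, a uniform fraction of
#' `beta` is moved instead.  Totals are conserved and exactly two
#' resources are touched.
#'
#' @param allocation Allocation matrix.
#' @param instance The instance.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param state Lookup state (stochastic mode).
#' @return A list `(activity, from, to, amount)`, or `NULL` when no valid
#'   move exists (e.g. a single-resource instance).
#' @export
perturb_allocation <- function(allocation, instance,
                               mode = c("deterministic", "stochastic"),
                               state = NULL) {
  mode <- match.arg(mode)
  view <- resource_view(instance)
  emean <- activity_means(instance)
  if (mode == "deterministic") {
    EU <- occupancy_det(allocation, instance)
    metric <- EU - view$availability
    maxO <- metric
  } else {
    if (is.null(state)) stop("stochastic perturbation needs a lookup state")
    Umat <- occupancy_matrix(allocation, state)
    Tr <- view$availability
    metric <- vapply(view$ids, function(r)
      mean(Umat[r, ] > Tr[[r]] + 1e-9 * Tr[[r]]), numeric(1))
    maxO <- vapply(view$ids, function(r) max(Umat[r, ]) - Tr[[r]], numeric(1))
    names(metric) <- view$ids
    names(maxO) <- view$ids
  }
  propose_move(allocation, view, metric, maxO, emean)
}

#' Improve an allocation with simulated annealing / threshold accepting
#'
#' Starting from an allocation, repeatedly proposes load-shifting moves and
#' accepts them per [accept_move()], decaying the control after every
#' `steps` perturbations, until the SLV reaches zero or the control falls
#' below its final value.  The best allocation seen is returned (with, in
#' stochastic mode, a snapshot of the lookup lists under which its score
#' was observed, so the score can be reproduced exactly).  A positive SLV
#' at exit is a legitimate answer: it reports that no feasible allocation
#' was found.
#'
#' @param allocation Starting allocation (e.g. from [greedy_allocate()]).
#' @param instance The instance.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param state Lookup state synchronised to `allocation` (stochastic mode).
#' @param control An [mh_control()] object.
#' @return A list with `allocation`, `slv`, `state` (stochastic snapshot or
#'   `NULL`), `perturbations`, `accepted`, `iterates`.
#' @export
run_metaheuristic <- function(allocation, instance,
                              mode = c("deterministic", "stochastic"),
                              state = NULL, control = mh_control()) {
  mode <- match.arg(mode)
  stopifnot(inherits(control, "shca_mh_control"))
  if (!is.null(control$seed)) set.seed(control$seed)
  env <- mh_env_init(allocation, instance, mode, state)
  cur <- mh_env_slv(env)
  best <- list(allocation = env$alloc, slv = cur,
               state = if (mode == "stochastic") env$state else NULL)
  if (cur <= 0)
    return(c(best, list(perturbations = 0L, accepted = 0L, iterates = 0L)))
  t <- control$lambda * cur
  t_r <- exp(log(control$t_f / t) / control$n_controls)
  n_pert <- 0L
  n_acc <- 0L
  iterates <- 0L
  repeat {
    iterates <- iterates + 1L
    for (k in seq_len(control$steps)) {
      move <- propose_move(env$alloc, env$view, env$stats$metric,
                           env$stats$maxO, env$emean)
      if (is.null(move)) break
      n_pert <- n_pert + 1L
      mh_env_apply(env, move)
      new <- mh_env_slv(env)
      if (accept_move(new - cur, t, control$alg)) {
        n_acc <- n_acc + 1L
        cur <- new
        if (cur < best$slv) {
          best$allocation <- env$alloc
          best$slv <- cur
          if (mode == "stochastic") best$state <- env$state
        }
        if (cur <= 0) break
      } else {
        ## undo by applying the reverse shift
        mh_env_apply(env, list(activity = move$activity, from = move$to,
                               to = move$from, amount = move$amount))
        cur <- mh_env_slv(env)
      }
    }
    if (best$slv <= 0 || is.null(move)) break
    t <- t * t_r
    if (t < control$t_f) break
  }
  c(best, list(perturbations = n_pert, accepted = n_acc, iterates = iterates))
}
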