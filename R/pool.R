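## Scenario pool for sample average approximation, and the per-(activity,
## resource) lookup lists that tie fractional allocations to fixed sampled
## durations so that an allocation always evaluates to the same occupancy,
## no matter what perturbations happened in between.
##
## Samples are shared across alternative resources (t_{a,s}^{i,n} =
## t_a^{i,n}), the economical convention for identical alternative spaces.
## Each pool column is generated from its own sub-stream seeded
## deterministically from (master seed, activity, column), so the table is
## bit-reproducible and can be grown lazily without disturbing existing
## values.

## floor/ceiling with a tolerance so that arithmetic like 1.9 + 0.3
## lands on the intended integer lattice.
beta_floor <- function(b) floor(b + 1e-9)
beta_ceil <- function(b) ceiling(b - 1e-9)

substream_seed <- function(master, activity_index, column) {
  ## doubles are exact here: master < 2^31, products < 2^53
  s <- (master %% 2147483647) * 48271
  s <- (s + activity_index * 69621 + column * 16807) %% 2147483629
  as.integer(s + 1)
}

#' Generate the scenario pool
#'
#' Pre-samples `n_scenarios` complete realisations of every activity's
#' duration.  The per-activity pool width is the ceiling of the activity's
#' caseload bound plus slack (default 10%, at least one) to absorb
#' re-allocations.  Regenerating with the same seed reproduces the table
#' bit-exactly.
#'
#' @param instance An [shca_instance()] object.
#' @param n_scenarios Number of scenarios `|I|` (>= 1).
#' @param seed Master seed (integer).
#' @param bounds Optional [upper_bound_N()] result (computed if missing).
#' @param slack Fractional slack on the per-activity pool width.
#' @param max_values Capacity guard: total stored values may not exceed
#'   this (default 5e7). Exceeding it raises an error suggesting fewer
#'   scenarios or a shorter horizon.
#' @return An object of class `shca_pool`.
#' @export
scenario_pool <- function(instance, n_scenarios, seed, bounds = NULL,
                          slack = 0.10, max_values = 5e7) {
  stopifnot(inherits(instance, "shca_instance"), n_scenarios >= 1)
  n_scenarios <- as.integer(n_scenarios)
  seed <- as.integer(seed)
  if (is.null(bounds)) bounds <- upper_bound_N(instance)
  acts <- instance$catalog$activities
  n_hat <- vapply(names(acts), function(aid) {
    base <- ceiling(bounds$n3_hat[[aid]])
    max(base + 1L, ceiling(base * (1 + slack)), 2L)
  }, numeric(1))
  total <- n_scenarios * sum(n_hat)
  if (total > max_values)
    stop("scenario pool of ", format(total, big.mark = ","),
         " values exceeds the configured cap (", format(max_values),
         "); use fewer scenarios or a shorter horizon")
  samples <- vector("list", length(acts))
  names(samples) <- names(acts)
  for (ai in seq_along(acts)) {
    aid <- names(acts)[ai]
    samples[[aid]] <- pool_columns(acts[[aid]]$duration, n_scenarios,
                                   seed, ai, seq_len(n_hat[[aid]]))
  }
  structure(list(n_scenarios = n_scenarios, n_hat = n_hat,
                 samples = samples, seed = seed,
                 activity_index = setNames(seq_along(acts), names(acts))),
            class = "shca_pool")
}

pool_columns <- function(dist, n_scenarios, seed, activity_index, columns) {
  m <- matrix(0, nrow = n_scenarios, ncol = length(columns))
  for (k in seq_along(columns)) {
    set.seed(substream_seed(seed, activity_index, columns[k]))
    m[, k] <- dist_sample(dist, n_scenarios)
  }
  m
}

#' @export
print.shca_pool <- function(x, ...) {
  total <- x$n_scenarios * sum(x$n_hat)
  cat("<shca_pool> |I| =", x$n_scenarios, "scenarios,",
      length(x$samples), "activities,",
      format(total, big.mark = ","), "stored values (~",
      format(round(total * 8 / 2^20, 1)), "MiB)\n")
  invisible(x)
}

## Grow activity aid's pool to at least `width` columns, deterministically.
pool_grow <- function(pool, instance, aid, width) {
  cur <- ncol(pool$samples[[aid]])
  if (width <= cur) return(pool)
  ai <- pool$activity_index[[aid]]
  extra <- pool_columns(instance$catalog$activities[[aid]]$duration,
                        pool$n_scenarios, pool$seed, ai, (cur + 1L):width)
  pool$samples[[aid]] <- cbind(pool$samples[[aid]], extra)
  pool$n_hat[[aid]] <- width
  pool
}

#' Initialise lookup lists for an allocation
#'
#' Builds, for every activity/resource pair with a positive allocation, the
#' ordered list of pool indices realising it (`|L_{a,s}| = ceiling(beta)`),
#' and the per-activity set of unused indices.  Indices are taken lowest
#' first, in catalogue and resource order, so the construction is
#' deterministic.
#'
#' @param pool An [scenario_pool()] object.
#' @param allocation An allocation matrix (see [greedy_allocate()]).
#' @param instance The instance the pool was built for (needed to regrow
#'   the pool deterministically if slack runs out).
#' @return An object of class `shca_lookups`.
#' @export
lookup_state <- function(pool, allocation, instance) {
  stopifnot(inherits(pool, "shca_pool"))
  aids <- rownames(allocation)
  state <- structure(list(
    pool = pool, instance = instance,
    lists = setNames(lapply(aids, function(a) list()), aids),
    unused = setNames(lapply(aids, function(a)
      seq_len(ncol(pool$samples[[a]]))), aids)),
    class = "shca_lookups")
  sync_lookups(state, allocation)
}

#' Synchronise lookup lists with an allocation
#'
#' Restores the invariant `|L_{a,s}| = ceiling(beta_{a,s})` for the given
#' pairs (all pairs by default).  Shrinking a list releases its trailing
#' indices back to the unused set; growing appends the lowest unused
#' indices.  Lists not named in `pairs` are untouched, which is what makes
#' evaluation invariant across unrelated perturbations.
#'
#' @param state An [lookup_state()] object.
#' @param allocation The allocation matrix to synchronise with.
#' @param pairs Optional list of `c(activity, resource)` character pairs to
#'   restrict the update to.
#' @return The updated `shca_lookups` object.
#' @export
sync_lookups <- function(state, allocation, pairs = NULL) {
  stopifnot(inherits(state, "shca_lookups"))
  if (is.null(pairs)) {
    pairs <- list()
    for (aid in rownames(allocation)) {
      rids <- union(colnames(allocation)[allocation[aid, ] > 0],
                    names(state$lists[[aid]]))
      for (rid in rids) pairs[[length(pairs) + 1L]] <- c(aid, rid)
    }
  }
  for (pr in pairs) {
    aid <- pr[[1L]]; rid <- pr[[2L]]
    beta <- allocation[aid, rid]
    target <- if (beta > 0) beta_ceil(beta) else 0L
    cur <- state$lists[[aid]][[rid]]
    if (is.null(cur)) cur <- integer(0)
    if (target < length(cur)) {
      released <- cur[(target + 1L):length(cur)]
      cur <- cur[seq_len(target)]
      state$unused[[aid]] <- sort(c(state$unused[[aid]], released))
    } else if (target > length(cur)) {
      need <- target - length(cur)
      if (length(state$unused[[aid]]) < need) {
        grown <- pool_grow(state$pool, state$instance, aid,
                           ncol(state$pool$samples[[aid]]) + max(need, 8L))
        new_idx <- (ncol(state$pool$samples[[aid]]) + 1L):
          ncol(grown$samples[[aid]])
        state$pool <- grown
        state$unused[[aid]] <- sort(c(state$unused[[aid]], new_idx))
      }
      take <- state$unused[[aid]][seq_len(need)]
      state$unused[[aid]] <- state$unused[[aid]][-seq_len(need)]
      cur <- c(cur, take)
    }
    state$lists[[aid]][[rid]] <- cur
  }
  state
}

## Invariant check used by tests and debug runs: every index used at most
## once per activity, used and unused partition the pool columns.
lookup_state_check <- function(state, allocation) {
  for (aid in names(state$lists)) {
    used <- unlist(state$lists[[aid]], use.names = FALSE)
    if (anyDuplicated(used)) return(FALSE)
    all_idx <- seq_len(ncol(state$pool$samples[[aid]]))
    if (!setequal(c(used, state$unused[[aid]]), all_idx)) return(FALSE)
    if (length(intersect(used, state$unused[[aid]])) > 0) return(FALSE)
    for (rid in names(state$lists[[aid]])) {
      beta <- allocation[aid, rid]
      if (length(state$lists[[aid]][[rid]]) !=
          (if (beta > 0) beta_ceil(beta) else 0L)) return(FALSE)
    }
  }
  TRUE
}
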