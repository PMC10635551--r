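## Exact reference models for tiny instances, used to certify the
## heuristic stack: the deterministic capacity LP, and the SAA
## deterministic-equivalent optimum computed by exhaustive enumeration of
## the discrete structure (which scenarios may violate, and the integer
## floors of the allocation) with a linear program in the remaining
## continuous variables.  The enumeration is exact but exponential, hence
## the hard size guards.

lp_var_name <- function(x) gsub("[^A-Za-z0-9]", "_", x)

## Build the deterministic capacity LP in matrix form.
det_lp_model <- function(instance) {
  view <- resource_view(instance)
  m <- activity_multipliers(instance)
  emean <- activity_means(instance)
  pairs <- list()
  for (aid in names(m))
    for (rid in view$candidates[[aid]])
      pairs[[length(pairs) + 1L]] <- c(aid, rid)
  nv <- 1L + length(pairs)
  if (nv > 1e4) stop("deterministic LP exceeds the 10^4-variable guard")
  cc <- c(1, rep(0, length(pairs)))
  Aeq <- matrix(0, nrow = length(m), ncol = nv)
  beq <- rep(0, length(m))
  for (ai in seq_along(m)) {
    Aeq[ai, 1L] <- -m[[ai]]
    for (pi in seq_along(pairs))
      if (pairs[[pi]][1L] == names(m)[ai]) Aeq[ai, 1L + pi] <- 1
  }
  A <- matrix(0, nrow = length(view$ids), ncol = nv)
  b <- unname(view$availability)
  for (ri in seq_along(view$ids))
    for (pi in seq_along(pairs))
      if (pairs[[pi]][2L] == view$ids[ri])
        A[ri, 1L + pi] <- emean[[pairs[[pi]][1L]]]
  list(cc = cc, A = A, b = b, Aeq = Aeq, beq = beq, pairs = pairs,
       view = view, m = m, emean = emean)
}

#' Export the deterministic capacity model in LP text format
#'
#' Writes the model in the standard CPLEX LP file format for external
#' verification with any LP solver.
#'
#' @param instance An [shca_instance()] object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_lp_file <- function(instance, path) {
  mod <- det_lp_model(instance)
  vn <- c("N", vapply(mod$pairs, function(p)
    paste0("b_", lp_var_name(p[1L]), "__", lp_var_name(p[2L])), character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("\\ deterministic hospital capacity allocation",
               "Maximize", " obj: N", "Subject To"), con)
  for (i in seq_len(nrow(mod$Aeq))) {
    co <- mod$Aeq[i, ]
    terms <- paste(sprintf("%+.12g %s", co[co != 0], vn[co != 0]),
                   collapse = " ")
    writeLines(sprintf(" alloc_%s: %s = %.12g",
                       lp_var_name(names(mod$m)[i]), terms, mod$beq[i]), con)
  }
  for (i in seq_len(nrow(mod$A))) {
    co <- mod$A[i, ]
    terms <- paste(sprintf("%+.12g %s", co[co != 0], vn[co != 0]),
                   collapse = " ")
    writeLines(sprintf(" cap_%s: %s <= %.12g",
                       lp_var_name(mod$view$ids[i]), terms, mod$b[i]), con)
  }
  writeLines(c("Bounds", paste0(" 0 <= ", vn), "End"), con)
  invisible(path)
}

run_lp <- function(cc, A, b, Aeq, beq, maxiter = 500) {
  r <- tryCatch(
    suppressWarnings(pracma::linprog(cc, A = A, b = b, Aeq = Aeq, beq = beq,
                                     maximize = TRUE, maxiter = maxiter)),
    error = function(e) NULL)
  if (is.null(r) || is.null(r$x) || length(r$x) == 0 ||
      !isTRUE(r$errno == 1)) return(NULL)
  r
}

## Exact deterministic capacity via the cut condition of the underlying
## transportation problem: routing per-patient workloads m_a E[t_a] N into
## space capacities T_s over the bipartite candidate structure is feasible
## iff, for every subset of activities, the subset's workload fits within
## the total availability of its candidate neighbourhood (Gale-Hoffman).
## The capacity is therefore the minimum neighbourhood-capacity-to-workload
## ratio over all non-empty subsets; exact, and immune to simplex cycling.
mincut_det_capacity <- function(instance) {
  view <- resource_view(instance)
  d <- activity_multipliers(instance) * activity_means(instance)
  keep <- names(d)[d > 0]
  if (length(keep) == 0L) return(Inf)
  if (length(keep) > 20L)
    stop("combinatorial capacity check limited to 20 in-demand activities")
  best <- Inf
  for (mask in seq_len(2^length(keep) - 1L)) {
    sel <- keep[bitwAnd(mask, 2^(seq_along(keep) - 1L)) > 0]
    nb <- unique(unlist(view$candidates[sel], use.names = FALSE))
    best <- min(best, sum(view$availability[nb]) / sum(d[sel]))
  }
  best
}

#' Exact deterministic capacity by linear programming
#'
#' Solves `max N` subject to the allocation-balance equalities, candidate
#' restrictions and expected-occupancy constraints `E[U_s] <= T_s`.
#' Intended for tiny certification instances (guard: at most `1e4`
#' variables).
#'
#' @param instance An [shca_instance()] object.
#' @param lp_file Optional path; when given the model is also exported via
#'   [write_lp_file()] (and is still written if the solver fails).
#' @return A list with `N` (the optimum), `beta` (activity x resource
#'   matrix) and `model`.
#' @export
solve_det_lp <- function(instance, lp_file = NULL) {
  stopifnot(inherits(instance, "shca_instance"))
  if (!is.null(lp_file)) write_lp_file(instance, lp_file)
  view <- resource_view(instance)
  m <- activity_multipliers(instance)
  ## an in-demand activity with no candidate resource pins N at zero
  for (aid in names(m))
    if (m[[aid]] > 0 && length(view$candidates[[aid]]) == 0L)
      return(list(N = 0, beta = new_allocation(instance, view), model = NULL))
  if (length(view$ids) == 0L)
    return(list(N = 0, beta = NULL, model = NULL))
  mod <- det_lp_model(instance)
  r <- run_lp(mod$cc, mod$A, mod$b, mod$Aeq, mod$beq, maxiter = 1000)
  if (is.null(r)) {
    ## simplex cycled or failed: fall back to the exact cut condition of
    ## the underlying transportation problem (no allocation recovered)
    N <- tryCatch(mincut_det_capacity(instance), error = function(e) NULL)
    if (is.null(N))
      stop("LP solver failed on the deterministic capacity model",
           if (!is.null(lp_file)) paste0(" (model written to ", lp_file, ")"))
    return(list(N = min(N, upper_bound_N(instance)$N_hat), beta = NULL,
                model = mod))
  }
  beta <- new_allocation(instance, view)
  for (pi in seq_along(mod$pairs))
    beta[mod$pairs[[pi]][1L], mod$pairs[[pi]][2L]] <- r$x[1L + pi]
  list(N = r$fval, beta = beta, model = mod)
}

#' Scenario pool from explicit sample matrices
#'
#' Wraps user-supplied realisation tables as a scenario pool, mainly for
#' oracle certification and tests where the scenario durations must be
#' known exactly.
#'
#' @param samples Named list (by activity id) of numeric matrices with one
#'   row per scenario and one column per realisation.
#' @return An object of class `shca_pool`.
#' @export
scenario_pool_from_samples <- function(samples) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  ns <- unique(vapply(samples, nrow, integer(1)))
  if (length(ns) != 1L) stop("all sample matrices need the same row count")
  structure(list(n_scenarios = ns,
                 n_hat = vapply(samples, ncol, integer(1)),
                 samples = samples, seed = NA_integer_,
                 activity_index = setNames(seq_along(samples),
                                           names(samples))),
            class = "shca_pool")
}

## subsets of 1..n of size k, as a list of integer vectors
subsets_of_size <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  cmb <- utils::combn(n, k)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

#' Exact SAA capacity optimum for tiny instances
#'
#' Computes the optimum of the sample-average deterministic equivalent by
#' exhaustive enumeration: for every admissible set of violating scenarios
#' per resource (at most `floor((1 - SL_s) |I|)` of them) and every integer
#' floor of each allocation entry, the remaining fractional parts and `N`
#' solve a small linear program; the best value over all combinations is
#' the exact optimum.  Realisation indices follow a fixed block convention
#' (consecutive pool columns per activity/resource pair) so the optimum is
#' directly comparable with [occupancy_scenario()] under matching lookup
#' lists.  Refuses instances beyond 2 activities, 2 resources, 6 scenarios
#' or a modest enumeration budget, where the model is intractable.
#'
#' @param instance An [shca_instance()] object.
#' @param pool An `shca_pool` (e.g. [scenario_pool_from_samples()]) whose
#'   matrices are wide enough for the block convention.
#' @param beta_cap Hard cap on the per-pair allocation bound (guard).
#' @param max_lps Enumeration budget (guard).
#' @return A list with `N` (the optimum), `beta` (allocation matrix),
#'   `violations` (per-resource violating scenario sets) and `n_lps`.
#' @export
solve_saa_mip_tiny <- function(instance, pool, beta_cap = 60,
                               max_lps = 5e4) {
  stopifnot(inherits(instance, "shca_instance"), inherits(pool, "shca_pool"))
  view <- resource_view(instance)
  m <- activity_multipliers(instance)
  nI <- pool$n_scenarios
  if (length(m) > 2L || length(view$ids) > 2L || nI > 6L)
    stop("tiny-SAA oracle is restricted to <= 2 activities, <= 2 resources ",
         "and <= 6 scenarios; larger deterministic equivalents are ",
         "intractable for exact solution")
  active <- names(m)[m > 0]
  ## per-pair allocation bound from the smallest realisable duration
  pairs <- list()
  for (aid in active) for (rid in view$candidates[[aid]]) {
    tmin <- min(pool$samples[[aid]])
    bh <- if (tmin > 0) ceiling(view$availability[[rid]] / tmin) else Inf
    if (!is.finite(bh) || bh > beta_cap)
      stop("allocation bound ", bh, " exceeds the oracle guard (", beta_cap, ")")
    pairs[[length(pairs) + 1L]] <- list(aid = aid, rid = rid, beta_hat = bh)
  }
  if (length(pairs) == 0L)
    return(list(N = 0, beta = new_allocation(instance, view),
                violations = NULL, n_lps = 0L))
  ## fixed disjoint column blocks per pair
  off <- 0L
  for (pi in seq_along(pairs)) {
    w <- pairs[[pi]]$beta_hat + 1L
    prev <- Filter(function(q) q$aid == pairs[[pi]]$aid,
                   pairs[seq_len(pi - 1L)])
    start <- if (length(prev)) sum(vapply(prev, function(q)
      q$beta_hat + 1L, numeric(1))) else 0L
    pairs[[pi]]$cols <- (start + 1L):(start + w)
    need <- start + w
    if (ncol(pool$samples[[pairs[[pi]]$aid]]) < need)
      stop("pool for activity '", pairs[[pi]]$aid, "' needs at least ",
           need, " realisations per scenario for the oracle block convention")
  }
  ## big-M occupancy ceiling per resource
  u_plus <- vapply(view$ids, function(rid) {
    tot <- view$availability[[rid]]
    for (p in pairs) if (p$rid == rid)
      tot <- tot + p$beta_hat * max(pool$samples[[p$aid]])
    min(tot, 10 * view$availability[[rid]])
  }, numeric(1))
  names(u_plus) <- view$ids
  ## violation budgets and admissible violation sets per resource
  k_s <- vapply(view$ids, function(rid)
    floor((1 - view$service_level[[rid]]) * nI + 1e-9), numeric(1))
  viol_sets <- lapply(view$ids, function(rid)
    subsets_of_size(nI, as.integer(min(k_s[[match(rid, view$ids)]], nI))))
  names(viol_sets) <- view$ids
  y_opts <- lapply(pairs, function(p) 0:p$beta_hat)
  n_y <- prod(vapply(y_opts, length, numeric(1)))
  n_e <- prod(vapply(viol_sets, length, numeric(1)))
  if (n_y * n_e > max_lps)
    stop("enumeration budget exceeded (", format(n_y * n_e),
         " linear programs); the deterministic equivalent is intractable ",
         "at this size")
  ## cumulative sums of block samples: C[[pi]][i, y+1] = sum of first y
  csum <- lapply(pairs, function(p) {
    M <- pool$samples[[p$aid]][, p$cols, drop = FALSE]
    out <- matrix(0, nrow = nrow(M), ncol = ncol(M) + 1L)
    for (j in seq_len(ncol(M))) out[, j + 1L] <- out[, j] + M[, j]
    out
  })
  np <- length(pairs)
  best <- list(N = 0, beta = new_allocation(instance, view),
               violations = NULL)
  n_lps <- 0L
  e_grid <- expand.grid(lapply(viol_sets, seq_along))
  y_grid <- as.matrix(expand.grid(y_opts))
  for (eg in seq_len(nrow(e_grid))) {
    viol <- lapply(seq_along(view$ids), function(ri)
      viol_sets[[ri]][[e_grid[eg, ri]]])
    names(viol) <- view$ids
    for (yg in seq_len(nrow(y_grid))) {
      y <- y_grid[yg, ]
      ## vars: N, r_1..r_np ; maximize N
      cc <- c(1, rep(0, np))
      Aeq <- matrix(0, nrow = length(active), ncol = 1L + np)
      beq <- numeric(length(active))
      for (ai in seq_along(active)) {
        Aeq[ai, 1L] <- -m[[active[ai]]]
        for (pi in seq_len(np)) if (pairs[[pi]]$aid == active[ai]) {
          Aeq[ai, 1L + pi] <- 1
          beq[ai] <- beq[ai] - y[pi]
        }
      }
      Arows <- list()
      brows <- numeric(0)
      for (ri in seq_along(view$ids)) {
        rid <- view$ids[ri]
        for (i in seq_len(nI)) {
          lim <- if (i %in% viol[[rid]]) u_plus[[rid]]
          else view$availability[[rid]]
          row <- numeric(1L + np)
          base <- 0
          for (pi in seq_len(np)) if (pairs[[pi]]$rid == rid) {
            base <- base + csum[[pi]][i, y[pi] + 1L]
            row[1L + pi] <-
              pool$samples[[pairs[[pi]]$aid]][i, pairs[[pi]]$cols[y[pi] + 1L]]
          }
          if (any(row != 0) || base > lim) {
            Arows[[length(Arows) + 1L]] <- row
            brows <- c(brows, lim - base)
          }
        }
      }
      ## fractional parts bounded by one
      for (pi in seq_len(np)) {
        row <- numeric(1L + np)
        row[1L + pi] <- 1
        Arows[[length(Arows) + 1L]] <- row
        brows <- c(brows, 1)
      }
      if (any(brows < 0)) next  # fixed part already infeasible
      A <- do.call(rbind, Arows)
      n_lps <- n_lps + 1L
      r <- run_lp(cc, A, brows, Aeq, beq)
      if (is.null(r)) next
      if (r$fval > best$N + 1e-9) {
        beta <- new_allocation(instance, view)
        for (pi in seq_len(np))
          beta[pairs[[pi]]$aid, pairs[[pi]]$rid] <- y[pi] + r$x[1L + pi]
        best <- list(N = r$fval, beta = beta, violations = viol)
      }
    }
  }
  c(best, list(n_lps = n_lps))
}
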