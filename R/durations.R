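## Activity-duration random variables.
##
## The workhorse representation is the piecewise-constant empirical
## distribution: a vector of strictly increasing breakpoints whose adjacent
## pairs define sub-intervals, and one probability weight per sub-interval;
## within a sub-interval values are uniform.  Point-mass, normal and uniform
## families are also provided (the latter two mainly for closed-form
## cross-checks of the scenario machinery).

new_dist <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "shca_dist")
}

#' Piecewise-constant duration distribution
#'
#' Empirical activity-duration model: values are uniformly distributed over
#' each contiguous sub-interval defined by adjacent breakpoints, with
#' sub-interval probabilities given by `weights`.
#'
#' @param breakpoints Strictly increasing numeric vector (length m + 1) of
#'   sub-interval endpoints, in time units. The support must be non-negative.
#' @param weights Non-negative numeric vector (length m) of sub-interval
#'   probabilities; normalised to sum to one.
#' @return An object of class `shca_dist`.
#' @examples
#' d <- dist_piecewise(c(0, 2, 10), c(0.5, 0.5))
#' mean(d)  # 0.5*1 + 0.5*6 = 3.5
#' @seealso [dist_point()], [dist_normal()], [dist_uniform()], [dist_sample()]
#' @export
dist_piecewise <- function(breakpoints, weights) {
  breakpoints <- as.numeric(breakpoints)
  weights <- as.numeric(weights)
  if (length(breakpoints) < 2L)
    stop("piecewise distribution needs at least two breakpoints")
  if (any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  if (breakpoints[1L] < 0)
    stop("duration support must be non-negative")
  if (length(weights) != length(breakpoints) - 1L)
    stop("need one weight per sub-interval (length(breakpoints) - 1)")
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative, finite, and not all zero")
  weights <- weights / sum(weights)
  new_dist("piecewise-constant", breakpoints = breakpoints, weights = weights)
}

#' Point-mass (deterministic) duration
#'
#' @param value Duration in time units (>= 0).
#' @return An object of class `shca_dist`.
#' @export
dist_point <- function(value) {
  value <- as.numeric(value)
  stopifnot(length(value) == 1L, is.finite(value), value >= 0)
  new_dist("point-mass", value = value)
}

#' Normal duration distribution
#'
#' Used chiefly for closed-form convolution checks; the support is not
#' truncated at zero, so choose `mean` well above `sd` for physically
#' meaningful durations.
#'
#' @param mean,sd Mean and standard deviation in time units (`sd` > 0).
#' @return An object of class `shca_dist`.
#' @export
dist_normal <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  new_dist("normal", mean = as.numeric(mean), sd = as.numeric(sd))
}

#' Uniform duration distribution
#'
#' @param min,max Support endpoints in time units, `0 <= min < max`.
#' @return An object of class `shca_dist`.
#' @export
dist_uniform <- function(min, max) {
  stopifnot(is.finite(min), is.finite(max), min >= 0, max > min)
  new_dist("uniform", min = as.numeric(min), max = as.numeric(max))
}

#' @export
print.shca_dist <- function(x, ...) {
  cat("<duration:", x$kind, "> mean =", format(mean(x)), "\n")
  invisible(x)
}

#' Expected duration
#'
#' Exact closed-form mean. For the piecewise-constant family this is
#' `sum_j w_j (b_j + b_{j+1}) / 2`.
#'
#' @param x An object of class `shca_dist`.
#' @param ... Ignored.
#' @return The mean duration (time units).
#' @export
mean.shca_dist <- function(x, ...) {
  switch(x$kind,
    "piecewise-constant" = {
      b <- x$breakpoints
      sum(x$weights * (b[-length(b)] + b[-1L]) / 2)
    },
    "point-mass" = x$value,
    "normal" = x$mean,
    "uniform" = (x$min + x$max) / 2,
    stop("unknown distribution kind: ", x$kind)
  )
}

#' Sample activity durations
#'
#' Piecewise-constant sampling is inverse-CDF: a sub-interval is picked with
#' probability equal to its weight, then the value is uniform within it.
#' Results depend only on the current RNG state, so a seeded stream gives
#' bit-reproducible draws.
#'
#' @param dist An object of class `shca_dist`.
#' @param n Number of draws (>= 0).
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(dist, n) {
  stopifnot(inherits(dist, "shca_dist"), n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  switch(dist$kind,
    "piecewise-constant" = {
      b <- dist$breakpoints
      cw <- cumsum(dist$weights)
      u <- runif(n)
      j <- findInterval(u, c(0, cw[-length(cw)]), rightmost.closed = FALSE)
      lo <- b[j]
      hi <- b[j + 1L]
      lo + runif(n) * (hi - lo)
    },
    "point-mass" = rep(dist$value, n),
    "normal" = rnorm(n, dist$mean, dist$sd),
    "uniform" = runif(n, dist$min, dist$max),
    stop("unknown distribution kind: ", dist$kind)
  )
}

#' Distribution function of a duration model
#'
#' @param dist An object of class `shca_dist`.
#' @param q Numeric vector of quantiles.
#' @return `Pr(t <= q)`, vectorised over `q`.
#' @export
dist_cdf <- function(dist, q) {
  stopifnot(inherits(dist, "shca_dist"))
  switch(dist$kind,
    "piecewise-constant" = {
      b <- dist$breakpoints
      cw <- c(0, cumsum(dist$weights))
      vapply(q, function(x) {
        if (x <= b[1L]) return(0)
        if (x >= b[length(b)]) return(1)
        j <- findInterval(x, b)
        cw[j] + dist$weights[j] * (x - b[j]) / (b[j + 1L] - b[j])
      }, numeric(1))
    },
    "point-mass" = as.numeric(q >= dist$value),
    "normal" = pnorm(q, dist$mean, dist$sd),
    "uniform" = punif(q, dist$min, dist$max),
    stop("unknown distribution kind: ", dist$kind)
  )
}

#' Quantile function of a duration model
#'
#' @param dist An object of class `shca_dist`.
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Quantiles, vectorised over `p`.
#' @export
dist_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "shca_dist"), all(p >= 0 & p <= 1))
  switch(dist$kind,
    "piecewise-constant" = {
      b <- dist$breakpoints
      cw <- c(0, cumsum(dist$weights))
      cw[length(cw)] <- 1  # guard rounding
      vapply(p, function(u) {
        j <- max(which(cw <= u + 1e-15))
        if (j >= length(b)) return(b[length(b)])
        w <- dist$weights[j]
        if (w <= 0) return(b[j])
        b[j] + (u - cw[j]) / w * (b[j + 1L] - b[j])
      }, numeric(1))
    },
    "point-mass" = rep(dist$value, length(p)),
    "normal" = qnorm(p, dist$mean, dist$sd),
    "uniform" = stats::qunif(p, dist$min, dist$max),
    stop("unknown distribution kind: ", dist$kind)
  )
}

## Lower end of the support (used for allocation upper bounds).
dist_support_min <- function(dist) {
  switch(dist$kind,
    "piecewise-constant" = dist$breakpoints[1L],
    "point-mass" = dist$value,
    "normal" = -Inf,
    "uniform" = dist$min
  )
}

## High quantile used when deriving the big-M occupancy ceiling.
dist_upper_ref <- function(dist, p = 0.999) {
  switch(dist$kind,
    "piecewise-constant" = dist$breakpoints[length(dist$breakpoints)],
    "point-mass" = dist$value,
    "normal" = qnorm(p, dist$mean, dist$sd),
    "uniform" = dist$max
  )
}

#' Closed-form service level for homogeneous duration families
#'
#' For a space holding integer counts of activities whose durations are all
#' normal, the occupancy is normal with summed mean and variance and
#' `Pr(U <= T)` is exact by the normal CDF.  When every activity is standard
#' uniform on `[0, 1]` the occupancy follows an Irwin-Hall distribution and
#' its CDF is used.  Mixed families have no closed form here and raise an
#' error (use the scenario-pool estimate instead).
#'
#' @param counts Integer vector: number of occurrences of each activity.
#' @param dists List of `shca_dist` objects, parallel to `counts`.
#' @param availability Time availability `T_s` of the space.
#' @return The exact probability `Pr(U_s <= T_s)`.
#' @examples
#' closed_form_service_level(10, list(dist_normal(50, 5)), 520)
#' @export
closed_form_service_level <- function(counts, dists, availability) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == length(dists), all(counts >= 0),
            availability >= 0)
  dists <- dists[counts > 0]
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(1.0)
  kinds <- vapply(dists, `[[`, character(1), "kind")
  if (all(kinds == "normal")) {
    mu <- sum(counts * vapply(dists, `[[`, numeric(1), "mean"))
    v <- sum(counts * vapply(dists, `[[`, numeric(1), "sd")^2)
    return(pnorm((availability - mu) / sqrt(v)))
  }
  if (all(kinds == "uniform")) {
    std <- vapply(dists, function(d) d$min == 0 && d$max == 1, logical(1))
    if (all(std)) {
      n <- sum(counts)
      return(irwin_hall_cdf(availability, n))
    }
  }
  stop("no closed form for this family mix; use the Monte-Carlo estimate")
}

## Irwin-Hall CDF: distribution of the sum of n iid standard uniforms.
irwin_hall_cdf <- function(x, n) {
  if (x <= 0) return(0)
  if (x >= n) return(1)
  k <- 0:floor(x)
  # log-space terms to keep n! manageable; n is small in practice
  s <- sum((-1)^k * exp(lchoose(n, k) + n * log(x - k) - lfactorial(n)))
  min(max(s, 0), 1)
}
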