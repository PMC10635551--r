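## Structured configuration I/O.  One YAML or JSON document describes a
## whole instance: hospital structure, pathways with duration models and
## candidate spaces, and the case mix.  Schema errors name the offending
## field path (e.g. "areas[2].spaces[1].availability").

cfg_fail <- function(path, msg) stop("config field ", path, ": ", msg, call. = FALSE)

cfg_need <- function(x, field, path) {
  if (is.null(x[[field]])) cfg_fail(paste0(path, ".", field), "is missing")
  x[[field]]
}

cfg_num <- function(x, field, path) {
  v <- cfg_need(x, field, path)
  if (!is.numeric(v) || length(v) != 1L || is.na(v))
    cfg_fail(paste0(path, ".", field), "must be a single number")
  v
}

cfg_chr <- function(x, field, path) {
  v <- cfg_need(x, field, path)
  if (!is.character(v) || length(v) != 1L || !nzchar(v))
    cfg_fail(paste0(path, ".", field), "must be a non-empty string")
  v
}

parse_duration_cfg <- function(d, path) {
  if (!is.list(d)) cfg_fail(path, "must be a mapping with a 'kind' entry")
  kind <- cfg_chr(d, "kind", path)
  out <- try(switch(kind,
    "piecewise-constant" = dist_piecewise(
      unlist(cfg_need(d, "breakpoints", path)),
      unlist(cfg_need(d, "weights", path))),
    "point-mass" = dist_point(cfg_num(d, "value", path)),
    "normal" = dist_normal(cfg_num(d, "mean", path), cfg_num(d, "sd", path)),
    "uniform" = dist_uniform(cfg_num(d, "min", path), cfg_num(d, "max", path)),
    cfg_fail(paste0(path, ".kind"), paste0("unknown kind '", kind, "'"))
  ), silent = TRUE)
  if (inherits(out, "try-error"))
    cfg_fail(path, conditionMessage(attr(out, "condition")))
  out
}

duration_to_cfg <- function(d) {
  switch(d$kind,
    "piecewise-constant" = list(kind = d$kind,
                                breakpoints = as.numeric(d$breakpoints),
                                weights = as.numeric(d$weights)),
    "point-mass" = list(kind = d$kind, value = d$value),
    "normal" = list(kind = d$kind, mean = d$mean, sd = d$sd),
    "uniform" = list(kind = d$kind, min = d$min, max = d$max))
}

#' Read a problem instance from a configuration file
#'
#' The file (YAML or JSON, chosen by extension) holds the hospital
#' (`areas` with nested `spaces`), the patient types (`patient_types`,
#' each with a `mix` proportion and nested `pathways` carrying ordered
#' `activities` with duration models and candidate `spaces`), and optional
#' top-level `horizon` and `mode`.  Validation errors name the offending
#' field path.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param renormalise Passed to [case_mix()]: rescale mixes that sum to
#'   one only within `mix_tol`.
#' @param mix_tol Tolerance on mix sums (default `1e-9`).
#' @return An [shca_instance()] object.
#' @seealso [write_instance()], [fixture()]
#' @export
read_instance <- function(path, renormalise = FALSE, mix_tol = 1e-9) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else stop("unrecognised config extension (expect .yaml/.yml/.json): ", path)
  instance_from_config(cfg, renormalise = renormalise, mix_tol = mix_tol)
}

instance_from_config <- function(cfg, renormalise = FALSE, mix_tol = 1e-9) {
  if (!is.list(cfg)) cfg_fail("<root>", "must be a mapping")
  areas_cfg <- cfg_need(cfg, "areas", "<root>")
  areas <- vector("list", length(areas_cfg))
  for (i in seq_along(areas_cfg)) {
    w <- areas_cfg[[i]]
    wp <- sprintf("areas[%d]", i)
    sp_cfg <- if (is.null(w$spaces)) list() else w$spaces
    spaces <- vector("list", length(sp_cfg))
    for (j in seq_along(sp_cfg)) {
      s <- sp_cfg[[j]]
      spp <- sprintf("%s.spaces[%d]", wp, j)
      avail <- cfg_num(s, "availability", spp)
      if (avail <= 0) cfg_fail(paste0(spp, ".availability"), "must be > 0")
      sl <- if (is.null(s$service_level)) 0.95 else cfg_num(s, "service_level", spp)
      if (sl < 0 || sl > 1)
        cfg_fail(paste0(spp, ".service_level"), "must lie in [0, 1]")
      om <- if (is.null(s$o_max)) Inf else cfg_num(s, "o_max", spp)
      spaces[[j]] <- treatment_space(cfg_chr(s, "id", spp), avail, sl, om)
    }
    areas[[i]] <- treatment_area(cfg_chr(w, "id", wp), spaces)
  }
  horizon <- if (is.null(cfg$horizon)) NULL else cfg_num(cfg, "horizon", "<root>")
  hosp <- hospital(areas, horizon)

  types_cfg <- cfg_need(cfg, "patient_types", "<root>")
  mu1 <- numeric(0)
  mu2 <- list()
  pws <- list()
  for (i in seq_along(types_cfg)) {
    g <- types_cfg[[i]]
    gp <- sprintf("patient_types[%d]", i)
    gid <- cfg_chr(g, "type", gp)
    mu1[[gid]] <- cfg_num(g, "mix", gp)
    paths_cfg <- cfg_need(g, "pathways", gp)
    v <- numeric(0)
    for (j in seq_along(paths_cfg)) {
      p <- paths_cfg[[j]]
      pp <- sprintf("%s.pathways[%d]", gp, j)
      pid <- cfg_chr(p, "path", pp)
      v[[pid]] <- cfg_num(p, "mix", pp)
      acts_cfg <- cfg_need(p, "activities", pp)
      if (length(acts_cfg) == 0L) cfg_fail(paste0(pp, ".activities"), "is empty")
      acts <- vector("list", length(acts_cfg))
      for (k in seq_along(acts_cfg)) {
        a <- acts_cfg[[k]]
        ap <- sprintf("%s.activities[%d]", pp, k)
        cand <- unlist(cfg_need(a, "spaces", ap))
        if (!is.character(cand) || length(cand) < 1L)
          cfg_fail(paste0(ap, ".spaces"), "must list at least one space id")
        acts[[k]] <- activity(
          id = cfg_chr(a, "id", ap),
          duration = parse_duration_cfg(cfg_need(a, "duration", ap),
                                        paste0(ap, ".duration")),
          spaces = cand,
          type = if (is.null(a$activity_type)) "generic" else
            cfg_chr(a, "activity_type", ap),
          unit = if (is.null(a$unit)) NA_character_ else a$unit)
      }
      pws[[length(pws) + 1L]] <- pathway(gid, pid, acts)
    }
    mu2[[gid]] <- v
  }
  mix <- case_mix(mu1, mu2, tol = mix_tol, renormalise = renormalise)
  mode <- if (is.null(cfg$mode)) "space" else cfg$mode
  shca_instance(hosp, pathway_catalog(pws), mix, mode = mode)
}

instance_to_config <- function(instance) {
  hosp <- instance$hospital
  areas <- lapply(hosp$areas, function(w) list(
    id = w$id,
    spaces = lapply(w$spaces, function(s) {
      out <- list(id = s$id, availability = s$availability,
                  service_level = s$service_level)
      if (is.finite(s$o_max)) out$o_max <- s$o_max
      out
    })))
  types <- list()
  for (g in names(instance$mix$mu1)) {
    paths <- list()
    for (p in names(instance$mix$mu2[[g]])) {
      pw <- Filter(function(x) x$type == g && x$path == p,
                   instance$catalog$pathways)[[1L]]
      paths[[length(paths) + 1L]] <- list(
        path = p, mix = unname(instance$mix$mu2[[g]][[p]]),
        activities = lapply(pw$activities, function(a) list(
          id = a$id, activity_type = a$type,
          duration = duration_to_cfg(a$duration), spaces = a$spaces)))
    }
    types[[length(types) + 1L]] <- list(
      type = g, mix = unname(instance$mix$mu1[[g]]), pathways = paths)
  }
  list(horizon = hosp$horizon, mode = instance$mode, areas = areas,
       patient_types = types)
}

#' Write a problem instance to a configuration file
#'
#' Round-trips losslessly with [read_instance()].
#'
#' @param instance An [shca_instance()] object.
#' @param path Destination file, `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_instance <- function(instance, path) {
  stopifnot(inherits(instance, "shca_instance"))
  cfg <- instance_to_config(instance)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(cfg, path, precision = 15)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else stop("unrecognised config extension (expect .yaml/.yml/.json): ", path)
  invisible(path)
}

#' Import piecewise-constant durations from long-format CSV
#'
#' Reads rows `(activity, breakpoint, weight)`: for each activity, sorted
#' breakpoints define the sub-intervals and the weight on a row applies to
#' the sub-interval starting at that row's breakpoint; the final row's
#' weight is ignored (may be `NA`).
#'
#' @param path CSV file path.
#' @return Named list of `shca_dist` piecewise-constant distributions.
#' @export
read_durations_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("activity", "breakpoint", "weight")
  if (!all(need %in% names(df)))
    stop("durations CSV needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (aid in unique(df$activity)) {
    sub <- df[df$activity == aid, , drop = FALSE]
    sub <- sub[order(sub$breakpoint), , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("activity '", aid, "' needs at least two breakpoints")
    out[[aid]] <- dist_piecewise(sub$breakpoint,
                                 sub$weight[-nrow(sub)])
  }
  out
}
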