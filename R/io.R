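# Instance bundles are directories of plain CSV files plus a config.json:
# diffable, editable fixtures. Schema (bundle version 1):
#   groups.csv     id,name,care_class,vo_category,n_patients,n_visits,
#                  max_travel_min[,annual_cost_meur]
#   zips.csv       id,x_km,y_km,population
#   sites.csv      id,x_km,y_km,from_existing_hospital
#   traveltime.csv zip_id + one column per site id (minutes)
#   demand.csv     zip_id + one column per group id (patients/yr)
#   usage.csv      group_id,OR,WARD,ICU (facility units/patient)
#   quality.csv    group_id,nl_lo,nl_hi,slope,intercept,baseline_nl
#   colocate.csv   group_id_1,group_id_2
#   config.json    model_config fields + bundle_version

io_stop <- function(kind, msg) {
  stop(structure(class = c(kind, "hosp_io_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Write an instance bundle to a directory
#'
#' @param inst a `hosp_instance`.
#' @param path directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_instance <- function(inst, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(path, f),
                                        row.names = FALSE)
  w(inst$groups, "groups.csv")
  w(inst$zips, "zips.csv")
  w(inst$sites, "sites.csv")
  w(data.frame(zip_id = inst$zips$id, inst$travel, check.names = FALSE),
    "traveltime.csv")
  w(data.frame(zip_id = inst$zips$id, inst$demand, check.names = FALSE),
    "demand.csv")
  w(data.frame(group_id = inst$groups$id, inst$usage, check.names = FALSE),
    "usage.csv")
  qrows <- lapply(as.character(inst$groups$id), function(id) {
    qf <- inst$quality[[id]]
    data.frame(group_id = id, nl_lo = qf$nl_lo, nl_hi = qf$nl_hi,
               slope = qf$slope, intercept = qf$intercept,
               baseline_nl = if (is.null(attr(qf, "baseline_nl")))
                 NA_integer_ else attr(qf, "baseline_nl"),
               vo_category = attr(qf, "vo_category"))
  })
  w(do.call(rbind, qrows), "quality.csv")
  w(data.frame(group_id_1 = inst$colocate[, 1],
               group_id_2 = inst$colocate[, 2]), "colocate.csv")
  cfg <- unclass(inst$config)
  cfg$min_utilization <- as.list(cfg$min_utilization)
  cfg$bundle_version <- 1L
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an instance bundle from a directory
#'
#' Validates the bundle as it loads: missing files, malformed values (e.g. a
#' negative drive time, named by zip and site) and demand-conservation
#' violations are raised as distinct condition classes (`hosp_io_missing`,
#' `hosp_io_value`, `hosp_io_conservation`), all subclasses of
#' `hosp_io_error`.
#'
#' @param path bundle directory written by [write_instance()].
#' @return a `hosp_instance`.
#' @export
read_instance <- function(path) {
  need <- c("groups.csv", "zips.csv", "sites.csv", "traveltime.csv",
            "demand.csv", "usage.csv", "quality.csv", "colocate.csv",
            "config.json")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      io_stop("hosp_io_missing", paste0("bundle file missing: ", f))
  rd <- function(f) utils::read.csv(file.path(path, f), check.names = FALSE,
                                    stringsAsFactors = FALSE)
  groups <- rd("groups.csv")
  zips <- rd("zips.csv")
  sites <- rd("sites.csv")
  ttdf <- rd("traveltime.csv")
  travel <- as.matrix(ttdf[, -1, drop = FALSE])
  bad <- which(!is.finite(travel) | travel < 0, arr.ind = TRUE)
  if (nrow(bad))
    io_stop("hosp_io_value",
            sprintf("traveltime.csv: invalid entry at zip %s, site %s",
                    ttdf$zip_id[bad[1, 1]], colnames(travel)[bad[1, 2]]))
  ddf <- rd("demand.csv")
  demand <- as.matrix(ddf[, -1, drop = FALSE])
  if (any(demand < 0))
    io_stop("hosp_io_value", "demand.csv: negative entry")
  dev <- abs(colSums(demand) - groups$n_patients)
  if (any(dev > 1))
    io_stop("hosp_io_conservation",
            paste0("demand.csv: column sum differs from n_patients by > 1 ",
                   "for group(s) ",
                   paste(groups$id[dev > 1], collapse = ", ")))
  udf <- rd("usage.csv")
  usage <- as.matrix(udf[, facility_types(), drop = FALSE])
  rownames(usage) <- udf$group_id
  qdf <- rd("quality.csv")
  quality <- stats::setNames(lapply(seq_len(nrow(groups)), function(gi) {
    id <- as.character(groups$id[gi])
    qi <- qdf[as.character(qdf$group_id) == id, ]
    structure(data.frame(nl_lo = as.integer(qi$nl_lo),
                         nl_hi = as.integer(qi$nl_hi),
                         slope = qi$slope, intercept = qi$intercept),
              class = c("quality_function", "data.frame"),
              group_id = groups$id[gi], vo_category = qi$vo_category[1],
              baseline_nl = if (is.na(qi$baseline_nl[1])) NULL
                            else as.integer(qi$baseline_nl[1]))
  }), as.character(groups$id))
  cdf <- rd("colocate.csv")
  colocate <- if (nrow(cdf)) as.matrix(cdf) else matrix(integer(0), ncol = 2)
  cfg <- jsonlite::fromJSON(file.path(path, "config.json"))
  if (!is.null(cfg$bundle_version) && cfg$bundle_version != 1L)
    io_stop("hosp_io_value",
            paste0("unsupported bundle version: ", cfg$bundle_version))
  config <- model_config(
    euros_per_qaly = cfg$euros_per_qaly,
    euros_per_travel_hour = cfg$euros_per_travel_hour,
    round_trip_factor = cfg$round_trip_factor,
    big_m = cfg$big_m, mip_gap = cfg$mip_gap,
    utilization_mode = cfg$utilization_mode,
    min_utilization = unlist(cfg$min_utilization),
    seed = cfg$seed, max_refinement_iters = cfg$max_refinement_iters)
  hosp_instance(groups, zips, sites, travel, demand, usage, quality,
                colocate = colocate, config = config)
}

#' Serialize a solution (with a run manifest) to JSON
#'
#' The written file doubles as the run manifest: it snapshots the
#' configuration, seed, solver backend, model size, refinement trace and
#' timestamps next to the solution itself, so a run can be reproduced from
#' the file alone given the instance bundle.
#'
#' @param sol a `hosp_solution`.
#' @param inst the instance it solves.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_solution <- function(sol, inst, path) {
  tr <- attr(sol, "refinement_trace")
  out <- list(
    solver_status = sol$solver_status,
    gap = sol$gap,
    objective_eur = sol$objective_eur,
    open_sites = names(sol$open)[sol$open],
    n_locations = as.list(sol$n_locations),
    quality_eur = as.list(sol$quality_eur),
    travel_eur = as.list(sol$travel_eur),
    offers = lapply(seq_len(ncol(sol$offers)), function(j)
      rownames(sol$offers)[sol$offers[, j] == 1]),
    assign = local({    # columns = groups, rows follow the bundle zip order
      df <- as.data.frame(sol$assign)
      rownames(df) <- NULL
      df
    }),
    manifest = list(
      package_version = as.character(utils::packageVersion("hospalloc")),
      backend = "highs/scipy.optimize.milp",
      seed = inst$config$seed,
      config = local({
        cl <- unclass(inst$config)
        cl$min_utilization <- as.list(cl$min_utilization)
        cl
      }),
      model_size = as.list(attr(sol, "model_size")),
      refinement_trace = tr,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  names(out$offers) <- colnames(sol$offers)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "columns")
  invisible(path)
}
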