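# File formats: events CSV, boundary GeoJSON, covariate tables, result CSVs.

#' Sinusoidal equal-area projection of lon/lat to planar km
#'
#' Area-preserving, adequate at the regional scales the model targets. The
#' origin defaults to the centroid of the input so coordinates are small.
#'
#' @param lon,lat degrees.
#' @param lon0,lat0 projection origin (degrees); default data means.
#' @return matrix with columns `x`, `y` (km).
#' @export
project_lonlat <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  R <- 6371
  x <- R * (lon - lon0) * pi / 180 * cos(lat * pi / 180)
  y <- R * (lat - lat0) * pi / 180
  cbind(x = x, y = y)
}

#' Read an events CSV
#'
#' Expects columns `x,y,date` (planar km) or `lon,lat,date` (converted via
#' the equal-area projection). Dates must be ISO-8601. Rows with unparseable
#' dates are rejected with their line numbers; the read aborts if more than
#' `max_bad_fraction` of rows fail.
#'
#' @param path CSV path.
#' @param max_bad_fraction tolerated fraction of malformed rows.
#' @return data.frame `x, y, date` (planar, Date); attribute `"rejected"`
#'   lists rejected line numbers.
#' @export
read_events <- function(path, max_bad_fraction = 0.01) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lonlat <- all(c("lon", "lat") %in% names(df))
  if (!lonlat && !all(c("x", "y") %in% names(df)))
    stop("schema error: events CSV needs columns x,y,date or lon,lat,date", call. = FALSE)
  if (!"date" %in% names(df))
    stop("schema error: events CSV needs a date column", call. = FALSE)
  dates <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  # reject calendar-impossible dates that as.Date silently rolls over
  ok <- !is.na(dates) & format(dates, "%Y-%m-%d") == as.character(df$date)
  bad <- which(!ok)
  if (length(bad) > max_bad_fraction * nrow(df))
    stop(sprintf("schema error: %d unparseable date(s), e.g. line %d ('%s')",
                 length(bad), bad[1L] + 1L, df$date[bad[1L]]), call. = FALSE)
  df <- df[ok, , drop = FALSE]; dates <- dates[ok]
  xy <- if (lonlat) project_lonlat(df$lon, df$lat) else cbind(x = df$x, y = df$y)
  out <- data.frame(x = xy[, 1L], y = xy[, 2L], date = dates)
  attr(out, "rejected") <- bad
  out
}

#' Read an observation-window polygon from GeoJSON
#'
#' Accepts a `Polygon` geometry (directly, as a `Feature`, or the first
#' feature of a `FeatureCollection`); the first ring is the exterior.
#'
#' @param path GeoJSON file.
#' @return `n x 2` coordinate matrix.
#' @export
read_boundary_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(g$type) && g$type == "Polygon") g
  else if (!is.null(g$geometry)) g$geometry
  else if (!is.null(g$features)) g$features$geometry[1, ] %||% g$features[[1]]$geometry
  else NULL
  if (is.null(geom) || is.null(geom$type))
    stop("schema error: no Polygon geometry found in GeoJSON", call. = FALSE)
  coords <- geom$coordinates
  ring <- if (is.array(coords) && length(dim(coords)) == 3L) coords[1L, , ]
  else if (is.list(coords)) matrix(unlist(coords[[1L]]), ncol = 2L, byrow = TRUE)
  else coords
  as_polygon(ring)
}

#' Write a polygon as GeoJSON
#' @param poly `n x 2` matrix; `path` output file.
#' @export
write_boundary_geojson <- function(poly, path) {
  poly <- as_polygon(poly)
  ring <- rbind(poly, poly[1L, ])
  obj <- list(type = "Polygon",
              coordinates = list(lapply(seq_len(nrow(ring)),
                                        function(i) c(ring[i, 1L], ring[i, 2L]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a long-format node covariate table
#'
#' CSV columns `node_id, period, name, value`; reshaped to the
#' `(N*T) x p` design (vertex index fastest).
#'
#' @param path CSV path.
#' @param N,T mesh vertex and period counts (validated).
#' @return an `lgcp_covariates`.
#' @export
read_node_covariates <- function(path, N, T) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "period", "name", "value")
  if (!all(need %in% names(df)))
    stop("schema error: covariates CSV needs columns node_id,period,name,value",
         call. = FALSE)
  nms <- sort(unique(df$name))
  node <- matrix(NA_real_, N * T, length(nms), dimnames = list(NULL, nms))
  idx <- (df$period - 1L) * N + df$node_id
  for (nm in nms) {
    sel <- df$name == nm
    node[idx[sel], nm] <- df$value[sel]
  }
  if (anyNA(node))
    stop("schema error: covariate table does not cover every node-period", call. = FALSE)
  covariate_design(node, nms)
}

#' @noRd
write_csv6 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a fit as a CSV set plus JSON metadata
#'
#' Writes `hyperparameters.csv`, `fixed_effects.csv`, `components.csv`,
#' `spatial_field.csv`, `intensity.csv` and `run.json` (config echo, seed,
#' convergence) into `dir`. Numeric columns are stored at 6 significant
#' digits.
#'
#' @param fit an `lgcp_fit`.
#' @param dir output directory.
#' @param config optional configuration list echoed into `run.json`.
#' @export
write_fit_csvs <- function(fit, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv6(fit$hyper, file.path(dir, "hyperparameters.csv"))
  write_csv6(fit$fixed, file.path(dir, "fixed_effects.csv"))
  comp <- NULL
  for (nm in names(fit$components)) {
    cs <- fit$components[[nm]]
    comp <- rbind(comp, data.frame(component = nm, period = seq_len(fit$model$layout$T),
                                   mean = cs$mean, sd = cs$sd,
                                   q0.025 = cs$q0.025, q0.5 = cs$q0.5,
                                   q0.975 = cs$q0.975))
  }
  if (is.null(comp)) comp <- data.frame(component = character(0), period = integer(0),
                                        mean = numeric(0), sd = numeric(0),
                                        q0.025 = numeric(0), q0.5 = numeric(0),
                                        q0.975 = numeric(0))
  write_csv6(comp, file.path(dir, "components.csv"))
  if (!is.null(fit$field)) {
    write_csv6(data.frame(vertex = seq_len(nrow(fit$model$mesh$vertices)),
                          x = fit$model$mesh$vertices[, 1L],
                          y = fit$model$mesh$vertices[, 2L],
                          mean = fit$field$time_avg_mean,
                          sd = fit$field$time_avg_sd),
               file.path(dir, "spatial_field.csv"))
  }
  N <- fit$model$aug$N; T <- fit$model$layout$T
  write_csv6(data.frame(vertex = rep(seq_len(N), T),
                        period = rep(seq_len(T), each = N),
                        log_intensity = as.vector(fit$eta_fit)),
             file.path(dir, "intensity.csv"))
  meta <- list(package = "dynlgcp",
               version = as.character(utils::packageVersion("dynlgcp")),
               seed = fit$seed, strategy = fit$strategy,
               convergence = fit$convergence,
               theta = as.list(fit$theta),
               config = config,
               r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(meta, file.path(dir, "run.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
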