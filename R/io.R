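#' Write a trace set to disk
#'
#' Writes the long-format trace table (`time_s`, `tank_id`, `channel`,
#' `conc_mg_per_L`, tab-separated, full double precision) and a YAML
#' metadata sidecar (group, geometry, schedule, start clock, seed) next
#' to it.  True-rate information is not persisted: files describe what an
#' instrument would have produced.
#'
#' @param ts A `trace_set`.
#' @param path Stem path; writes `<path>_traces.tsv` and
#'   `<path>_meta.yml`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  tr <- ts$traces
  df <- data.frame(time_s = sprintf("%.17g", tr$time_s),
                   tank_id = tr$tank_id, channel = tr$channel,
                   conc_mg_per_L = sprintf("%.17g", tr$conc))
  utils::write.table(df, paste0(path, "_traces.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  m <- ts$meta
  meta <- list(
    group = m$group, days = m$days, tanks = m$tanks, seed = m$seed,
    start_clock = m$start_clock,
    start_conc = as.list(m$start_conc),
    fish = list(n_fish = m$fish$n_fish, mean_weight = m$fish$mean_weight,
                mean_volume = m$fish$mean_volume,
                body_length = m$fish$body_length),
    chamber = list(respir_vol = m$chamber$respir_vol,
                   cycle_length = m$chamber$cycle_length,
                   measure_window = m$chamber$measure_window,
                   sensor_interval = m$chamber$sensor_interval,
                   tank_volume = m$chamber$tank_volume),
    schedule = list(lights_on = m$schedule$lights_on,
                    lights_off = m$schedule$lights_off,
                    cycle_length = m$schedule$cycle_length)
  )
  yaml::write_yaml(meta, paste0(path, "_meta.yml"), precision = 15)
  invisible(path)
}

#' Read a trace set from disk
#'
#' Counterpart of [write_traces()].  Validates the table (known
#' channels, strictly increasing time within each tank x channel) and
#' reports malformed rows with their line numbers.
#'
#' @param path Stem path used at write time.
#' @return A `trace_set` (with `truth = NULL`).
#' @export
read_traces <- function(path) {
  tsv <- paste0(path, "_traces.tsv")
  yml <- paste0(path, "_meta.yml")
  if (!file.exists(tsv)) stop("trace file not found: ", tsv, call. = FALSE)
  if (!file.exists(yml)) stop("metadata sidecar not found: ", yml,
                              call. = FALSE)
  tr <- utils::read.table(tsv, header = TRUE, sep = "\t",
                          colClasses = c("numeric", "character",
                                         "character", "numeric"))
  names(tr) <- c("time_s", "tank_id", "channel", "conc")
  bad <- which(!tr$channel %in% .channels)
  if (length(bad)) {
    stop("unknown channel '", tr$channel[bad[1]], "' at line ",
         bad[1] + 1, " of ", tsv, call. = FALSE)
  }
  key <- paste(tr$tank_id, tr$channel)
  for (k in unique(key)) {
    idx <- which(key == k)
    t <- tr$time_s[idx]
    if (is.unsorted(t, strictly = TRUE)) {
      off <- idx[which(diff(t) <= 0)[1] + 1]
      stop("non-monotone time for ", k, " at line ", off + 1, " of ",
           tsv, call. = FALSE)
    }
  }
  m <- yaml::read_yaml(yml)
  meta <- list(
    group = m$group, days = m$days, tanks = m$tanks, seed = m$seed,
    fish = fish_lot(m$fish$n_fish, m$fish$mean_weight,
                    m$fish$mean_volume, m$fish$body_length),
    chamber = chamber_spec(m$chamber$respir_vol, m$chamber$cycle_length,
                           m$chamber$measure_window,
                           m$chamber$sensor_interval,
                           m$chamber$tank_volume),
    schedule = photoperiod_schedule(m$schedule$lights_on,
                                    m$schedule$lights_off,
                                    m$schedule$cycle_length),
    start_clock = m$start_clock,
    start_conc = unlist(m$start_conc)
  )
  structure(list(traces = tr, meta = meta, truth = NULL),
            class = "trace_set")
}

#' Write a rate/quotient table as delimited text
#'
#' One row per record: `time_h`, `tank_id`, `vo2`, `vco2`, `rq` (hourly
#' grid) and `vn`, `aq` (bi-hourly grid); fields that do not exist on a
#' row's grid are left empty.
#'
#' @param rs A `rate_series`.
#' @param file Output path (TSV).
#' @return `file`, invisibly.
#' @export
write_rate_table <- function(rs, file) {
  h <- rs$hourly
  h$vn <- NA_real_
  h$aq <- NA_real_
  b <- rs$bihourly
  if (!is.null(b)) {
    b <- data.frame(tank_id = b$tank_id, time_h = b$time_h,
                    vo2 = NA_real_, vco2 = NA_real_, rq = NA_real_,
                    vn = b$vn, aq = b$aq)
    h <- rbind(h, b)
  }
  h <- h[order(h$tank_id, h$time_h), ]
  utils::write.table(h, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' Plot the tank-mean profile of one parameter with scotophase shading
#'
#' @param rs A `rate_series`.
#' @param parameter One of `OR`, `CR`, `AE`, `RQ`, `AQ`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted profile data.frame.
#' @export
plot_profile <- function(rs, parameter = "OR", ...) {
  prof <- metabolic_profile(rs)
  y <- prof[[parameter]]
  graphics::plot(prof$time_h, y, type = "n", xlab = "time (h)",
                 ylab = sprintf("%s (mg/kg/h)", parameter), ...)
  dark <- prof$phase == "scotophase"
  blocks <- rle(as.integer(dark))
  ends <- cumsum(blocks$lengths)
  starts <- ends - blocks$lengths + 1
  for (i in which(blocks$values == 1)) {
    graphics::rect(prof$time_h[starts[i]] - 0.5, graphics::par("usr")[3],
                   prof$time_h[ends[i]] + 0.5, graphics::par("usr")[4],
                   col = grDevices::grey(0.9), border = NA)
  }
  graphics::lines(prof$time_h, y)
  invisible(prof)
}
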