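# CSV dialect throughout: RFC 4180, dot decimal, UTF-8, one header row.
# Units are fixed per format: minutes (events), ms/mV/uA (sweeps),
# seconds/AU (traces).

read_csv_checked <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Read / write egg-laying event tables
#'
#' Event CSV: columns `animal_id`, `t` (event time, minutes). Times must be
#' strictly increasing within each animal.
#'
#' @param path CSV file path.
#' @return `read_events()`: named list of `egg_timeline` objects (duration
#'   taken as the last event time).
#' @export
read_events <- function(path) {
  df <- read_csv_checked(path, c("animal_id", "t"))
  if (nrow(df) == 0) {
    warning("empty event file: ", path)
    return(list())
  }
  if (any(!is.finite(df$t)))
    stop(sprintf("%s: non-numeric event time at row %d", path,
                 which(!is.finite(df$t))[1]), call. = FALSE)
  out <- list()
  for (id in unique(df$animal_id)) {
    rows <- which(df$animal_id == id)
    t <- df$t[rows]
    bad <- which(diff(t) <= 0)
    if (length(bad))
      stop(sprintf("%s: non-increasing event time for animal '%s' at row %d",
                   path, id, rows[bad[1] + 1]), call. = FALSE)
    out[[as.character(id)]] <- structure(
      list(event_times = t, duration = max(t)), class = "egg_timeline")
  }
  out
}

#' @rdname read_events
#' @param timelines named list of `egg_timeline` objects.
#' @export
write_events <- function(timelines, path) {
  if (inherits(timelines, "egg_timeline")) timelines <- list(animal1 = timelines)
  ids <- names(timelines)
  if (is.null(ids)) ids <- paste0("animal", seq_along(timelines))
  df <- do.call(rbind, lapply(seq_along(timelines), function(i) {
    tl <- timelines[[i]]
    if (length(tl$event_times) == 0) return(NULL)
    data.frame(animal_id = ids[i], t = tl$event_times)
  }))
  if (is.null(df)) df <- data.frame(animal_id = character(0), t = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write voltage-clamp sweep tables
#'
#' Sweep CSV: column `t_ms` then one current column per step labeled by
#' voltage, e.g. `V_-60` for a -60 mV step. Currents in µA.
#'
#' @param path CSV file path.
#' @param protocol optional [step_protocol()]; when absent a minimal
#'   activation protocol is reconstructed from the file (steps from the
#'   column labels, durations from the time grid).
#' @return `read_sweeps()`: a `sweep_set` object.
#' @export
read_sweeps <- function(path, protocol = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"t_ms" %in% names(df))
    stop(sprintf("%s: missing required column(s): t_ms", path), call. = FALSE)
  vcols <- grep("^V_", names(df), value = TRUE)
  if (length(vcols) == 0)
    stop(sprintf("%s: no sweep columns (expected labels like V_-60)", path),
         call. = FALSE)
  currents <- as.matrix(df[vcols])
  if (any(!is.finite(currents)))
    stop(sprintf("%s: NaN/non-numeric current value", path), call. = FALSE)
  steps <- as.numeric(sub("^V_", "", vcols))
  if (any(is.na(steps)))
    stop(sprintf("%s: unparseable voltage label '%s'", path,
                 vcols[which(is.na(steps))[1]]), call. = FALSE)
  t <- df$t_ms
  if (is.null(protocol))
    protocol <- step_protocol("activation", steps = steps,
                              step_duration = max(t),
                              sample_interval = if (length(t) > 1) t[2] - t[1] else 1)
  structure(list(protocol = protocol, time = t, currents = currents),
            class = "sweep_set")
}

#' @rdname read_sweeps
#' @param sweeps a `sweep_set`.
#' @export
write_sweeps <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  df <- data.frame(t_ms = sweeps$time, sweeps$currents, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write fluorescence traces
#'
#' Trace CSV: columns `t_s` (seconds), `roi`, `background` (AU). The
#' sampling rate is recovered from the time column.
#'
#' @param path CSV file path.
#' @return `read_traces()`: a [fluorescence_trace()].
#' @export
read_traces <- function(path) {
  df <- read_csv_checked(path, c("t_s", "roi", "background"))
  if (any(!is.finite(df$roi)) || any(!is.finite(df$background)))
    stop(sprintf("%s: NaN/non-numeric fluorescence value", path), call. = FALSE)
  rate <- if (nrow(df) > 1) 1 / stats::median(diff(df$t_s)) else 0.5
  fluorescence_trace(df$roi, df$background, sample_rate = rate)
}

#' @rdname read_traces
#' @param trace a [fluorescence_trace()].
#' @export
write_traces <- function(trace, path) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  t <- (seq_along(trace$roi) - 1) / trace$sample_rate
  utils::write.csv(data.frame(t_s = t, roi = trace$roi,
                              background = trace$background),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write embryo-stage count tables
#'
#' Stage CSV: columns `genotype`, `cat1` .. `cat7` (counts per ordinal
#' category, earliest first).
#'
#' @param path CSV file path.
#' @return `read_stages()`: named list of [stage_distribution()] objects.
#' @export
read_stages <- function(path) {
  cats <- paste0("cat", 1:7)
  df <- read_csv_checked(path, c("genotype", cats))
  out <- lapply(seq_len(nrow(df)), function(i)
    stage_distribution(as.integer(df[i, cats])))
  names(out) <- df$genotype
  out
}

#' @rdname read_stages
#' @param dists named list of [stage_distribution()] objects.
#' @export
write_stages <- function(dists, path) {
  df <- do.call(rbind, lapply(names(dists), function(g)
    data.frame(genotype = g, t(stats::setNames(as.integer(dists[[g]]),
                                               paste0("cat", 1:7))))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
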