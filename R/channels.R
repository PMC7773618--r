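#' Kinematic channel sets
#'
#' A `neck_channels` object holds named, uniformly sampled time series on a
#' shared time grid: boundary inputs (`t1_x`, `t1_z`, `t1_ry`, `sled_x`),
#' simulation outputs (`head_x`, `head_z`, `head_ry`, `c1_ry` ... `c7_ry`)
#' and per-muscle activation traces.  Time is in milliseconds; displacements
#' in metres, rotations in radians, activations dimensionless.
#'
#' @param time_ms strictly increasing, uniform time grid in ms.
#' @param values named list or data.frame of numeric vectors, one per channel,
#'   each the same length as `time_ms`.
#' @param units named character vector of unit strings, one per channel
#'   (defaults to `"m"` for `*_x`/`*_z`, `"rad"` for `*_ry`, `"1"` otherwise).
#' @return an object of class `neck_channels` (a data.frame with a `units`
#'   attribute; first column `time_ms`).
#' @export
kinematic_channels <- function(time_ms, values, units = NULL) {
  time_ms <- as.numeric(time_ms)
  stop_if(length(time_ms) < 2, "need at least two time samples")
  check_finite(time_ms, "time_ms")
  dt <- diff(time_ms)
  stop_if(any(dt <= 0), "time grid must be strictly increasing")
  stop_if(max(abs(dt - dt[1])) > 1e-9 * max(abs(time_ms)) + 1e-12,
          "time grid must be uniform")
  values <- as.list(values)
  stop_if(is.null(names(values)) || any(names(values) == ""),
          "all channels must be named")
  for (nm in names(values)) {
    v <- as.numeric(values[[nm]])
    stop_if(length(v) != length(time_ms),
            sprintf("channel '%s' length differs from time grid", nm))
    check_finite(v, sprintf("channel '%s'", nm))
    values[[nm]] <- v
  }
  if (is.null(units)) units <- vapply(names(values), default_unit, character(1))
  stopifnot(all(names(values) %in% names(units)) || length(units) == length(values))
  if (is.null(names(units))) names(units) <- names(values)
  df <- data.frame(time_ms = time_ms, values, check.names = FALSE)
  structure(df, units = units[names(values)], class = c("neck_channels", "data.frame"))
}

default_unit <- function(name) {
  if (grepl("_ry$", name)) "rad"
  else if (grepl("_(x|z)$", name)) "m"
  else "1"
}

#' @export
print.neck_channels <- function(x, ...) {
  cat(sprintf("<neck_channels> %d channels, %d samples, t = [%g, %g] ms\n",
              ncol(x) - 1L, nrow(x), min(x$time_ms), max(x$time_ms)))
  un <- attr(x, "units")
  cat("  ", paste(sprintf("%s [%s]", names(un), un), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract a single channel
#'
#' @param x a `neck_channels` object.
#' @param name channel name.
#' @return data.frame with columns `time_ms` and `value`, plus a `unit`
#'   attribute (class `kin_channel`).
#' @export
channel <- function(x, name) {
  stop_if(!name %in% names(x), sprintf("channel '%s' not present", name))
  structure(data.frame(time_ms = x$time_ms, value = x[[name]]),
            unit = attr(x, "units")[[name]], name = name,
            class = c("kin_channel", "data.frame"))
}

channel_names <- function(x) setdiff(names(x), "time_ms")

#' Read and write channel files
#'
#' CSV layout: header `time_ms,<name>,...`, a second row holding the unit of
#' each column, then numeric rows.  The JSON layout is an object with `time_ms`,
#' `units` and `channels` members.  Both round-trip bit-exactly (values are
#' serialized with 17 significant digits).
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return `read_channels` returns a [kinematic_channels()] object.
#' @export
read_channels <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    return(kinematic_channels(obj$time_ms, obj$channels, unlist(obj$units)))
  }
  lines <- readLines(path)
  stop_if(length(lines) < 3, "channel CSV needs header, unit row and data")
  hdr <- strsplit(lines[1], ",")[[1]]
  stop_if(hdr[1] != "time_ms", "first column must be time_ms")
  units <- strsplit(lines[2], ",")[[1]]
  dat <- read.csv(text = lines[-2], check.names = FALSE)
  tm <- dat$time_ms
  stop_if(any(!is.finite(tm)), "non-numeric time values")
  bad <- which(diff(tm) <= 0)
  stop_if(length(bad) > 0,
          sprintf("time column not strictly increasing at data row %d", bad[1] + 1L))
  kinematic_channels(tm, dat[-1], structure(units[-1], names = hdr[-1]))
}

#' @param x a `neck_channels` object.
#' @rdname read_channels
#' @export
write_channels <- function(x, path) {
  stopifnot(inherits(x, "neck_channels"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(time_ms = x$time_ms,
                units = as.list(attr(x, "units")),
                channels = as.list(x[channel_names(x)]))
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("time_ms", channel_names(x)), collapse = ","), con)
    writeLines(paste(c("ms", attr(x, "units")[channel_names(x)]), collapse = ","), con)
    body <- apply(vapply(names(x), function(nm) format(x[[nm]], digits = 17, trim = TRUE),
                         character(nrow(x))), 1, paste, collapse = ",")
    writeLines(body, con)
  }
  invisible(path)
}

# resample one channel to a given uniform grid (linear interpolation)
resample_channel <- function(ch, time_ms) {
  v <- stats::approx(ch$time_ms, ch$value, xout = time_ms, rule = 2)$y
  structure(data.frame(time_ms = time_ms, value = v),
            unit = attr(ch, "unit"), name = attr(ch, "name"),
            class = c("kin_channel", "data.frame"))
}
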