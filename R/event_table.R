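# Per-cell measurement container: named channel columns on a linear scale,
# acquisition/transform metadata, and attached boolean gate masks.

#' Event table
#'
#' The carrier for list-mode cytometry data: a data frame of per-event
#' channel values (linear scale), plus metadata and named [gate_mask()]
#' objects attached as analysis proceeds.
#'
#' @param data data frame of numeric channel columns; no missing values.
#' @param metadata list of acquisition info / transforms applied.
#' @param masks named list of [gate_mask()] objects.
#' @return an object of class `event_table`.
#' @export
event_table <- function(data, metadata = list(), masks = list()) {
  data <- as.data.frame(data)
  if (!nrow(data)) stop("event table must contain at least one event")
  num <- vapply(data, is.numeric, logical(1))
  if (!all(num)) stop("all channels must be numeric: ",
                      paste(names(data)[!num], collapse = ", "))
  if (anyNA(data)) stop("event table must not contain missing values")
  for (m in masks) {
    if (length(m$mask) != nrow(data)) stop("mask length does not match event count")
  }
  structure(list(data = data, metadata = metadata, masks = masks),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("event_table:", nrow(x$data), "events x", ncol(x$data), "channels (",
      paste(names(x$data), collapse = ", "), ")\n")
  if (length(x$masks)) {
    cat("  masks:", paste(sprintf("%s[%d]", names(x$masks),
                                  vapply(x$masks, function(m) sum(m$mask), integer(1))),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

as_event_table <- function(x) {
  if (inherits(x, "event_table")) return(x)
  if (inherits(x, "synthetic_population")) return(x$events)
  if (is.data.frame(x)) return(event_table(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an event table")
}

#' @rdname event_table
#' @param events an `event_table`.
#' @export
n_events <- function(events) nrow(as_event_table(events)$data)

#' @rdname event_table
#' @export
channels <- function(events) names(as_event_table(events)$data)

channel_values <- function(events, channel) {
  events <- as_event_table(events)
  if (!channel %in% names(events$data)) {
    stop("channel '", channel, "' not present (have: ",
         paste(names(events$data), collapse = ", "), ")")
  }
  events$data[[channel]]
}

#' Attach a gate mask to an event table
#'
#' @param events an [event_table()].
#' @param mask a [gate_mask()].
#' @return the event table with the mask stored under its name.
#' @export
attach_mask <- function(events, mask) {
  events <- as_event_table(events)
  stopifnot(inherits(mask, "gate_mask"))
  if (length(mask$mask) != n_events(events)) {
    stop("mask length does not match event count")
  }
  events$masks[[mask$name]] <- mask
  events
}
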