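# Readers/writers and channel-role mapping. Canonical channel roles (dna,
# dna_width, phh3, cyclin_a2, cyclin_b1, ssc) decouple instrument parameter
# names from analysis code.

#' Read events from FCS or CSV
#'
#' Reads an FCS 3.x file (values returned on the linear scale; see
#' [read_fcs()]) or a CSV with a header row. Non-numeric CSV columns are
#' dropped into metadata. An optional mapping renames instrument parameter
#' names to canonical channel roles; mapping a name that is absent from the
#' file is an error that lists the available parameter names.
#'
#' @param path input file (`.fcs` or `.csv`).
#' @param mapping named character vector, `c(role = "parameter name", ...)`.
#' @return an [event_table()].
#' @export
read_events <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    events <- read_fcs(path)
  } else {
    df <- read.csv(path, check.names = FALSE)
    meta <- list(source = path)
    # channels are complete numeric columns; anything else (simulator truth
    # annotations, labels, columns with missing values) goes to metadata
    chan <- vapply(df, is.numeric, logical(1)) & !vapply(df, anyNA, logical(1)) &
      !startsWith(names(df), "truth_")
    if (!all(chan)) {
      meta$dropped_columns <- names(df)[!chan]
      meta$annotations <- df[!chan]
      df <- df[chan]
    }
    events <- event_table(df, metadata = meta)
  }
  if (!is.null(mapping)) {
    missing <- setdiff(unname(mapping), names(events$data))
    if (length(missing)) {
      stop("mapped parameter(s) not in file: ", paste(missing, collapse = ", "),
           "; available: ", paste(names(events$data), collapse = ", "))
    }
    nm <- names(events$data)
    for (role in names(mapping)) nm[nm == mapping[[role]]] <- role
    names(events$data) <- nm
  }
  events
}

#' Write events to CSV (channels plus attached mask columns)
#'
#' @param events an [event_table()].
#' @param path output path.
#' @param masks include attached gate masks as logical label columns.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, masks = TRUE) {
  events <- as_event_table(events)
  df <- events$data
  if (masks && length(events$masks)) {
    for (m in events$masks) df[[paste0("gate_", m$name)]] <- m$mask
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export gate definitions and counts as JSON
#'
#' @param events an [event_table()] with attached masks.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gate_log <- function(events, path) {
  events <- as_event_table(events)
  obj <- lapply(events$masks, function(m) {
    list(name = m$name, definition = m$definition,
         events_in = sum(m$mask), events_total = length(m$mask))
  })
  jsonlite::write_json(unname(obj), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
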