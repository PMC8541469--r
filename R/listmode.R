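#' List-mode coincidence data
#'
#' A `listmode_set` holds one coincidence event per row. Mandatory per-photon
#' columns are `block` (0-based id), `u`, `v` (face-local mm), `doi` (mm) and
#' `e` (deposited energy, keV), suffixed `1`/`2`, plus a per-event time stamp
#' `t` (ns, carried but unused). Optional ground-truth columns (present for
#' all events or none) are `scatter1`/`scatter2` (logical: photon Compton
#' scattered in the phantom at least once), `nscat1`/`nscat2` (phantom scatter
#' multiplicities), `origin_z` (annihilation z, mm), `origin_in_fov` and
#' `source_id`.
#'
#' The constructor enforces the scanner's hardware acceptance window on both
#' photon energies: events failing it are dropped (the count is kept in
#' `provenance$n_window_rejected_at_load`).
#'
#' @param events a data.frame of events (see above).
#' @param geometry the [scanner_geometry()] the events were acquired on.
#' @param provenance free-form list of acquisition metadata (simulation
#'   parameters, seeds, counters).
#' @return an object of class `listmode_set`.
#' @export
listmode_set <- function(events, geometry, provenance = list()) {
  events <- data.table::as.data.table(events)
  req <- c("block1", "u1", "v1", "doi1", "e1", "block2", "u2", "v2", "doi2",
           "e2", "t")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("missing event columns: ", paste(miss, collapse = ", "))
  truth_cols <- c("scatter1", "scatter2", "nscat1", "nscat2")
  has_truth <- all(truth_cols %in% names(events))
  if (!has_truth && any(truth_cols %in% names(events)))
    stop("truth columns must be present for all events or none")
  win <- geometry$acceptance_window
  keep <- events$e1 >= win[1] & events$e1 <= win[2] &
    events$e2 >= win[1] & events$e2 <= win[2]
  n_rej <- sum(!keep)
  if (n_rej > 0) events <- events[keep]
  provenance$n_window_rejected_at_load <-
    n_rej + (provenance$n_window_rejected_at_load %||% 0)
  structure(list(events = events, geometry = geometry,
                 provenance = provenance, has_truth = has_truth),
            class = "listmode_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.listmode_set <- function(x, ...) {
  cat(sprintf("<listmode_set> %d events (%s truth labels), geometry %s\n",
              nrow(x$events), if (x$has_truth) "with" else "no",
              geometry_hash(x$geometry)))
  invisible(x)
}

#' Number of events in a list-mode set
#' @param set a [listmode_set()].
#' @export
n_events <- function(set) nrow(set$events)

lm_columns <- function(has_truth) {
  cols <- c("block1", "u1", "v1", "doi1", "e1", "block2", "u2", "v2", "doi2",
            "e2", "t")
  if (has_truth)
    cols <- c(cols, "scatter1", "scatter2", "nscat1", "nscat2",
              "e_true1", "e_true2", "origin_z", "origin_in_fov", "source_id")
  cols
}

LM_MAGIC <- "PETSCLM1"

#' Write a list-mode set to disk
#'
#' Two formats are supported. `csv`: a header line of column names followed by
#' one row per event, doubles printed with 17 significant digits so the
#' round trip is bit-exact. `binary`: a small versioned text header (magic,
#' version, event count, truth flag, geometry hash, column list) terminated by
#' a newline, followed by the columns as consecutive little-endian float64
#' arrays.
#'
#' @param set a [listmode_set()].
#' @param path output file path.
#' @param format `"csv"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_listmode <- function(set, path, format = c("csv", "binary")) {
  format <- match.arg(format)
  cols <- intersect(lm_columns(set$has_truth), names(set$events))
  ev <- set$events[, cols, with = FALSE]
  if (format == "csv") {
    txt <- vapply(ev, function(col) sprintf("%.17g", as.numeric(col)),
                  character(nrow(ev)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(cols, collapse = ","), con)
    if (nrow(ev) > 0) {
      if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1)
      writeLines(apply(txt, 1, paste, collapse = ","), con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- sprintf("%s v1 n=%d truth=%d geom=%s cols=%s\n", LM_MAGIC,
                   nrow(ev), as.integer(set$has_truth),
                   geometry_hash(set$geometry), paste(cols, collapse = ","))
    writeBin(charToRaw(hdr), con)
    for (cl in cols) writeBin(as.numeric(ev[[cl]]), con, size = 8,
                              endian = "little")
  }
  invisible(path)
}

#' Read a list-mode set written by [write_listmode()]
#'
#' The acceptance energy window of `geometry` is re-applied at load; rejected
#' rows are counted in the returned set's provenance.
#'
#' @param path input file.
#' @param geometry the [scanner_geometry()] to attach (and whose acceptance
#'   window to enforce).
#' @param format `"auto"` (sniff the binary magic), `"csv"` or `"binary"`.
#' @return a [listmode_set()].
#' @export
read_listmode <- function(path, geometry, format = c("auto", "csv", "binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    con <- file(path, "rb")
    magic <- rawToChar(readBin(con, "raw", nchar(LM_MAGIC)))
    close(con)
    format <- if (identical(magic, LM_MAGIC)) "binary" else "csv"
  }
  if (format == "csv") {
    ev <- data.table::fread(path, colClasses = "numeric", sep = ",",
                            header = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr_bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0) stop("truncated header in ", path)
      if (b == charToRaw("\n")) break
      hdr_bytes <- c(hdr_bytes, b)
    }
    hdr <- strsplit(rawToChar(hdr_bytes), " ")[[1]]
    if (!identical(hdr[1], LM_MAGIC)) stop("not a petscatter binary list-mode file")
    if (!identical(hdr[2], "v1")) stop("unsupported list-mode format version: ", hdr[2])
    nev <- as.integer(sub("^n=", "", hdr[3]))
    cols <- strsplit(sub("^cols=", "", hdr[6]), ",")[[1]]
    ev <- data.table::as.data.table(
      lapply(setNames(cols, cols),
             function(cl) readBin(con, "numeric", nev, size = 8,
                                  endian = "little")))
  }
  for (cl in intersect(names(ev), c("scatter1", "scatter2", "origin_in_fov")))
    ev[[cl]] <- as.logical(ev[[cl]])
  for (cl in intersect(names(ev), c("block1", "block2", "nscat1", "nscat2",
                                    "source_id")))
    ev[[cl]] <- as.integer(ev[[cl]])
  listmode_set(ev, geometry, provenance = list(file = path))
}

#' Read GATE-style coincidence ASCII output
#'
#' Parses whitespace-delimited coincidence rows. Because GATE column layouts
#' vary by version, the caller supplies 1-based column indices through
#' `column_map`, a named list with entries `x1, y1, z1, e1, x2, y2, z2, e2`
#' and optionally `t1`, `compton_phantom1`, `compton_phantom2`. Global impact
#' positions are converted to block-local coordinates on `geometry`; a
#' positive per-photon phantom-Compton counter marks the photon as scattered.
#'
#' @param path ASCII coincidence file.
#' @param geometry a [scanner_geometry()].
#' @param column_map named list of 1-based column indices (see above).
#' @param energy_unit `"keV"` or `"MeV"` (GATE's native unit).
#' @return a [listmode_set()]; malformed rows are skipped and counted in
#'   `provenance$n_malformed`.
#' @export
read_gate_ascii <- function(path, geometry, column_map,
                            energy_unit = c("keV", "MeV")) {
  energy_unit <- match.arg(energy_unit)
  need <- c("x1", "y1", "z1", "e1", "x2", "y2", "z2", "e2")
  miss <- setdiff(need, names(column_map))
  if (length(miss))
    stop("column_map lacks mandatory entries: ", paste(miss, collapse = ", "))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  maxcol <- max(unlist(column_map))
  ok <- vapply(fields, length, 1L) >= maxcol
  n_malformed <- sum(!ok)
  if (n_malformed > 0) {
    warning(sprintf("skipped %d malformed row(s) in %s", n_malformed, path))
    fields <- fields[ok]
  }
  if (!length(fields)) {
    ev <- data.table::data.table(block1 = integer(), u1 = numeric(),
                                 v1 = numeric(), doi1 = numeric(),
                                 e1 = numeric(), block2 = integer(),
                                 u2 = numeric(), v2 = numeric(),
                                 doi2 = numeric(), e2 = numeric(),
                                 t = numeric())
    return(listmode_set(ev, geometry,
                        provenance = list(file = path,
                                          n_malformed = n_malformed)))
  }
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[seq_len(maxcol)])))
  col <- function(name) m[, column_map[[name]]]
  escale <- if (energy_unit == "MeV") 1000 else 1
  loc1 <- global_to_local(geometry, cbind(col("x1"), col("y1"), col("z1")))
  loc2 <- global_to_local(geometry, cbind(col("x2"), col("y2"), col("z2")))
  ev <- data.table::data.table(
    block1 = loc1$block, u1 = loc1$u, v1 = loc1$v,
    doi1 = pmax(0, pmin(geometry$block_depth, loc1$doi)),
    e1 = col("e1") * escale,
    block2 = loc2$block, u2 = loc2$u, v2 = loc2$v,
    doi2 = pmax(0, pmin(geometry$block_depth, loc2$doi)),
    e2 = col("e2") * escale,
    t = if (!is.null(column_map$t1)) col("t1") else seq_len(nrow(m)) - 1)
  if (!is.null(column_map$compton_phantom1) &&
      !is.null(column_map$compton_phantom2)) {
    ev$nscat1 <- as.integer(col("compton_phantom1"))
    ev$nscat2 <- as.integer(col("compton_phantom2"))
    ev$scatter1 <- ev$nscat1 > 0
    ev$scatter2 <- ev$nscat2 > 0
  }
  listmode_set(ev, geometry,
               provenance = list(file = path, n_malformed = n_malformed))
}

#' Does a set carry ground-truth scatter labels?
#' @param set a [listmode_set()].
#' @export
has_truth <- function(set) isTRUE(set$has_truth)

#' Per-event "scattered coincidence" truth flag
#'
#' A coincidence counts as scattered when at least one of its photons
#' Compton-scattered in the phantom.
#' @param set a labeled [listmode_set()].
#' @export
truth_scattered <- function(set) {
  if (!has_truth(set)) stop("list-mode set has no truth labels")
  set$events$scatter1 | set$events$scatter2
}
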