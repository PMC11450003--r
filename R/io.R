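# trace and configuration I/O (plain-text formats)

#' Write surface traces to CSV
#'
#' Column 1 is time in s; remaining columns hold one trace per position,
#' with the header carrying the positions in m (`x_<metres>`). Values are
#' written with 15 significant digits, so a round trip is exact to better
#' than 1e-12 relative.
#'
#' @param path Output file.
#' @param x A [scan_dataset()] or a `surface_record` (its pressure /
#'   velocity is written; see `field`).
#' @param field For a `surface_record`: `"u"` or `"d"`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(path, x, field = c("u", "d")) {
  if (inherits(x, "surface_record")) {
    field <- match.arg(field)
    tr <- x[[field]]; time <- x$time; pos <- x$x
  } else if (inherits(x, "scan_dataset")) {
    tr <- x$pressure; time <- x$time; pos <- x$positions
  } else stop("x must be a surface_record or scan_dataset")
  df <- data.frame(time = time, tr)
  names(df) <- c("time", sprintf("x_%.15g", pos))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  mat <- vapply(df, function(col) sprintf("%.15g", col),
                character(nrow(df)))
  writeLines(apply(matrix(mat, nrow(df)), 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read surface traces from CSV
#'
#' Inverse of [write_traces()]; returns a [scan_dataset()].
#'
#' @param path CSV file with a `time` column and `x_<position>` columns.
#' @param cutoff,c0 Passed to [scan_dataset()] for the pitch warning.
#' @return A `scan_dataset`.
#' @export
read_traces <- function(path, cutoff = 5e6, c0 = 1020) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("truncated trace file: no data rows")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "time" || length(header) < 2 ||
      !all(grepl("^x_", header[-1])))
    stop("malformed trace header: expected 'time,x_<pos>,...'")
  ncols <- length(header)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(rows) != ncols)
  if (length(bad) > 0)
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad[1] + 1L, lengths(rows)[bad[1]], ncols))
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = ncols, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in trace file")
  pos <- as.numeric(sub("^x_", "", header[-1]))
  scan_dataset(pos, m[, 1], m[, -1, drop = FALSE],
               cutoff = cutoff, c0 = c0)
}

#' Write / read a medium definition (CSV maps plus a YAML header)
#'
#' The sound-speed and density maps go to `<stem>_c.csv` and
#' `<stem>_rho.csv` (plain numeric CSV, rows = depth); the grid spacing
#' and boundary specification to `<stem>.yaml`.
#'
#' @param medium A `pa_medium`.
#' @param stem Path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_medium <- function(medium, stem) {
  stopifnot(inherits(medium, "pa_medium"))
  write.table(medium$c_map, paste0(stem, "_c.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(medium$rho_map, paste0(stem, "_rho.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(dx = medium$dx, thickness = medium$thickness,
                        sponge_cells = medium$sponge_cells,
                        boundary = medium$boundary), paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_medium
#' @export
read_medium <- function(stem) {
  meta <- yaml::read_yaml(paste0(stem, ".yaml"))
  c_map <- as.matrix(read.csv(paste0(stem, "_c.csv"), header = FALSE))
  rho_map <- as.matrix(read.csv(paste0(stem, "_rho.csv"), header = FALSE))
  dimnames(c_map) <- dimnames(rho_map) <- NULL
  nz <- nrow(c_map); nx <- ncol(c_map)
  x <- (seq_len(nx) - 1) * meta$dx
  x <- x - x[meta$sponge_cells + 1] -
    (nx - 1 - 2 * meta$sponge_cells) * meta$dx / 2
  structure(list(nx = nx, nz = nz, dx = meta$dx, c_map = c_map,
                 rho_map = rho_map, x = x,
                 z = (seq_len(nz) - 1) * meta$dx,
                 sponge_cells = as.integer(meta$sponge_cells),
                 boundary = meta$boundary, phantom = NULL,
                 thickness = meta$thickness),
            class = "pa_medium")
}

#' Write / read a triggered I/Q record as CSV
#'
#' Columns: `time`, then `i_<k>`, `q_<k>` per segment. The sampling rate is
#' recovered from the time column on read.
#'
#' @param path CSV file.
#' @param record An `iq_record`.
#' @return `path` (write) or an `iq_record` (read).
#' @export
write_iq_record <- function(path, record) {
  stopifnot(inherits(record, "iq_record"))
  n <- nrow(record$i); ns <- ncol(record$i)
  m <- cbind((seq_len(n) - 1) / record$fs, record$i, record$q)
  hdr <- c("time", sprintf("i_%d", seq_len(ns)), sprintf("q_%d", seq_len(ns)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  txt <- apply(matrix(sprintf("%.15g", m), n), 1, paste, collapse = ",")
  writeLines(txt, con)
  invisible(path)
}

#' @rdname write_iq_record
#' @export
read_iq_record <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "time"))
    stop("malformed I/Q record: first column must be 'time'")
  i_cols <- grep("^i_", names(df)); q_cols <- grep("^q_", names(df))
  if (length(i_cols) == 0 || length(i_cols) != length(q_cols))
    stop("malformed I/Q record: need matching i_/q_ columns")
  fs <- 1 / mean(diff(df$time))
  structure(list(i = as.matrix(df[i_cols]), q = as.matrix(df[q_cols]),
                 fs = fs, trigger_times = NULL, model = NULL, seed = NULL),
            class = "iq_record")
}
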