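# Ensemble files are plain CSV with a versioned comment header so any
# solver export can be converted without proprietary readers.

ensemble_format_version <- "dtemu-ensemble v1"
ensemble_units_line <- "units: SI (t s; x,y,z m; stresses Pa)"

#' Write a trajectory ensemble to CSV
#'
#' Columns are written in the canonical order
#' `traj_id,t,x,y,z,sxx,syy,szz,sxy,sxz,syz[,rxx,ryy,rzz,rxy,rxz,ryz]`
#' under a two-line `#` comment header declaring the format version and SI
#' units. Values round-trip losslessly through [read_ensemble()].
#'
#' @inheritParams check_ensemble
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  ensemble <- check_ensemble(ensemble)
  cols <- c(coord_cols, viscous_cols)
  if (all(reynolds_cols %in% names(ensemble))) cols <- c(cols, reynolds_cols)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("# ", ensemble_format_version),
               paste0("# ", ensemble_units_line)), con)
  readr::write_csv(ensemble[cols], con, append = FALSE, col_names = TRUE)
  invisible(path)
}

#' Read a trajectory ensemble from CSV
#'
#' Reads files produced by [write_ensemble()] (or any CSV with the same
#' header and column layout), validating the format version, the unit
#' declaration, the column set, and strict time monotonicity within each
#' trajectory.
#'
#' @param path Path to an ensemble CSV.
#' @return A validated ensemble tibble.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L || !identical(hdr[1], paste0("# ", ensemble_format_version))) {
    abort(paste0(path, ": missing or unsupported format header (expected '# ",
                 ensemble_format_version, "')"))
  }
  if (!identical(hdr[2], paste0("# ", ensemble_units_line))) {
    abort(paste0(path, ": unit declaration mismatch; expected '# ",
                 ensemble_units_line, "'"))
  }
  # base read.csv parses doubles correctly rounded, so write/read/write is
  # byte-stable; readr's fast path can be off by one ulp
  fields <- utils::count.fields(path, sep = ",", comment.char = "#")
  rows <- which(!is.na(fields) & fields > 0L)    # skip comment/blank lines
  if (length(rows) > 1L && any(fields[rows] != fields[rows[1]])) {
    bad <- rows[fields[rows] != fields[rows[1]]][1]
    abort(paste0(path, ": parse error at line ", bad, ": expected ",
                 fields[rows[1]], " fields, found ", fields[bad]))
  }
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(traj_id = "character"))
  check_ensemble(df)
}
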