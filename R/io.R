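#' Read and write trial tables and cells as CSV
#'
#' The trial dialect has header
#' `participant,lag,t1_correct,t2_correct,visibility,order_error` with
#' booleans coded 0/1; the cells dialect has header
#' `participant,measure,lag,successes,trials`. One file per dataset.
#'
#' @param trials,cells The tibble to write.
#' @param path File path.
#' @param overwrite Allow replacing an existing file?
#' @return The path (writers, invisibly) or the parsed tibble (readers).
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
write_trials_csv <- function(trials, path, overwrite = FALSE) {
  check_trials(trials)
  if (file.exists(path) && !overwrite) {
    abort(paste0("File exists (set overwrite = TRUE): ", path))
  }
  out <- mutate(as_tibble(trials),
                across(c("t1_correct", "t2_correct", "order_error"),
                       as.integer))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_trials_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant = readr::col_character(),
      lag = readr::col_integer(),
      t1_correct = readr::col_integer(),
      t2_correct = readr::col_integer(),
      visibility = readr::col_integer(),
      order_error = readr::col_integer()
    )
  )
  out <- mutate(raw,
                across(c("t1_correct", "t2_correct", "order_error"),
                       ~ .x == 1L))
  check_trials(out)
  out
}

#' @rdname csv_io
#' @export
write_cells_csv <- function(cells, path, overwrite = FALSE) {
  check_cells(cells)
  if (file.exists(path) && !overwrite) {
    abort(paste0("File exists (set overwrite = TRUE): ", path))
  }
  readr::write_csv(
    cells[c("participant", "measure", "lag", "successes", "trials")], path)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_cells_csv <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant = readr::col_character(),
      measure = readr::col_character(),
      lag = readr::col_integer(),
      successes = readr::col_integer(),
      trials = readr::col_integer()
    )
  )
  check_cells(out)
  out
}
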