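#' Construct a PM plate
#'
#' A plate holds the well-by-time signal matrix of one array together
#' with its experimental metadata (the two factor levels and the
#' replicate index).
#'
#' @param array_id identifier of the array (coerced to character).
#' @param times numeric vector of observation times in hours; strictly
#'   increasing, non-negative, length >= 4.
#' @param signals numeric matrix, one row per well and one column per
#'   time point; row names are well ids such as `"A01"`.
#' @param factor_a,factor_b factor level labels (e.g. temperature and
#'   strain).
#' @param replicate replicate index, integer >= 1.
#' @return an object of class `pm_plate`.
#' @export
pm_plate <- function(array_id, times, signals,
                     factor_a = NA_character_, factor_b = NA_character_,
                     replicate = 1L) {
  times <- as.numeric(times)
  if (length(times) < 4) stop("time grid must have at least 4 points")
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (ncol(signals) != length(times)) {
    stop("signals must have one column per time point")
  }
  if (is.null(rownames(signals))) {
    stop("signals must have well ids as row names")
  }
  if (anyDuplicated(rownames(signals))) stop("well ids must be unique")
  if (any(!is.finite(signals))) {
    stop("missing or non-finite signal values are not supported")
  }
  structure(
    list(
      array_id = as.character(array_id),
      times = times,
      wells = rownames(signals),
      signals = signals,
      factor_a = as.character(factor_a),
      factor_b = as.character(factor_b),
      replicate = as.integer(replicate)
    ),
    class = "pm_plate"
  )
}

#' @export
print.pm_plate <- function(x, ...) {
  cat(sprintf(
    "PM plate '%s' (%s x %s, replicate %d): %d wells, %d time points [%.2f, %.2f] h\n",
    x$array_id, x$factor_a, x$factor_b, x$replicate,
    length(x$wells), length(x$times), min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Standard 96-well ids
#'
#' Row letter A-H plus zero-padded column number, `"A01"` ... `"H12"`.
#' @param n_rows,n_cols plate layout (default 8 x 12).
#' @return character vector of well ids in row-major order.
#' @export
well_ids <- function(n_rows = 8, n_cols = 12) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)],
                    sprintf("%02d", seq_len(n_cols)), paste0)))
}

#' Read one plate from a wide CSV
#'
#' The expected dialect is a comma-separated table with a header row
#' `time,A01,...` — one `time` column in decimal hours and one column per
#' well. Missing or non-numeric cells are a hard error: the kinetic
#' models assume a complete time grid.
#'
#' @param file path to the CSV file.
#' @param array_id,factor_a,factor_b,replicate plate metadata (see
#'   [pm_plate()]); `array_id` defaults to the file name without
#'   extension.
#' @return a [pm_plate()].
#' @export
read_plate <- function(file, array_id = NULL,
                       factor_a = NA_character_, factor_b = NA_character_,
                       replicate = 1L) {
  if (!file.exists(file)) stop("plate file not found: ", file)
  if (is.null(array_id)) {
    array_id <- sub("\\.[^.]*$", "", basename(file))
  }
  tab <- tryCatch(
    utils::read.csv(file, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("malformed plate CSV '", file, "': ",
                             conditionMessage(e))
  )
  if (ncol(tab) < 2 || names(tab)[1] != "time") {
    stop("plate CSV '", file, "' must have a 'time' column followed by well columns")
  }
  num <- suppressWarnings(
    vapply(tab, function(col) as.numeric(col), numeric(nrow(tab)))
  )
  if (nrow(tab) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(tab)))
  bad <- which(is.na(num) | tab == "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-numeric or missing value in '%s' at data row %d, column '%s'",
      file, bad[1, 1], names(tab)[bad[1, 2]]
    ))
  }
  signals <- t(num[, -1, drop = FALSE])
  rownames(signals) <- names(tab)[-1]
  pm_plate(array_id, num[, 1], signals,
           factor_a = factor_a, factor_b = factor_b, replicate = replicate)
}

#' Write a plate to a wide CSV
#'
#' Inverse of [read_plate()]: a `time` column followed by one column per
#' well. The round trip `read_plate(write_plate(p))` reproduces the
#' signal matrix exactly (signals are written with full precision).
#'
#' @param plate a [pm_plate()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_plate <- function(plate, file) {
  tab <- data.frame(time = plate$times, t(plate$signals),
                    check.names = FALSE)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Assemble an experiment from plates
#'
#' @param plates list of [pm_plate()] sharing one time grid.
#' @param control length-2 character vector `c(factor_a, factor_b)`
#'   naming the control condition.
#' @return an object of class `pm_experiment`: plates ordered by
#'   (factor_a, factor_b, replicate), common `times`, and the `control`
#'   combination.
#' @export
pm_experiment <- function(plates, control) {
  if (length(plates) == 0) stop("experiment needs at least one plate")
  if (!all(vapply(plates, inherits, logical(1), "pm_plate"))) {
    stop("all elements must be pm_plate objects")
  }
  times <- plates[[1]]$times
  same <- vapply(plates, function(p) {
    length(p$times) == length(times) && all(p$times == times)
  }, logical(1))
  if (!all(same)) {
    stop("plates have mismatched time grids: ",
         paste(vapply(plates[!same], `[[`, "", "array_id"), collapse = ", "))
  }
  ids <- vapply(plates, `[[`, "", "array_id")
  if (anyDuplicated(ids)) stop("duplicate array ids")
  meta <- data.frame(
    array_id = ids,
    factor_a = vapply(plates, `[[`, "", "factor_a"),
    factor_b = vapply(plates, `[[`, "", "factor_b"),
    replicate = vapply(plates, function(p) p$replicate, integer(1)),
    stringsAsFactors = FALSE
  )
  o <- order(meta$factor_a, meta$factor_b, meta$replicate)
  plates <- plates[o]
  meta <- meta[o, , drop = FALSE]
  rownames(meta) <- NULL
  control <- as.character(control)
  if (length(control) != 2) stop("control must be c(factor_a, factor_b)")
  if (!any(meta$factor_a == control[1] & meta$factor_b == control[2])) {
    stop(sprintf("control condition (%s, %s) has no plates",
                 control[1], control[2]))
  }
  names(plates) <- meta$array_id
  structure(
    list(plates = plates, times = times, control = control, meta = meta),
    class = "pm_experiment"
  )
}

#' Read a full experiment from plate CSVs plus a metadata table
#'
#' @param metadata_file CSV with columns `array_id, factor_a, factor_b,
#'   replicate, file`; `file` paths are resolved relative to the
#'   metadata file's directory unless absolute.
#' @param control length-2 character vector naming the control
#'   condition.
#' @return a [pm_experiment()].
#' @export
read_experiment <- function(metadata_file, control) {
  if (!file.exists(metadata_file)) {
    stop("metadata file not found: ", metadata_file)
  }
  meta <- utils::read.csv(metadata_file, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("array_id", "factor_a", "factor_b", "replicate", "file")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  base <- dirname(metadata_file)
  plates <- lapply(seq_len(nrow(meta)), function(i) {
    path <- meta$file[i]
    if (!file.exists(path)) path <- file.path(base, meta$file[i])
    read_plate(path,
               array_id = meta$array_id[i],
               factor_a = meta$factor_a[i], factor_b = meta$factor_b[i],
               replicate = as.integer(meta$replicate[i]))
  })
  pm_experiment(plates, control)
}

#' Subtract a negative-control well
#'
#' Subtracts the control well's profile from every well on the plate,
#' truncating negative differences at zero. The control well itself is
#' retained (and becomes all-zero). Off by default in the pipeline: the
#' downstream stages work with or without background subtraction.
#'
#' @param plate a [pm_plate()].
#' @param control_well_id id of the negative-control well, e.g. `"A01"`.
#' @return the background-subtracted [pm_plate()].
#' @export
subtract_background <- function(plate, control_well_id) {
  if (!control_well_id %in% plate$wells) {
    stop("control well '", control_well_id, "' not on plate '",
         plate$array_id, "'")
  }
  ctrl <- plate$signals[control_well_id, ]
  plate$signals <- pmax(sweep(plate$signals, 2, ctrl, "-"), 0)
  plate
}

#' @export
print.pm_experiment <- function(x, ...) {
  cells <- unique(x$meta[, c("factor_a", "factor_b")])
  cat(sprintf(
    "PM experiment: %d plates, %d conditions, control (%s, %s), %d time points\n",
    length(x$plates), nrow(cells), x$control[1], x$control[2], length(x$times)
  ))
  print(x$meta)
  invisible(x)
}

# Setup = one (factor_a, factor_b) combination. Returns a list of
# character vectors of array ids, one per setup, in meta order.
experiment_setups <- function(experiment) {
  key <- paste(experiment$meta$factor_a, experiment$meta$factor_b, sep = "\r")
  split(experiment$meta$array_id, factor(key, levels = unique(key)))
}
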