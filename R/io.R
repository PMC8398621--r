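fmt_num <- function(x) sprintf("%.17g", x)

#' Write a trial to CSV
#'
#' Pressure dialect: `time_s, ch01..ch10` (kPa). Angle dialect:
#' `time_s, angle_deg`. Values are written with 17 significant digits so a
#' write-then-read round trip is exact.
#'
#' @param trial A [pressure_trial()] or [angle_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  t_axis <- (seq_len(round(trial$duration * trial$sampling_rate)) - 1) /
    trial$sampling_rate
  if (inherits(trial, "pressure_trial")) {
    header <- c("time_s", sprintf("ch%02d", 1:10))
    body <- cbind(t_axis, trial$channels)
  } else if (inherits(trial, "angle_trial")) {
    header <- c("time_s", "angle_deg")
    body <- cbind(t_axis, trial$angle)
  } else stop("not a trial object", call. = FALSE)
  lines <- c(paste(header, collapse = ","),
             apply(body, 1, function(r) paste(fmt_num(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trial from CSV
#'
#' Recognizes the two trial dialects by their header; malformed rows are
#' reported with their line number. Sampling rate is inferred from the time
#' column.
#'
#' @param path CSV file written by [write_trial_csv()].
#' @param subject_id,shoe,speed Optional condition labels to attach.
#' @return A [pressure_trial()] or [angle_trial()].
#' @export
read_trial_csv <- function(path, subject_id = NA_character_,
                           shoe = NA_character_, speed = NA_character_) {
  lines <- readLines(path)
  if (length(lines) < 2)
    stop("parse error in ", path, ": no data rows", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  kind <- if (identical(header, c("time_s", sprintf("ch%02d", 1:10))))
    "pressure"
  else if (identical(header, c("time_s", "angle_deg"))) "angle"
  else stop("parse error in ", path, " at line 1: unrecognized header (",
            length(header) - 1, " data columns)", call. = FALSE)
  nf <- utils::count.fields(path, sep = ",")
  bad <- which(nf != length(header))
  if (length(bad) > 0)
    stop("parse error in ", path, " at line ", bad[1], ": expected ",
         length(header), " fields, found ", nf[bad[1]], call. = FALSE)
  body <- utils::read.csv(path, header = TRUE, colClasses = "numeric")
  rate <- round(1 / median(diff(body$time_s)))
  if (kind == "pressure")
    pressure_trial(unname(as.matrix(body[, -1])), rate, subject_id, shoe,
                   speed)
  else
    angle_trial(body$angle_deg, rate, subject_id, shoe, speed)
}

#' Write a bound cycle table to CSV
#'
#' One row per gait cycle: label columns (subject, shoe, speed, modality,
#' cycle_index) followed by the 100 samples `s000..s099`. Pressure and angle
#' cycles are interleaved as separate rows.
#'
#' @param cycles Bound table from [bind_cycle_pairs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(cycles, path) {
  scol <- sprintf("s%03d", 0:99)
  header <- paste(c("subject", "shoe", "speed", "modality", "cycle_index",
                    scol), collapse = ",")
  row_of <- function(i, modality, mat)
    paste(c(cycles$meta$subject[i], cycles$meta$shoe[i],
            cycles$meta$speed[i], modality, cycles$meta$cycle_index[i],
            fmt_num(mat[i, ])), collapse = ",")
  n <- nrow(cycles$meta)
  lines <- c(header,
             vapply(seq_len(n), row_of, character(1), "pressure",
                    cycles$pressure),
             vapply(seq_len(n), row_of, character(1), "angle", cycles$angle))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cycle table written by [write_cycles_csv()]
#'
#' @param path CSV file path.
#' @return A bound cycle table (list with `pressure`, `angle`, `meta`).
#' @export
read_cycles_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  scol <- sprintf("s%03d", 0:99)
  p <- df[df$modality == "pressure", ]
  a <- df[df$modality == "angle", ]
  list(pressure = unname(as.matrix(p[, scol])),
       angle = unname(as.matrix(a[, scol])),
       meta = data.frame(subject = p$subject, shoe = p$shoe,
                         speed = p$speed, cycle_index = p$cycle_index,
                         stringsAsFactors = FALSE))
}

#' Serialize a trained perceptron to JSON
#'
#' Stores layer sizes, flattened weights and biases, the ELU alpha and the
#' normalization parameters; [read_mlp_json()] restores an identical model.
#'
#' @param model An `mlp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mlp_json <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(layer_sizes = model$layer_sizes,
              W1 = as.numeric(model$W1), b1 = model$b1,
              W2 = as.numeric(model$W2), b2 = model$b2,
              W3 = as.numeric(model$W3), b3 = model$b3,
              elu_alpha = model$elu_alpha,
              norm_input = unclass(model$norm_input),
              norm_target = unclass(model$norm_target),
              trained = model$trained,
              model_id = if (is.null(model$model_id)) NA else model$model_id)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a perceptron serialized by [write_mlp_json()]
#'
#' @param path JSON file path.
#' @return An `mlp_model`.
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- obj$layer_sizes
  m <- init_mlp(1L, layer_sizes = ls, elu_alpha = obj$elu_alpha)
  m$W1 <- matrix(obj$W1, nrow = ls[2]); m$b1 <- obj$b1
  m$W2 <- matrix(obj$W2, nrow = ls[3]); m$b2 <- obj$b2
  m$W3 <- matrix(obj$W3, nrow = ls[4]); m$b3 <- obj$b3
  if (!is.null(obj$norm_input))
    m$norm_input <- structure(obj$norm_input, class = "minmax_params")
  if (!is.null(obj$norm_target))
    m$norm_target <- structure(obj$norm_target, class = "minmax_params")
  m$trained <- isTRUE(obj$trained)
  if (!is.null(obj$model_id) && !is.na(obj$model_id))
    m$model_id <- obj$model_id
  m
}
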