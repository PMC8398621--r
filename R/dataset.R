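# Shoe/speed combinations that define the six models: three shoe-based
# (M1-M3: one shoe, both speeds), two speed-based (M4-M5: all shoes, one
# speed) and the all-condition model M6.
model_conditions <- function(model_id) {
  switch(model_id,
         M1 = list(shoes = "S1", speeds = c("C", "F")),
         M2 = list(shoes = "S2", speeds = c("C", "F")),
         M3 = list(shoes = "S3", speeds = c("C", "F")),
         M4 = list(shoes = c("S1", "S2", "S3"), speeds = "C"),
         M5 = list(shoes = c("S1", "S2", "S3"), speeds = "F"),
         M6 = list(shoes = c("S1", "S2", "S3"), speeds = c("C", "F")),
         stop("unknown model id: ", model_id, call. = FALSE))
}

#' Bind preprocessed cycle pairs into one table
#'
#' @param pair_list List of `cycle_pairs` from [preprocess_trial_pair()].
#' @return List with `pressure` and `angle` matrices (one row per cycle) and
#'   a `meta` data frame (subject, shoe, speed, cycle_index).
#' @export
bind_cycle_pairs <- function(pair_list) {
  list(pressure = do.call(rbind, lapply(pair_list, `[[`, "pressure")),
       angle = do.call(rbind, lapply(pair_list, `[[`, "angle")),
       meta = do.call(rbind, lapply(pair_list, `[[`, "meta")))
}

#' Assemble a training dataset for one model
#'
#' Selects the shoe/speed combinations belonging to `model_id` over the
#' training subjects, fits global min-max normalization parameters for the
#' pressure and angle streams on the selected rows only, and returns the
#' normalized matrices. With 5 training subjects the row counts are 300
#' (M1-M3), 450 (M4-M5) and 900 (M6).
#'
#' @param cycles Bound cycle table from [bind_cycle_pairs()].
#' @param model_id One of "M1".."M6".
#' @param training_subjects Character vector of subject ids to include.
#' @return An object of class `gait_dataset` with normalized `inputs` and
#'   `targets` (rows in \[0, 1\]), row `labels`, the `model_id` and the
#'   fitted `norm_input` / `norm_target` parameters.
#' @export
assemble_dataset <- function(cycles, model_id, training_subjects) {
  cond <- model_conditions(model_id)
  meta <- cycles$meta
  for (subj in training_subjects)
    for (sh in cond$shoes)
      for (sp in cond$speeds)
        if (!any(meta$subject == subj & meta$shoe == sh & meta$speed == sp))
          stop(sprintf("missing condition for %s: subject %s, shoe %s, speed %s",
                       model_id, subj, sh, sp), call. = FALSE)
  keep <- meta$subject %in% training_subjects &
    meta$shoe %in% cond$shoes & meta$speed %in% cond$speeds
  norm_input <- fit_minmax(cycles$pressure[keep, , drop = FALSE])
  norm_target <- fit_minmax(cycles$angle[keep, , drop = FALSE])
  structure(
    list(model_id = model_id,
         inputs = apply_minmax(cycles$pressure[keep, , drop = FALSE],
                               norm_input),
         targets = apply_minmax(cycles$angle[keep, , drop = FALSE],
                                norm_target),
         labels = meta[keep, , drop = FALSE],
         norm_input = norm_input, norm_target = norm_target),
    class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("Dataset %s: %d gait cycles x %d points, %d subjects\n",
              x$model_id, nrow(x$inputs), ncol(x$inputs),
              length(unique(x$labels$subject))))
  invisible(x)
}
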