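#' Write / read the daily participant-day panel
#'
#' The daily panel is exchanged as plain CSV with columns `participant_id`,
#' `study_day`, `week_index`, `arm`, `delivered`, `message_id`, `mood`,
#' `steps`, `sleep_minutes`. Missing values are written as empty fields
#' (never zero). Reading validates integrity: no duplicated
#' (participant, study_day), `week_index == ceiling(study_day / 7)`,
#' deliveries only in active weeks, and non-negative steps/sleep.
#'
#' @param daily Daily panel data frame.
#' @param path CSV path.
#' @return `write_daily_panel`: the path, invisibly. `read_daily_panel`:
#'   the validated daily panel with `day_of_week` recomputed and `arm` as a
#'   factor.
#' @export
write_daily_panel <- function(daily, path) {
  cols <- intersect(c("participant_id", "study_day", "week_index", "arm",
                      "delivered", "message_id", "mood", "steps",
                      "sleep_minutes"), names(daily))
  out <- daily[, cols, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_daily_panel
#' @export
read_daily_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  daily <- utils::read.csv(path, na.strings = "",
                           colClasses = c(message_id = "character"))
  needed <- c("participant_id", "study_day", "week_index", "arm")
  miss <- setdiff(needed, names(daily))
  if (length(miss)) {
    stop("daily panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(daily$participant_id, daily$study_day)
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, study_day) rows", call. = FALSE)
  }
  if (!all(daily$week_index == ceiling(daily$study_day / 7))) {
    stop("week_index inconsistent with study_day", call. = FALSE)
  }
  if (!all(daily$arm %in% ARM_LEVELS)) {
    stop("unknown arm label(s): ",
         paste(setdiff(unique(daily$arm), ARM_LEVELS), collapse = ", "),
         call. = FALSE)
  }
  if ("delivered" %in% names(daily)) {
    daily$delivered <- as.logical(daily$delivered)
    if (any(daily$delivered & daily$arm == "none")) {
      stop("delivery recorded in a no-notification week", call. = FALSE)
    }
  }
  for (col in c("steps", "sleep_minutes")) {
    if (col %in% names(daily) && any(daily[[col]] < 0, na.rm = TRUE)) {
      stop("negative ", col, " values", call. = FALSE)
    }
  }
  daily$arm <- factor(daily$arm, levels = ARM_LEVELS)
  daily$day_of_week <- daily$study_day - (daily$week_index - 1L) * 7L
  daily
}

#' Write / read the weekly analysis panel
#'
#' @param panel A [weekly_panel()] data frame.
#' @param path CSV path.
#' @export
write_weekly_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_weekly_panel
#' @param measure,transform Panel metadata to re-attach on read.
#' @export
read_weekly_panel <- function(path, measure = NULL, transform = NULL) {
  panel <- utils::read.csv(path, na.strings = "")
  panel$arm <- factor(panel$arm, levels = ARM_LEVELS)
  attr(panel, "measure") <- measure
  attr(panel, "transform") <- transform
  class(panel) <- c("week_record", "data.frame")
  panel
}

#' Echo ground-truth parameters to a JSON sidecar
#'
#' @param truth Named list of [truth_params()].
#' @param path JSON path.
#' @param seed Seed to record.
#' @export
write_truth_json <- function(truth, path, seed = NULL) {
  out <- lapply(truth, function(tp) {
    tp <- unclass(tp)
    tp$b0 <- as.list(tp$b0)   # keep category names in the JSON
    tp$b1 <- as.list(tp$b1)
    tp
  })
  if (!is.null(seed)) out$seed <- seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
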