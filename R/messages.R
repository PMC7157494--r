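#' Draw notification messages for a delivery schedule
#'
#' Notifications alternate between the two framing types ("tip" and
#' "insight") within each participant-category stream, starting with a tip.
#' Within each (category, type) bucket, message identifiers are drawn
#' without replacement; once a bucket is emptied it is refilled and a fresh
#' permutation begins. State is carried across weeks, so a participant who
#' is re-randomized to the same category later in the study continues both
#' the alternation and the bucket where they left off.
#'
#' @param schedule Daily schedule from [schedule_daily()] (rows ordered by
#'   participant then study day).
#' @param bucket_sizes Messages per (category, type) bucket.
#' @param seed Integer seed.
#' @return `schedule` with a `message_id` column (`NA` on non-delivery
#'   days), identifiers of the form `"<category>_<type>_<number>"`.
#' @export
draw_messages <- function(schedule, bucket_sizes = 7L, seed = 1L) {
  bucket_sizes <- as.integer(bucket_sizes)
  if (bucket_sizes < 1L) stop("`bucket_sizes` must be >= 1", call. = FALSE)
  ord <- order(schedule$participant_id, schedule$study_day)
  if (any(ord != seq_along(ord))) schedule <- schedule[ord, ]
  message_id <- rep(NA_character_, nrow(schedule))
  idx <- which(schedule$delivered)
  if (length(idx)) {
    grp <- interaction(schedule$participant_id[idx],
                       as.character(schedule$arm[idx]), drop = TRUE)
    withr_seed(seed, "messages", {
      for (g in split(idx, grp)) {
        arm <- as.character(schedule$arm[g[1L]])
        L <- length(g)
        type <- rep(c("tip", "insight"), length.out = L)
        for (ty in c("tip", "insight")) {
          pos <- which(type == ty)
          if (!length(pos)) next
          n_cycles <- ceiling(length(pos) / bucket_sizes)
          ids <- unlist(lapply(seq_len(n_cycles),
                               function(i) sample.int(bucket_sizes)))
          message_id[g[pos]] <- sprintf("%s_%s_%02d", arm, ty,
                                        ids[seq_along(pos)])
        }
      }
    })
  }
  schedule$message_id <- message_id
  schedule
}
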