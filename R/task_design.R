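# Task schedules for the block-design emotional faces paradigm.

TASK_CONDITIONS <- c("sad", "happy", "neutral", "fixation")

#' Construct a task design
#'
#' A task design is an ordered table of non-overlapping stimulus blocks
#' (onset, duration, condition). Conditions are `sad`, `happy`, `neutral`
#' and `fixation`; the fixation rows mark the rest baseline and are ignored
#' when building design matrices.
#'
#' @param onset Numeric vector of block onsets (seconds).
#' @param duration Numeric vector of block durations (seconds).
#' @param condition Character vector of conditions.
#' @param total_duration_s Total run duration; defaults to the end of the last
#'   block.
#' @return A `task_design` object: a data frame with columns `onset`,
#'   `duration`, `condition` and attribute `total_duration_s`.
#' @examples
#' td <- task_design(c(0, 20), c(20, 20), c("neutral", "sad"))
#' @export
task_design <- function(onset, duration, condition, total_duration_s = NULL) {
  stopifnot(length(onset) == length(duration), length(onset) == length(condition))
  if (any(!condition %in% TASK_CONDITIONS))
    stop("unknown condition(s): ",
         paste(setdiff(unique(condition), TASK_CONDITIONS), collapse = ", "))
  if (any(duration <= 0)) stop("block durations must be positive")
  if (any(onset < 0)) stop("block onsets must be non-negative")
  o <- order(onset)
  onset <- onset[o]; duration <- duration[o]; condition <- condition[o]
  ends <- onset + duration
  if (length(onset) > 1L && any(onset[-1L] < ends[-length(ends)] - 1e-9)) {
    bad <- which(onset[-1L] < ends[-length(ends)] - 1e-9)
    stop("overlapping blocks at rows ", paste(bad + 1L, collapse = ", "))
  }
  total <- total_duration_s %||% max(ends)
  if (total < max(ends) - 1e-9)
    stop("total_duration_s shorter than the last block end")
  out <- data.frame(onset = onset, duration = duration,
                    condition = condition, stringsAsFactors = FALSE)
  structure(out, total_duration_s = total,
            class = c("task_design", "data.frame"))
}

#' Build the interleaved faces block schedule
#'
#' Emits the alternating block sequence used by the backward-masking faces
#' task: 9 neutral blocks interleaved with 4 sad and 4 happy blocks
#' (neutral - emotion - neutral - ... - neutral, emotions alternating and the
#' first emotion set by `order_variant`), with a fixation block between every
#' pair of task blocks.
#'
#' @param block_duration_s Duration of each task block (seconds).
#' @param order_variant `"sad_first"` or `"happy_first"` — which emotion leads
#'   the alternation.
#' @param fixation_s Duration of the fixation blocks separating task blocks.
#' @return A [task_design()] with 17 task blocks (9 neutral, 4 sad, 4 happy)
#'   and 16 interleaved fixation blocks.
#' @examples
#' td <- make_task_schedule(20, "sad_first", 10)
#' table(td$condition)
#' @export
make_task_schedule <- function(block_duration_s = 20,
                               order_variant = c("sad_first", "happy_first"),
                               fixation_s = 10) {
  order_variant <- match.arg(order_variant)
  stop_if_not_scalar_pos(block_duration_s, "block_duration_s")
  stop_if_not_scalar_pos(fixation_s, "fixation_s")
  emo <- if (order_variant == "sad_first") c("sad", "happy") else c("happy", "sad")
  emotions <- rep(emo, 4L)                  # 8 emotion blocks, alternating
  conds <- character(0)
  for (i in seq_len(8L)) conds <- c(conds, "neutral", emotions[i])
  conds <- c(conds, "neutral")              # 17 task blocks
  onset <- numeric(0); duration <- numeric(0); condition <- character(0)
  t <- 0
  for (i in seq_along(conds)) {
    onset <- c(onset, t); duration <- c(duration, block_duration_s)
    condition <- c(condition, conds[i])
    t <- t + block_duration_s
    if (i < length(conds)) {                # fixation between task blocks only
      onset <- c(onset, t); duration <- c(duration, fixation_s)
      condition <- c(condition, "fixation")
      t <- t + fixation_s
    }
  }
  task_design(onset, duration, condition, total_duration_s = t)
}

#' @export
print.task_design <- function(x, ...) {
  tab <- table(factor(x$condition, levels = TASK_CONDITIONS))
  cat(sprintf("Task design: %d blocks (%s), %.0f s total\n", nrow(x),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              attr(x, "total_duration_s")))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more blocks\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a BIDS-style events table
#'
#' @param path Tab-separated file with columns `onset`, `duration`,
#'   `trial_type` (seconds).
#' @param allow_extra_types Keep rows whose `trial_type` is not one of the
#'   known conditions? If `FALSE` (default) unknown types are an error.
#' @return A [task_design()].
#' @export
read_events_tsv <- function(path, allow_extra_types = FALSE) {
  if (!file.exists(path)) stop("events file not found: ", path)
  ev <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events file missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(ev), need)
  if (length(extra))
    warning("ignoring extra events column(s): ", paste(extra, collapse = ", "))
  unknown <- !ev$trial_type %in% TASK_CONDITIONS
  if (any(unknown)) {
    if (!allow_extra_types)
      stop("unknown trial_type(s): ",
           paste(unique(ev$trial_type[unknown]), collapse = ", "))
    ev <- ev[!unknown, , drop = FALSE]
  }
  task_design(ev$onset, ev$duration, ev$trial_type)
}

#' Write a task design as a BIDS-style events table
#'
#' @param design A [task_design()].
#' @param path Output path (tab-separated; columns `onset`, `duration`,
#'   `trial_type`).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  out <- data.frame(onset = design$onset, duration = design$duration,
                    trial_type = design$condition)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
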