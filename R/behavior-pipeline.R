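# Behavioral data backbone: the trial-table CSV dialect, validation,
# preprocessing exactly as specified (fast-RT exclusion, log-RT), baseline
# z-scoring, accuracy measures, and cross-task change correlations.

TRIAL_COLUMNS <- c("participant_id", "session", "condition", "moment",
                   "task", "rt_s", "response", "correct", "reproduction_s",
                   "deadline_s", "missed_deadline")

#' Convert a synthetic study to the flat trial table
#'
#' @param study A [generate_study()] result.
#' @return Data frame in the trial-table dialect (see [write_trials()]),
#'   with a derived `cell` column (`condition:moment`).
#' @export
as_trial_table <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  cellinfo <- design_cells()
  t_cond <- cellinfo$condition[match(study$timing$cell, cellinfo$cell)]
  t_mom <- cellinfo$moment[match(study$timing$cell, cellinfo$cell)]
  timing <- data.frame(
    participant_id = study$timing$participant_id,
    session = study$timing$session,
    condition = t_cond, moment = t_mom, task = "timing",
    rt_s = NA_real_, response = NA_character_, correct = NA_integer_,
    reproduction_s = study$timing$reproduction_s,
    deadline_s = NA_real_, missed_deadline = NA_integer_,
    stringsAsFactors = FALSE)
  c_cond <- cellinfo$condition[match(study$choice$cell, cellinfo$cell)]
  c_mom <- cellinfo$moment[match(study$choice$cell, cellinfo$cell)]
  choice <- data.frame(
    participant_id = study$choice$participant_id,
    session = study$choice$session,
    condition = c_cond, moment = c_mom, task = "choice",
    rt_s = study$choice$rt_s, response = study$choice$response,
    correct = as.integer(study$choice$correct),
    reproduction_s = NA_real_,
    deadline_s = study$choice$deadline_s,
    missed_deadline = as.integer(study$choice$missed_deadline),
    stringsAsFactors = FALSE)
  out <- rbind(timing, choice)
  out$cell <- paste(out$condition, out$moment, sep = ":")
  out
}

validate_trials <- function(df) {
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  errs <- character(0)
  row_err <- function(rows, msg) {
    if (length(rows))
      errs <<- c(errs, paste0("row ", rows, ": ", msg))
  }
  row_err(which(!df$condition %in% c("Neutral", "Warm")),
          "unknown condition label")
  row_err(which(!df$moment %in% c("Baseline", "Begin", "End")),
          "unknown moment label")
  row_err(which(!df$task %in% c("timing", "choice")), "unknown task label")
  row_err(which(!df$session %in% c(1L, 2L)), "session must be 1 or 2")
  ch <- df$task == "choice"
  row_err(which(ch & (is.na(df$rt_s) | df$rt_s <= 0)),
          "choice trial needs rt_s > 0")
  row_err(which(ch & !df$response %in% c("target", "foil")),
          "choice trial needs response target|foil")
  row_err(which(ch & !df$correct %in% c(0L, 1L)),
          "choice trial needs correct 0|1")
  row_err(which(ch & (df$correct == 1L) != (df$response == "target")),
          "correct must equal (response == target)")
  tm <- df$task == "timing"
  row_err(which(tm & (is.na(df$reproduction_s) | df$reproduction_s <= 0)),
          "timing trial needs reproduction_s > 0")
  if (length(errs))
    stop("invalid trial table:\n", paste(utils::head(errs, 20),
                                         collapse = "\n"), call. = FALSE)
  invisible(df)
}

#' Write / read the trial-table CSV dialect
#'
#' UTF-8 CSV with a required header; provenance (for instance the generator
#' seed) is carried in `#`-prefixed comment lines before the header.
#' Reading validates every row and rejects malformed input with row
#' numbers; the round trip through write and read is lossless.
#'
#' @param table Trial table data frame (see [as_trial_table()]).
#' @param path File path.
#' @param provenance Named character vector written as comment lines.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the validated table with a derived `cell` column and a `provenance`
#'   attribute.
#' @export
write_trials <- function(table, path, provenance = character(0)) {
  validate_trials(table)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  utils::write.csv(table[TRIAL_COLUMNS], con, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  prov_lines <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines, comment.char = "#",
                        stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       response = "character"))
  validate_trials(df)
  df$cell <- paste(df$condition, df$moment, sep = ":")
  prov <- sub("^#\\s*", "", prov_lines)
  attr(df, "provenance") <- prov
  df
}

#' Exclude implausibly fast choice responses
#'
#' Removes choice trials with RT strictly below the threshold (default
#' 200 ms, the value used before fitting; "faster than" is read strictly,
#' so an RT of exactly 0.2 s is retained).  Timing trials pass through
#' untouched.
#'
#' @param table Trial table.
#' @param threshold_s Exclusion threshold in seconds (>= 0).
#' @return List with `trials` (filtered table) and `report` (per-participant
#'   counts and exclusion fractions plus totals).
#' @export
filter_fast_rts <- function(table, threshold_s = 0.2) {
  stopifnot(threshold_s >= 0)
  is_choice <- !is.na(table$task) & table$task == "choice"
  fast <- is_choice & !is.na(table$rt_s) & table$rt_s < threshold_s
  ids <- table$participant_id[is_choice]
  excl <- tapply(fast[is_choice], ids, sum)
  tot <- tapply(rep(1L, sum(is_choice)), ids, sum)
  per <- data.frame(participant_id = names(tot),
                    excluded = as.integer(excl[names(tot)]),
                    total = as.integer(tot),
                    row.names = NULL, stringsAsFactors = FALSE)
  per$fraction <- per$excluded / per$total
  list(trials = table[!fast, , drop = FALSE],
       report = list(threshold_s = threshold_s,
                     per_participant = per,
                     n_input = nrow(table),
                     n_excluded = sum(fast),
                     n_retained = nrow(table) - sum(fast)))
}

#' Add natural-log response times
#'
#' @param table Trial table; all choice RTs must be positive.
#' @return The table with a `log_rt_s` column (NA for timing trials); the
#'   original `rt_s` is preserved.
#' @export
log_transform_rts <- function(table) {
  is_choice <- !is.na(table$task) & table$task == "choice"
  if (any(is_choice & (is.na(table$rt_s) | table$rt_s <= 0)))
    stop("non-positive RT; validate the table first")
  table$log_rt_s <- ifelse(is_choice, log(table$rt_s), NA_real_)
  table
}

#' Baseline-relative z-scores of a continuous measure
#'
#' For each participant and session, expresses the in-tub cell means (Begin,
#' End) of the chosen measure as z-scores relative to that session's own
#' out-of-tub Baseline: `z = (cell mean - baseline mean) / baseline SD`.
#' Baseline rows are consumed, not emitted.
#'
#' @param table Trial table (with `log_rt_s` if that measure is requested).
#' @param measure `"reproduction_s"` or `"log_rt_s"`.
#' @return Data frame: `participant_id`, `condition`, `moment` (Begin/End),
#'   `value` (the z-score).
#' @export
baseline_zscore <- function(table, measure = c("reproduction_s", "log_rt_s")) {
  measure <- match.arg(measure)
  task <- if (measure == "reproduction_s") "timing" else "choice"
  df <- table[!is.na(table$task) & table$task == task &
                !is.na(table[[measure]]), ]
  if (!nrow(df)) stop("no trials carry measure ", measure)
  out <- list()
  for (id in unique(df$participant_id)) {
    for (ses in unique(df$session[df$participant_id == id])) {
      sub <- df[df$participant_id == id & df$session == ses, ]
      base <- sub[[measure]][sub$moment == "Baseline"]
      if (length(base) < 2)
        stop("participant ", id, " session ", ses,
             ": needs >= 2 Baseline trials")
      bsd <- stats::sd(base)
      if (bsd == 0)
        stop("participant ", id, " session ", ses,
             ": zero Baseline SD for ", measure)
      bm <- mean(base)
      for (mom in intersect(c("Begin", "End"), sub$moment)) {
        cm <- mean(sub[[measure]][sub$moment == mom])
        out[[length(out) + 1L]] <- data.frame(
          participant_id = id,
          condition = sub$condition[1],
          moment = mom,
          value = (cm - bm) / bsd,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Per-cell accuracy with baseline covariate and change score
#'
#' Choice accuracy per participant and cell; because z-scoring a nominal
#' variable is meaningless, the session's Baseline accuracy is carried as a
#' covariate column and the change from baseline as a difference.
#'
#' @param table Trial table.
#' @return Data frame: `participant_id`, `condition`, `moment` (Begin/End),
#'   `accuracy`, `baseline_accuracy`, `accuracy_change`, `n_trials`,
#'   `missing` (TRUE where a cell had no trials; nothing is imputed).
#' @export
accuracy_measures <- function(table) {
  df <- table[!is.na(table$task) & table$task == "choice", ]
  if (!nrow(df)) stop("no choice trials")
  out <- list()
  for (id in unique(df$participant_id)) {
    for (ses in unique(df$session[df$participant_id == id])) {
      sub <- df[df$participant_id == id & df$session == ses, ]
      base <- sub$correct[sub$moment == "Baseline"]
      base_acc <- if (length(base)) mean(base) else NA_real_
      for (mom in c("Begin", "End")) {
        cc <- sub$correct[sub$moment == mom]
        out[[length(out) + 1L]] <- data.frame(
          participant_id = id,
          condition = sub$condition[1],
          moment = mom,
          accuracy = if (length(cc)) mean(cc) else NA_real_,
          baseline_accuracy = base_acc,
          accuracy_change = if (length(cc) && length(base))
            mean(cc) - base_acc else NA_real_,
          n_trials = length(cc),
          missing = !length(cc),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Correlate baseline-relative changes across tasks or with parameters
#'
#' Pearson correlations between two baseline-relative measures, aligned on
#' participant, condition and moment; reported per condition and pooled.
#' Pairs with zero variance in either variable are reported as undefined,
#' never imputed.
#'
#' @param x,y Data frames with columns `participant_id`, `condition`,
#'   `moment`, `value` (as returned by [baseline_zscore()], or any
#'   baseline-relative parameter change in the same shape).
#' @return Data frame: `grouping` (`Neutral`, `Warm`, `pooled`), `n_pairs`,
#'   `r` (NA when undefined), `defined`.
#' @export
correlate_changes <- function(x, y) {
  key <- function(d) paste(d$participant_id, d$condition, d$moment, sep = "~")
  merged <- merge(
    data.frame(k = key(x), condition = x$condition, vx = x$value),
    data.frame(k = key(y), vy = y$value), by = "k")
  groups <- list(Neutral = merged[merged$condition == "Neutral", ],
                 Warm = merged[merged$condition == "Warm", ],
                 pooled = merged)
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    d <- d[stats::complete.cases(d$vx, d$vy), ]
    n <- nrow(d)
    if (n < 3)
      return(data.frame(grouping = g, n_pairs = n, r = NA_real_,
                        defined = FALSE))
    if (stats::sd(d$vx) == 0 || stats::sd(d$vy) == 0)
      return(data.frame(grouping = g, n_pairs = n, r = NA_real_,
                        defined = FALSE))
    data.frame(grouping = g, n_pairs = n,
               r = stats::cor(d$vx, d$vy), defined = TRUE)
  })
  do.call(rbind, rows)
}

#' Standard preprocessing in fixed order
#'
#' Validate, exclude fast RTs, add log-RTs.  The order is fixed; re-running
#' on its own output is idempotent.  The returned manifest (threshold,
#' counts, data hash) is what downstream fits record to enforce the
#' same-data precondition of model comparison.
#'
#' @param table Trial table.
#' @param threshold_s Fast-RT threshold, seconds.
#' @param drop_late Also drop choice trials slower than their deadline
#'   (default FALSE: late trials are retained in the likelihood with their
#'   observed RTs — in the task the deadline only gated feedback).
#' @return List with `trials` and `manifest`.
#' @export
preprocess_trials <- function(table, threshold_s = 0.2, drop_late = FALSE) {
  validate_trials(table[setdiff(names(table), "cell")])
  flt <- filter_fast_rts(table, threshold_s)
  trials <- flt$trials
  n_late_dropped <- 0L
  if (drop_late) {
    late <- !is.na(trials$task) & trials$task == "choice" &
      !is.na(trials$missed_deadline) & trials$missed_deadline == 1L
    n_late_dropped <- sum(late)
    trials <- trials[!late, , drop = FALSE]
  }
  trials <- log_transform_rts(trials)
  if (!"cell" %in% names(trials))
    trials$cell <- paste(trials$condition, trials$moment, sep = ":")
  list(trials = trials,
       manifest = list(threshold_s = threshold_s,
                       drop_late = drop_late,
                       n_input = flt$report$n_input,
                       n_fast_excluded = flt$report$n_excluded,
                       n_late_dropped = n_late_dropped,
                       n_output = nrow(trials),
                       exclusion_report = flt$report$per_participant,
                       data_hash = hash_trials(
                         trials[!is.na(trials$task) &
                                  trials$task == "choice", ])))
}
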