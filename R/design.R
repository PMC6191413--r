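#' Generate a balanced action-observation trial design
#'
#' Builds one events table per subject for an experiment in which, on
#' two-thirds of trials, participants execute an index or little finger
#' movement and then observe a congruent or incongruent action outcome, and on
#' the remaining third observe a movement without acting (`no_move`).  Trials
#' are balanced so that each run contains equal numbers of congruent,
#' incongruent and no-move trials, and within each condition equal numbers of
#' observed index and little movements.  The judgement task is blocked within
#' a run (first half one task, second half the other); which task comes first
#' alternates across runs and is counterbalanced over subjects.
#'
#' @param n_subjects number of subjects.
#' @param n_runs scanning runs per subject; at least 2 (cross-validation
#'   leaves one run out).
#' @param trials_per_session trials per run; must be divisible by 6 so the
#'   condition thirds and the stimulus balance within condition are integral.
#' @param seed integer seed; the design is a pure function of the arguments.
#' @param iti_range length-2 numeric, uniform jitter range of the
#'   inter-trial interval in seconds.
#' @param trial_dur_s fixed trial duration in seconds added to the jittered
#'   gap between consecutive onsets.
#' @param first_onset_s onset of the first trial in each run, seconds.
#' @return a list with one `event_table` (a `data.frame`) per subject, with
#'   columns `subject_id`, `run`, `trial_index`, `onset_s`, `task`,
#'   `executed`, `observed`, `condition`.  `executed` is `NA` on no-move
#'   trials.
#' @examples
#' d <- make_design(2, n_runs = 8, trials_per_session = 48, seed = 1)
#' table(d[[1]]$run, d[[1]]$condition)
#' @export
make_design <- function(n_subjects, n_runs = 8, trials_per_session = 48,
                        seed = 1, iti_range = c(2, 6), trial_dur_s = 6,
                        first_onset_s = 10) {
  if (trials_per_session %% 6 != 0)
    stop("trials_per_session must be divisible by 6 so that the three ",
         "conditions and the two observed stimuli within each condition ",
         "can be balanced exactly; got ", trials_per_session)
  if (n_runs < 2)
    stop("n_runs must be at least 2: leave-one-run-out cross-validation ",
         "needs a held-out run")
  stopifnot(n_subjects >= 1, length(iti_range) == 2,
            iti_range[1] <= iti_range[2], iti_range[1] >= 0)

  per_cell <- trials_per_session %/% 6   # trials per condition x stimulus
  cells <- expand.grid(condition = CONDITIONS, observed = STIMULI,
                       stringsAsFactors = FALSE)
  base <- cells[rep(seq_len(nrow(cells)), each = per_cell), ]

  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      runs <- lapply(seq_len(n_runs), function(r) {
        trials <- base[make_run_order(base, trials_per_session), ]
        trials$executed <- ifelse(
          trials$condition == "congruent", trials$observed,
          ifelse(trials$condition == "incongruent",
                 other_stimulus(trials$observed), NA_character_))
        # task blocks: subject parity counterbalances which task leads run 1,
        # and the leading task alternates across runs
        first <- TASKS[1 + (s + r) %% 2]
        second <- setdiff(TASKS, first)
        half <- trials_per_session %/% 2
        trials$task <- rep(c(first, second),
                           c(half, trials_per_session - half))
        gaps <- trial_dur_s + runif(trials_per_session - 1,
                                    iti_range[1], iti_range[2])
        data.frame(
          subject_id = sprintf("sub-%02d", s),
          run = r,
          trial_index = seq_len(trials_per_session),
          onset_s = first_onset_s + c(0, cumsum(gaps)),
          task = trials$task,
          executed = trials$executed,
          observed = trials$observed,
          condition = trials$condition,
          stringsAsFactors = FALSE
        )
      })
      out <- do.call(rbind, runs)
      rownames(out) <- NULL
      class(out) <- c("event_table", "data.frame")
      out
    })
  })
}

# Random trial order for one run.  When the count allows it (divisible by 12)
# the shuffle is stratified so each half-run carries half of every
# condition x stimulus cell, keeping the task split estimable; otherwise a
# plain permutation is used.
make_run_order <- function(base, n) {
  if (n %% 12 == 0) {
    cell <- interaction(base$condition, base$observed, drop = TRUE)
    first <- unlist(lapply(split(seq_len(n), cell), function(ix)
      sample(ix, length(ix) %/% 2)))
    c(sample(first), sample(setdiff(seq_len(n), first)))
  } else {
    sample.int(n)
  }
}

EVENT_COLUMNS <- c("subject_id", "run", "trial_index", "onset_s",
                   "task", "executed", "observed", "condition")

#' Validate an events table against the design invariants
#'
#' Checks an events table (from [make_design()], [read_events()], or built by
#' hand) for structural soundness and for the design invariants: unique
#' `(run, trial_index)` keys, strictly increasing onsets within run,
#' condition labels consistent with the executed/observed stimuli
#' (congruent = executed equals observed, incongruent = they differ,
#' no-move = no executed action), equal condition counts per run, and a
#' balanced observed stimulus within each run and condition.
#'
#' Missing required columns are a structural error and are raised as an R
#' error (condition class `popcode_structural_error`); invariant failures are
#' reported in the returned object.  The input is never modified.
#'
#' @param table an events `data.frame`.
#' @return an object of class `events_validation`: a list with `pass`
#'   (logical) and `violations` (character vector naming each violated rule,
#'   with offending rows).
#' @export
validate_events <- function(table) {
  missing <- setdiff(EVENT_COLUMNS, names(table))
  if (length(missing) > 0) {
    stop(structure(class = c("popcode_structural_error", "error", "condition"),
                   list(message = paste("events table lacks required columns:",
                                        paste(missing, collapse = ", ")),
                        call = sys.call())))
  }
  v <- character(0)
  note <- function(...) v <<- c(v, paste0(...))

  bad <- which(!table$condition %in% CONDITIONS)
  if (length(bad)) note("unknown condition labels at rows ",
                        paste(head(bad, 5), collapse = ", "))
  bad <- which(!table$observed %in% STIMULI)
  if (length(bad)) note("unknown observed stimulus at rows ",
                        paste(head(bad, 5), collapse = ", "))
  if (any(table$onset_s < 0, na.rm = TRUE)) note("negative onsets present")

  key <- paste(table$subject_id, table$run, table$trial_index)
  if (anyDuplicated(key))
    note("duplicate (run, trial_index) keys at rows ",
         paste(head(which(duplicated(key)), 5), collapse = ", "))

  for (sr in split(seq_len(nrow(table)),
                   paste(table$subject_id, table$run))) {
    ord <- sr[order(table$trial_index[sr])]
    if (any(diff(table$onset_s[ord]) <= 0))
      note("onsets not strictly increasing in run ", table$run[sr[1]],
           " of ", table$subject_id[sr[1]])
    cc <- table(factor(table$condition[sr], levels = CONDITIONS))
    if (length(unique(as.integer(cc))) != 1)
      note("unequal condition counts in run ", table$run[sr[1]],
           " of ", table$subject_id[sr[1]], " (",
           paste(cc, collapse = "/"), ")")
    for (cond in CONDITIONS) {
      ix <- sr[table$condition[sr] == cond]
      if (length(ix) == 0) next
      sc <- table(factor(table$observed[ix], levels = STIMULI))
      if (sc[1] != sc[2])
        note("observed stimulus unbalanced for ", cond, " in run ",
             table$run[sr[1]], " of ", table$subject_id[sr[1]])
    }
  }

  cong <- table$condition == "congruent"
  bad <- which(cong & (is.na(table$executed) |
                         table$executed != table$observed))
  if (length(bad))
    note("congruent rows with executed != observed: rows ",
         paste(head(bad, 5), collapse = ", "))
  inc <- table$condition == "incongruent"
  bad <- which(inc & (is.na(table$executed) |
                        table$executed == table$observed))
  if (length(bad))
    note("incongruent rows with executed == observed: rows ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(table$condition == "no_move" & !is.na(table$executed))
  if (length(bad))
    note("no_move rows with an executed action: rows ",
         paste(head(bad, 5), collapse = ", "))

  structure(list(pass = length(v) == 0, violations = v),
            class = "events_validation")
}

#' @export
print.events_validation <- function(x, ...) {
  cat(if (x$pass) "events table: PASS\n" else "events table: FAIL\n")
  for (v in x$violations) cat(" -", v, "\n")
  invisible(x)
}

#' Read or write an events table as tab-separated text
#'
#' The on-disk dialect is a TSV with one header row and exactly the columns
#' `subject_id, run, trial_index, onset_s, task, executed, observed,
#' condition`, onsets in seconds; `executed` is empty on no-move trials.
#'
#' @param table an events `data.frame`.
#' @param path file path.
#' @return `read_events` returns an `event_table`; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(table, path) {
  write.table(table[, EVENT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  t <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(EVENT_COLUMNS, names(t))
  if (length(missing) > 0)
    stop("events file lacks required columns: ",
         paste(missing, collapse = ", "))
  class(t) <- c("event_table", "data.frame")
  t
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event table: %d trials, %d subject(s), %d run(s)\n",
              nrow(x), length(unique(x$subject_id)),
              length(unique(x$run))))
  print.data.frame(head(x, 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
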