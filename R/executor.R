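#' Pre-create worker log files with a single actor
#'
#' On Lustre-family file systems every file creation is a metadata-server
#' request, and W workers creating their own logs at launch multiplies into
#' a request storm that can stall a whole machine's MDS. The fix is to have
#' exactly one actor create all W logs before any worker starts; workers
#' then only append. This function is that actor. It is idempotent: existing
#' logs (and anything already appended to them) are preserved.
#'
#' @param worker_count Number of workers (>= 0).
#' @param log_dir Directory for the logs; created if absent.
#' @return Tibble with one row per worker: `worker_id`, `path`, `created`
#'   (`FALSE` when the file already existed).
#' @export
precreate_logs <- function(worker_count, log_dir) {
  stopifnot(is_count(worker_count))
  if (!dir.exists(log_dir) && !dir.create(log_dir, recursive = TRUE, showWarnings = FALSE))
    abort(sprintf("log directory '%s' cannot be created", log_dir),
          class = "worker_startup_error")
  if (file.access(log_dir, 2L) != 0L)
    abort(sprintf("log directory '%s' is not writable", log_dir),
          class = "worker_startup_error")
  ids <- seq_len(worker_count)
  paths <- worker_log_path(log_dir, ids)
  created <- logical(worker_count)
  for (i in ids) {
    if (!file.exists(paths[i])) {
      file.create(paths[i])
      created[i] <- TRUE
    }
  }
  tibble(worker_id = ids, path = paths, created = created)
}

worker_log_path <- function(log_dir, worker_id) {
  file.path(log_dir, sprintf("worker_%d.log", worker_id))
}

#' Execute one array-job unit
#'
#' Runs a unit's command through POSIX `sh` with the array-task context in
#' the environment: `VGE_TASK_ID` (the unit's 1-based task index, the
#' array-job analogue of `SGE_TASK_ID`), `VGE_BASENAME`,
#' `VGE_SUBMISSION_ID` and `VGE_WORKER_ID`. Appends one tab-separated line
#' (timestamp, worker, submission, task index, basename, exit code) to the
#' worker's log, which must already exist (see [precreate_logs()]).
#'
#' @param assignment A list with `submission_id`, `task_index`, `basename`,
#'   `script_path` (the materialized per-submission command script) and
#'   `worker_id`.
#' @param log_path Path to this worker's log file.
#' @param extra_env Named character vector of additional environment
#'   variables for the command.
#' @return A list (execution record): `submission_id`, `task_index`,
#'   `worker_id`, `exit_code`, `t_start`, `t_end`, `log_path`. A script that
#'   cannot be read yields exit code 254 rather than an R error, so a broken
#'   submission still completes and unblocks its pipeline.
#' @export
run_unit <- function(assignment, log_path, extra_env = character()) {
  a <- assignment
  t_start <- now_s()
  if (!is_string(a$script_path) || !file.exists(a$script_path)) {
    code <- 254L  # sentinel: command script could not be materialized
  } else {
    env <- c(
      sprintf("VGE_TASK_ID=%d", as.integer(a$task_index)),
      sprintf("VGE_BASENAME=%s", shQuote(a$basename)),
      sprintf("VGE_SUBMISSION_ID=%d", as.integer(a$submission_id)),
      sprintf("VGE_WORKER_ID=%d", as.integer(a$worker_id)),
      sprintf("R_LIBS=%s", shQuote(paste(.libPaths(), collapse = .Platform$path.sep))),
      extra_env
    )
    code <- suppressWarnings(
      system2("sh", shQuote(a$script_path), env = env,
              stdout = FALSE, stderr = FALSE)
    )
    if (is.null(attr(code, "status")) && length(code) == 0L) code <- 0L
  }
  t_end <- now_s()
  line <- sprintf("%.6f\t%d\t%d\t%d\t%s\t%d", t_end,
                  as.integer(a$worker_id), as.integer(a$submission_id),
                  as.integer(a$task_index), a$basename, as.integer(code))
  try(cat(line, "\n", sep = "", file = log_path, append = TRUE), silent = TRUE)
  list(submission_id = as.integer(a$submission_id),
       task_index = as.integer(a$task_index),
       worker_id = as.integer(a$worker_id),
       exit_code = as.integer(code),
       t_start = t_start, t_end = t_end, log_path = log_path)
}

# --- executors: turn ASSIGN payloads into completion records ----------------
#
# "shell": forks one child per assignment (parallel::mcparallel), so up to
#   worker_count units run concurrently; poll() harvests finished children.
# "instant": completes units synchronously with exit 0 and zero duration —
#   for scheduling studies where only assignment order and counts matter.

new_executor <- function(type = c("shell", "instant")) {
  type <- match.arg(type)
  ex <- new.env(parent = emptyenv())
  ex$type <- type
  ex$jobs <- list()      # pid -> list(payload, job)
  ex$ready <- list()     # completion records not yet collected
  class(ex) <- "vge_executor"
  ex
}

executor_start <- function(ex, payload, log_path) {
  if (ex$type == "instant") {
    t <- now_s()
    ex$ready[[length(ex$ready) + 1L]] <- list(
      submission_id = payload$submission_id, task_index = payload$task_index,
      worker_id = payload$worker_id, exit_code = 0L,
      t_start = t, t_end = t, log_path = log_path)
  } else {
    job <- parallel::mcparallel(run_unit(payload, log_path))
    ex$jobs[[as.character(job$pid)]] <- list(payload = payload, job = job)
  }
  invisible(ex)
}

executor_poll <- function(ex) {
  if (ex$type == "shell" && length(ex$jobs) > 0) {
    jobs <- lapply(ex$jobs, `[[`, "job")
    res <- suppressWarnings(parallel::mccollect(jobs, wait = FALSE))
    for (pid in names(res)) {
      if (is.null(res[[pid]])) next
      rec <- res[[pid]]
      if (!is.list(rec) || inherits(rec, "try-error") || is.null(rec$exit_code)) {
        # child died or errored without a record
        payload <- ex$jobs[[pid]]$payload
        rec <- list(submission_id = payload$submission_id,
                    task_index = payload$task_index,
                    worker_id = payload$worker_id, exit_code = 255L,
                    t_start = now_s(), t_end = now_s(), log_path = NA_character_)
      }
      ex$ready[[length(ex$ready) + 1L]] <- rec
      ex$jobs[[pid]] <- NULL
    }
  }
  out <- ex$ready
  ex$ready <- list()
  out
}

executor_idle <- function(ex) length(ex$jobs) == 0L && length(ex$ready) == 0L
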