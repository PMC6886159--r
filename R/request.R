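#' An array-job submission
#'
#' One call to the engine submits a command together with the number of array
#' elements it should be expanded into — the grid-engine array-job triple:
#' the command (script content or path to an executable script), `max_task`
#' (the number of array jobs) and a `basename` label used for logs and status
#' lookup.
#'
#' @param command_text Shell command text (POSIX `sh`), or the path to an
#'   existing executable script.
#' @param max_task Number of array elements (integer >= 1). Each element
#'   runs the same command with `VGE_TASK_ID` set to its 1-based index.
#' @param basename Non-empty label for logs and status lookup.
#' @param pipeline_id Opaque identifier of the submitting pipeline.
#' @return A list of class `"task_request"`.
#' @export
#' @examples
#' task_request("echo hello", max_task = 4, basename = "greet")
task_request <- function(command_text, max_task, basename,
                         pipeline_id = "default") {
  if (!is_string(command_text) || !nzchar(command_text))
    abort("`command_text` must be a non-empty string",
          class = "task_request_error")
  if (!is_count(max_task, min = 1L))
    abort("`max_task` must be an integer >= 1", class = "task_request_error")
  if (!is_string(basename) || !nzchar(basename))
    abort("`basename` must be a non-empty string",
          class = "task_request_error")
  structure(
    list(
      command_text = command_text,
      max_task = as.integer(max_task),
      basename = basename,
      pipeline_id = as.character(pipeline_id),
      submit_time = NA_real_   # stamped by the engine at registration
    ),
    class = "task_request"
  )
}

#' @export
print.task_request <- function(x, ...) {
  cat(sprintf("<task_request '%s': max_task=%d>\n", x$basename, x$max_task))
  invisible(x)
}

#' Expand a submission into job units
#'
#' Turns one array-job request into its `max_task` independent units, all
#' `PENDING`, with ascending 1-based `task_index`. This is pure: it touches
#' no pool and assigns no worker.
#'
#' @param req A [task_request()].
#' @param submission_id Engine-assigned integer identifier.
#' @param t_submit Registration timestamp (epoch seconds).
#' @return A tibble with one row per unit: `submission_id`, `task_index`,
#'   `state`, `worker_id`, `exit_code`, `t_submit`, `t_assign`, `t_start`,
#'   `t_end`.
#' @export
#' @examples
#' expand_request(task_request("exit 0", 2, "fastq_splitter"), 1L)
expand_request <- function(req, submission_id, t_submit = now_s()) {
  if (!inherits(req, "task_request"))
    abort("`req` must be a task_request", class = "task_request_error")
  n <- req$max_task
  tibble(
    submission_id = as.integer(submission_id),
    task_index = seq_len(n),
    state = "PENDING",
    worker_id = NA_integer_,
    exit_code = NA_integer_,
    t_submit = as.numeric(t_submit),
    t_assign = NA_real_,
    t_start = NA_real_,
    t_end = NA_real_
  )
}

# legal lifecycle edges; anything else is a contract violation
.unit_transitions <- list(
  PENDING = "ASSIGNED",
  ASSIGNED = "RUNNING",
  RUNNING = c("DONE", "FAILED"),
  DONE = character(),
  FAILED = character()
)

#' Unit lifecycle states
#'
#' Units move strictly along `PENDING -> ASSIGNED -> RUNNING -> DONE/FAILED`.
#' `check_transition()` validates one edge and errors (class
#' `"unit_state_error"`) on any other move, including transitions out of a
#' terminal state.
#'
#' @param from,to State names.
#' @return `to`, invisibly, when the edge is legal.
#' @export
check_transition <- function(from, to) {
  ok <- from %in% names(.unit_transitions) && to %in% .unit_transitions[[from]]
  if (!ok)
    abort(sprintf("illegal unit state transition %s -> %s", from, to),
          class = "unit_state_error")
  invisible(to)
}

#' @rdname check_transition
#' @export
unit_states <- function() names(.unit_transitions)
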