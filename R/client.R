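#' Submit an array job and block until it finishes
#'
#' The grid-engine replacement call: submits `command` as an array job of
#' `max_task` elements and **blocks until every element has reached DONE or
#' FAILED**. This blocking is the farm's dependency mechanism — a later
#' `vge_task()` in the same script cannot submit before an earlier one
#' returns, so pipeline stages are ordered simply by the order in which
#' they are written.
#'
#' A failed element does not raise: it is "finished" for dependency
#' purposes, and its nonzero exit code is surfaced in the return value for
#' the caller to act on.
#'
#' @param command Shell command text (POSIX `sh`) or path to an executable
#'   script. Each element runs it with `VGE_TASK_ID` set to its 1-based
#'   index (plus `VGE_BASENAME`, `VGE_SUBMISSION_ID`, `VGE_WORKER_ID`).
#' @param max_task Number of array elements (>= 1).
#' @param basename Label for logs and status lookup.
#' @param endpoint Either a local [vge_engine()] (the in-memory backend) or
#'   a `"host:port"` string for a farm served by [vge_serve()].
#' @param poll_interval Seconds between status polls when `endpoint` is
#'   remote.
#' @param timeout Overall wall-clock bound in seconds.
#' @return A tibble with exactly `max_task` rows: `task_index`, `exit_code`,
#'   `state`, plus the `submission_id` as an attribute.
#' @export
#' @examples
#' eng <- vge_engine(farm_config(worker_count = 2, executor = "instant"))
#' vge_task("exit 0", max_task = 3, basename = "noop", endpoint = eng)
vge_task <- function(command, max_task, basename, endpoint,
                     poll_interval = 0.5, timeout = 3600) {
  if (inherits(endpoint, "vge_engine")) {
    sid <- handle_submit(endpoint, task_request(command, max_task, basename))
    engine_run(endpoint, submission_id = sid, timeout = timeout)
    codes <- submission_exit_codes(endpoint, sid)
    res <- tibble(task_index = seq_len(max_task), exit_code = codes,
                  state = ifelse(codes == 0L, "DONE", "FAILED"))
    attr(res, "submission_id") <- sid
    return(res)
  }
  vge_task_remote(command, max_task, basename, endpoint, poll_interval, timeout)
}

vge_task_remote <- function(command, max_task, basename, endpoint,
                            poll_interval, timeout) {
  con <- vge_connect(endpoint)
  on.exit(close(con), add = TRUE)
  ack <- client_request(con, vge_message("SUBMIT", list(
    command_text = command, max_task = as.integer(max_task),
    basename = basename)))
  if (!is.null(ack$payload$error))
    abort(paste0("submission rejected: ", ack$payload$error),
          class = "vge_submit_rejected")
  sid <- as.integer(ack$payload$submission_id)
  t0 <- now_s()
  repeat {
    rep <- client_request(con, vge_message("STATUS_QUERY",
                                           list(submission_id = sid)))
    p <- rep$payload
    if (!is.null(p$error))
      abort(paste0("engine interrupted wait: ", p$error),
            class = "vge_interrupted")
    if (isTRUE(p$all_done)) {
      codes <- as.integer(unlist(p$exit_codes))
      res <- tibble(task_index = seq_len(max_task), exit_code = codes,
                    state = ifelse(codes == 0L, "DONE", "FAILED"))
      attr(res, "submission_id") <- sid
      return(res)
    }
    if (now_s() - t0 > timeout)
      abort("vge_task timed out waiting for completion", class = "vge_timeout")
    Sys.sleep(poll_interval)
  }
}

#' Low-level client calls
#'
#' @param endpoint `"host:port"` of a running [vge_serve()] farm.
#' @return `vge_connect()`: an open blocking socket connection (caller
#'   closes). `vge_status()`: the status tibble of one submission.
#'   `vge_shutdown()`: the final summary payload from the master.
#' @name vge_client
#' @export
vge_connect <- function(endpoint) {
  parts <- strsplit(endpoint, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    abort("endpoint must be 'host:port'", class = "vge_connect_error")
  tryCatch(
    suppressWarnings(   # socketConnection warns before erroring on refusal
      socketConnection(parts[1], as.integer(parts[2]), blocking = TRUE,
                       open = "a+b", timeout = 30)),
    error = function(e) abort(paste0("engine unreachable at ", endpoint, ": ",
                                     conditionMessage(e)),
                              class = "vge_connect_error")
  )
}

client_request <- function(con, msg) {
  frame_write(con, msg)
  reply <- frame_read(con)
  if (is.null(reply))
    abort("engine closed the connection", class = "vge_interrupted")
  reply
}

#' @rdname vge_client
#' @param submission_id Submission to query.
#' @export
vge_status <- function(endpoint, submission_id) {
  con <- vge_connect(endpoint)
  on.exit(close(con), add = TRUE)
  rep <- client_request(con, vge_message("STATUS_QUERY",
                                         list(submission_id = as.integer(submission_id))))
  p <- rep$payload
  if (!is.null(p$error)) abort(p$error, class = "vge_not_found")
  tibble(submission_id = as.integer(p$submission_id), basename = p$basename,
         max_task = as.integer(p$max_task),
         n_pending = as.integer(p$n_pending),
         n_assigned = as.integer(p$n_assigned),
         n_running = as.integer(p$n_running),
         n_done = as.integer(p$n_done), n_failed = as.integer(p$n_failed),
         all_done = isTRUE(p$all_done))
}

#' @rdname vge_client
#' @export
vge_shutdown <- function(endpoint) {
  con <- vge_connect(endpoint)
  on.exit(close(con), add = TRUE)
  rep <- client_request(con, vge_message("SHUTDOWN"))
  rep$payload
}
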