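#' Engine configuration
#'
#' Builds a validated configuration for a task farm. The defaults suit a
#' desk-scale farm: a handful of workers on the local machine, commands run
#' through POSIX `sh`, and the submission endpoint bound to loopback (the
#' client, the submission endpoint and the master live on the same node, so
#' the engine never listens beyond `127.0.0.1` unless told to).
#'
#' @param worker_count Number of workers (>= 0). Zero is legal and useful for
#'   inspecting pool state without any execution.
#' @param log_dir Directory for worker logs, materialized command scripts and
#'   the run summary. Created (by a single actor) at engine start.
#' @param executor `"shell"` runs each unit's command in a forked POSIX `sh`
#'   so up to `worker_count` units run concurrently; `"instant"` acknowledges
#'   units as done (exit 0) without spawning a shell — for scheduling studies
#'   where the command body is irrelevant.
#' @param host,port Submission endpoint address for the socket backend.
#'   `port = 0` picks a free port at bind time.
#' @param poll_interval Seconds between client-side status polls while
#'   [vge_task()] blocks on a remote engine.
#' @param cycle_interval Seconds the master sleeps between scheduling cycles
#'   when it has nothing to do.
#' @param mds_request_limit Advisory metadata-operation rate limit
#'   (operations/second) for [mds_load_check()]; the default is the commonly
#'   quoted sustainable request rate of a Lustre-family metadata server.
#' @param fail_fast If `TRUE`, the first failed unit of a submission aborts
#'   that submission's still-queued units (they finish as FAILED with exit
#'   code 125).
#'
#' @return A list of class `"farm_config"`.
#' @seealso [read_farm_config()] to load the same fields from a YAML file.
#' @export
#' @examples
#' farm_config(worker_count = 4)
farm_config <- function(worker_count = 2L,
                        log_dir = file.path(tempdir(), "taskfarm"),
                        executor = c("shell", "instant"),
                        host = "127.0.0.1",
                        port = 0L,
                        poll_interval = 0.5,
                        cycle_interval = 0.05,
                        mds_request_limit = 1300,
                        fail_fast = FALSE) {
  executor <- match.arg(executor)
  stopifnot(is_count(worker_count), is_string(log_dir), is_string(host))
  if (!is.numeric(poll_interval) || poll_interval <= 0)
    abort("`poll_interval` must be > 0", class = "farm_config_error")
  if (!is.numeric(cycle_interval) || cycle_interval <= 0)
    abort("`cycle_interval` must be > 0", class = "farm_config_error")
  if (!is.numeric(mds_request_limit) || mds_request_limit <= 0)
    abort("`mds_request_limit` must be > 0", class = "farm_config_error")
  structure(
    list(
      worker_count = as.integer(worker_count),
      log_dir = log_dir,
      executor = executor,
      host = host,
      port = as.integer(port),
      poll_interval = poll_interval,
      cycle_interval = cycle_interval,
      mds_request_limit = mds_request_limit,
      fail_fast = isTRUE(fail_fast)
    ),
    class = "farm_config"
  )
}

#' Read an engine configuration from YAML
#'
#' Unknown keys are rejected rather than ignored, so a typo in a config file
#' fails loudly.
#'
#' @param path Path to a YAML file whose keys are the arguments of
#'   [farm_config()].
#' @param ... Overrides applied on top of the file (e.g. from CLI flags).
#' @return A `"farm_config"` list.
#' @export
read_farm_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(farm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "farm_config_error")
  vals <- modifyList(vals, list(...))
  do.call(farm_config, vals)
}

#' @export
print.farm_config <- function(x, ...) {
  cat("<farm_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}
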