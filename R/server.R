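#' Serve a farm over a loopback socket
#'
#' Runs the master event loop with a TCP submission endpoint: clients
#' connect (e.g. [vge_task()] with `endpoint = "host:port"`), submit, poll
#' status and request shutdown using the same length-prefixed JSON frames
#' used everywhere else. Binds to loopback by default — the pipeline
#' process, the submission endpoint and the master are assumed to share a
#' node. The call blocks until a client sends `SHUTDOWN` (or
#' `max_runtime` elapses); use [launch_farm()] to run it in a background
#' process.
#'
#' @param config A [farm_config()]. `port = 0` picks a free port.
#' @param ready_file If non-`NULL`, the chosen port is written here once the
#'   server is listening (how [launch_farm()] learns the endpoint).
#' @param max_runtime Safety bound in seconds, after which the farm shuts
#'   itself down.
#' @return The final `"vge_summary"`, invisibly.
#' @export
vge_serve <- function(config = farm_config(), ready_file = NULL,
                      max_runtime = Inf) {
  port <- config$port
  if (port == 0L) {
    bound <- bind_free_port(config$host)
    srv <- bound$sock; port <- bound$port
  } else {
    srv <- serverSocket(port)
  }
  on.exit(close(srv), add = TRUE)
  engine <- vge_engine(config)
  if (!is.null(ready_file))
    writeLines(as.character(port), ready_file)
  master_log(engine, "LISTEN\t%s:%d", config$host, port)

  clients <- list()
  t0 <- now_s()
  summary <- NULL
  repeat {
    while (isTRUE(tryCatch(socketSelect(list(srv), timeout = 0),
                           error = function(e) FALSE))) {
      clients[[length(clients) + 1L]] <-
        socketAccept(srv, blocking = TRUE, open = "a+b", timeout = 30)
    }
    drop <- integer()
    if (length(clients) > 0) {
      ready <- socketSelect(clients, timeout = 0)
      for (i in which(ready)) {
        msg <- tryCatch(frame_read(clients[[i]]), error = function(e) NULL)
        if (is.null(msg)) { drop <- c(drop, i); next }
        rep <- dispatch_client(engine, msg)
        tryCatch(frame_write(clients[[i]], rep),
                 error = function(e) drop <<- c(drop, i))
        if (msg$kind == "SHUTDOWN") summary <- attr(rep, "summary")
      }
    }
    if (length(drop) > 0) {
      for (i in drop) try(close(clients[[i]]), silent = TRUE)
      clients <- clients[-drop]
    }
    if (!is.null(summary)) break
    engine_cycle(engine)
    if (now_s() - t0 > max_runtime) {
      summary <- engine_shutdown(engine)
      break
    }
    if (farm_idle(engine)) Sys.sleep(config$cycle_interval)
  }
  for (cl in clients) try(close(cl), silent = TRUE)
  invisible(summary)
}

farm_idle <- function(engine) {
  pool_size(engine$first) == 0L && pool_size(engine$second) == 0L &&
    pool_size(engine$main) == 0L && !any(engine$w_status == "BUSY")
}

dispatch_client <- function(engine, msg) {
  cid <- msg$correlation_id
  if (msg$kind == "SUBMIT") {
    p <- msg$payload
    payload <- tryCatch({
      sid <- handle_submit(engine, task_request(p$command_text,
                                                as.integer(p$max_task),
                                                p$basename))
      list(submission_id = sid)
    }, error = function(e) list(error = conditionMessage(e)))
    return(vge_message("SUBMIT_ACK", payload, cid))
  }
  if (msg$kind == "STATUS_QUERY") {
    payload <- tryCatch({
      s <- query_status(engine, as.integer(msg$payload$submission_id))
      out <- as.list(s)
      if (out$all_done)
        out$exit_codes <- as.list(submission_exit_codes(engine, s$submission_id))
      out
    }, error = function(e) list(error = conditionMessage(e)))
    return(vge_message("STATUS_REPLY", payload, cid))
  }
  if (msg$kind == "SHUTDOWN") {
    summary <- engine_shutdown(engine)
    rep <- vge_message("SHUTDOWN_ACK", list(
      n_units = summary$n_units, n_done = summary$n_done,
      n_failed = summary$n_failed,
      never_assigned = summary$never_assigned), cid)
    attr(rep, "summary") <- summary
    return(rep)
  }
  vge_message("STATUS_REPLY", list(error = sprintf("unexpected kind %s",
                                                   msg$kind)), cid)
}

bind_free_port <- function(host, tries = 50L) {
  for (i in seq_len(tries)) {
    port <- sample(20000:60000, 1L)
    sock <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (!is.null(sock)) return(list(sock = sock, port = port))
  }
  abort("could not bind a free port", class = "vge_connect_error")
}

#' Launch a farm in a background process
#'
#' Starts [vge_serve()] under a fresh R process (via \pkg{callr}) and waits
#' for it to report its port. Stop it with [farm_stop()], which performs a
#' client-side `SHUTDOWN` and reaps the process.
#'
#' @param config A [farm_config()].
#' @param startup_timeout Seconds to wait for the server to start listening.
#' @return A list of class `"vge_farm"` with `endpoint` (`"host:port"`) and
#'   the background `process`.
#' @export
launch_farm <- function(config = farm_config(), startup_timeout = 30) {
  if (!requireNamespace("callr", quietly = TRUE))
    abort("launch_farm() needs the 'callr' package", class = "vge_connect_error")
  ready <- tempfile("farm-port-")
  px <- callr::r_bg(function(cfg, ready_file)
    taskfarm::vge_serve(cfg, ready_file = ready_file, max_runtime = 3600),
    args = list(cfg = config, ready_file = ready))
  t0 <- now_s()
  while (!file.exists(ready) || length(readLines(ready, warn = FALSE)) == 0) {
    if (!px$is_alive())
      abort(paste0("farm process died at startup: ",
                   paste(px$read_all_error_lines(), collapse = "\n")),
            class = "vge_connect_error")
    if (now_s() - t0 > startup_timeout)
      abort("farm did not start in time", class = "vge_connect_error")
    Sys.sleep(0.05)
  }
  port <- as.integer(readLines(ready, warn = FALSE)[1])
  structure(list(endpoint = sprintf("%s:%d", config$host, port),
                 process = px, config = config),
            class = "vge_farm")
}

#' @rdname launch_farm
#' @param farm A `"vge_farm"` handle.
#' @return `farm_stop()` returns the master's final summary payload.
#' @export
farm_stop <- function(farm) {
  out <- tryCatch(vge_shutdown(farm$endpoint), error = function(e) NULL)
  t0 <- now_s()
  while (farm$process$is_alive() && now_s() - t0 < 10) Sys.sleep(0.05)
  if (farm$process$is_alive()) farm$process$kill()
  out
}

#' @export
print.vge_farm <- function(x, ...) {
  cat(sprintf("<vge_farm at %s (%s)>\n", x$endpoint,
              if (x$process$is_alive()) "running" else "stopped"))
  invisible(x)
}
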