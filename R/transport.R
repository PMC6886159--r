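#' In-memory transport
#'
#' A pluggable delivery layer that decouples the engine from its runtime.
#' The in-memory backend gives reliable, ordered, exactly-once delivery of
#' frames between named endpoints inside one R process — the backend every
#' test runs on, and the carrier between the master and its in-process
#' workers. The loopback TCP backend ([vge_serve()] / [vge_task()] with an
#' `endpoint=`) carries the same frames between the client and the master.
#'
#' @param broker A broker created by `mem_transport()`.
#' @param name Endpoint name, unique within the broker.
#' @param role One of `"MASTER"`, `"WORKER"`, `"CLIENT"`. A broker admits
#'   exactly one MASTER.
#' @return `mem_transport()` returns a broker; `transport_endpoint()` an
#'   endpoint handle.
#' @name transport
NULL

#' @rdname transport
#' @export
mem_transport <- function() {
  broker <- new.env(parent = emptyenv())
  broker$queues <- new.env(parent = emptyenv())  # per-endpoint FIFO of (frame, source)
  broker$roles <- list()
  broker$closed <- character()
  class(broker) <- "mem_transport"
  broker
}

#' @rdname transport
#' @export
transport_endpoint <- function(broker, name, role = c("WORKER", "MASTER", "CLIENT")) {
  role <- match.arg(role)
  stopifnot(inherits(broker, "mem_transport"), is_string(name))
  if (!is.null(broker$roles[[name]]))
    abort(sprintf("endpoint '%s' already exists", name),
          class = "transport_error")
  if (role == "MASTER" && any(unlist(broker$roles) == "MASTER"))
    abort("a farm has exactly one MASTER endpoint", class = "transport_error")
  broker$roles[[name]] <- role
  assign(name, list(), envir = broker$queues)
  structure(list(broker = broker, name = name, role = role),
            class = "transport_endpoint")
}

#' Send a frame
#'
#' Delivery on the in-memory backend is immediate, ordered and exactly-once:
#' frames from a given sender to a given receiver are received in send
#' order, never duplicated, never dropped.
#'
#' @param ep The sending endpoint.
#' @param frame Raw vector (one encoded frame).
#' @param dest Name of the destination endpoint.
#' @return Invisibly, a delivery receipt (list with `dest` and queue depth).
#' @export
transport_send <- function(ep, frame, dest) {
  broker <- ep$broker
  if (ep$name %in% broker$closed)
    abort("sending endpoint is closed", class = "transport_closed_error")
  if (is.null(broker$roles[[dest]]))
    abort(sprintf("unknown destination '%s'", dest), class = "transport_error")
  if (dest %in% broker$closed)
    abort(sprintf("destination '%s' is closed", dest),
          class = "transport_error")
  q <- get(dest, envir = broker$queues)
  q[[length(q) + 1L]] <- list(frame = frame, source = ep$name)
  assign(dest, q, envir = broker$queues)
  invisible(list(dest = dest, depth = length(q)))
}

#' Receive the next frame
#'
#' @param ep The receiving endpoint.
#' @param from Optional source filter (endpoint name); frames from other
#'   sources are left queued.
#' @param timeout Seconds to wait. The in-memory backend has no concurrent
#'   producers, so any positive timeout is equivalent to a single check.
#' @return A list with `frame` and `source`, or `NULL` on timeout. Frames
#'   already queued are drained even after the endpoint's peers close; a
#'   `recv` on a closed endpoint with an empty queue errors with class
#'   `"transport_closed_error"`.
#' @export
transport_recv <- function(ep, from = NULL, timeout = 0) {
  broker <- ep$broker
  q <- get(ep$name, envir = broker$queues)
  idx <- 0L
  if (length(q) > 0) {
    if (is.null(from)) idx <- 1L
    else {
      hits <- which(vapply(q, function(m) m$source == from, logical(1)))
      if (length(hits) > 0) idx <- hits[[1L]]
    }
  }
  if (idx == 0L) {
    if (ep$name %in% broker$closed)
      abort("endpoint closed and queue drained", class = "transport_closed_error")
    return(NULL)
  }
  msg <- q[[idx]]
  assign(ep$name, q[-idx], envir = broker$queues)
  msg
}

#' @rdname transport
#' @param ep An endpoint to tear down. Frames already queued to it remain
#'   receivable; new sends to or from it fail.
#' @export
transport_close <- function(ep) {
  ep$broker$closed <- union(ep$broker$closed, ep$name)
  invisible(ep)
}

transport_is_closed <- function(ep) ep$name %in% ep$broker$closed
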