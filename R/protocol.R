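#' Wire messages
#'
#' Every conversation in the farm — client to master submission over a
#' socket, master to worker assignment, completion reports, status polls,
#' shutdown — uses one message schema and one codec. A frame on the wire is
#' a 4-byte big-endian unsigned length prefix followed by a UTF-8 JSON
#' object with exactly the fields `kind`, `correlation_id` and `payload`,
#' keys sorted recursively so a given message always encodes to the same
#' bytes.
#'
#' @param kind One of `SUBMIT`, `SUBMIT_ACK`, `STATUS_QUERY`, `STATUS_REPLY`,
#'   `ASSIGN`, `COMPLETE`, `SHUTDOWN`, `SHUTDOWN_ACK`.
#' @param payload Named list; contents depend on `kind` (a `SUBMIT` carries
#'   `command_text`, `max_task`, `basename`; an `ASSIGN` carries the unit key
#'   and command; a `COMPLETE` carries the unit key, exit code, worker id and
#'   timestamps).
#' @param correlation_id Opaque token echoed in replies.
#' @return `vge_message()` returns a list of class `"vge_message"`.
#' @name protocol
#' @examples
#' m <- vge_message("SUBMIT", list(command_text = "exit 0", max_task = 2L,
#'                                 basename = "fastq_splitter"))
#' identical(vge_decode(vge_encode(m)), m)
NULL

.message_kinds <- c("SUBMIT", "SUBMIT_ACK", "STATUS_QUERY", "STATUS_REPLY",
                    "ASSIGN", "COMPLETE", "SHUTDOWN", "SHUTDOWN_ACK")

#' @rdname protocol
#' @export
vge_message <- function(kind, payload = list(), correlation_id = new_correlation_id()) {
  if (!is_string(kind) || !(kind %in% .message_kinds))
    abort(sprintf("unknown message kind '%s'", format(kind)),
          class = "vge_protocol_error")
  if (!is.list(payload) || (length(payload) > 0 && is.null(names(payload))))
    abort("`payload` must be a named list (or empty)",
          class = "vge_protocol_error")
  if (length(payload) == 0) payload <- list()  # drop empty names attr
  structure(
    list(kind = kind, correlation_id = as.character(correlation_id),
         payload = payload),
    class = "vge_message"
  )
}

new_correlation_id <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    sprintf("c%d-%d", Sys.getpid(), counter)
  }
})

# recursively sort names so encoding is deterministic
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x) > 1L) x <- x[order(names(x))]
    x[] <- lapply(x, canonicalize)
  }
  x
}

#' @rdname protocol
#' @param msg A `vge_message`.
#' @return `vge_encode()` returns a raw vector (one complete frame).
#' @export
vge_encode <- function(msg) {
  if (!inherits(msg, "vge_message"))
    abort("`msg` must be a vge_message", class = "vge_protocol_error")
  fast <- fast_body(msg)
  body <- if (!is.null(fast)) charToRaw(fast) else {
    body_list <- list(correlation_id = msg$correlation_id,
                      kind = msg$kind,
                      payload = canonicalize(msg$payload))
    tryCatch(
      charToRaw(jsonlite::toJSON(body_list, auto_unbox = TRUE, digits = NA,
                                 null = "null")),
      error = function(e) abort(paste0("unencodable payload: ",
                                       conditionMessage(e)),
                                class = "vge_protocol_error")
    )
  }
  n <- length(body)
  prefix <- as.raw(c(bitwAnd(bitwShiftR(n, 24L), 255L),
                     bitwAnd(bitwShiftR(n, 16L), 255L),
                     bitwAnd(bitwShiftR(n, 8L), 255L),
                     bitwAnd(n, 255L)))
  c(prefix, body)
}

# hand-rolled encoding for the common case (flat payload of scalars): the
# per-assignment messages dominate large runs and skip jsonlite's dispatch.
# Produces the same canonical form (sorted keys) as the general path.
fast_body <- function(msg) {
  p <- msg$payload
  if (length(p) > 0) {
    ok <- vapply(p, function(v)
      is.atomic(v) && length(v) == 1L &&
        (is.character(v) || is.integer(v) || is.logical(v) ||
           (is.double(v) && (is.na(v) || is.finite(v)))),
      logical(1))
    if (!all(ok)) return(NULL)
    p <- p[order(names(p))]
    vals <- vapply(seq_along(p), function(i) json_scalar(p[[i]]), "")
    payload <- paste0("{", paste0("\"", json_escape(names(p)), "\":", vals,
                                  collapse = ","), "}")
  } else payload <- "{}"
  paste0("{\"correlation_id\":\"", json_escape(msg$correlation_id),
         "\",\"kind\":\"", msg$kind, "\",\"payload\":", payload, "}")
}

json_scalar <- function(v) {
  if (is.na(v)) return("null")
  if (is.character(v)) return(paste0("\"", json_escape(v), "\""))
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.integer(v)) return(as.character(v))
  if (v == floor(v) && abs(v) < 2^53) return(sprintf("%.0f", v))
  sprintf("%.17g", v)  # round-trips any finite double
}

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  gsub("\t", "\\t", s, fixed = TRUE)
}

frame_length <- function(prefix) {
  sum(as.integer(prefix) * c(16777216, 65536, 256, 1))
}

#' @rdname protocol
#' @param frame A raw vector holding exactly one complete frame.
#' @return `vge_decode()` returns the `vge_message` the frame encodes.
#' @export
vge_decode <- function(frame) {
  if (!is.raw(frame) || length(frame) < 4L)
    abort("truncated frame: missing length prefix", class = "vge_framing_error")
  n <- frame_length(frame[1:4])
  if (length(frame) - 4L < n)
    abort(sprintf("truncated frame: prefix says %d body bytes, got %d",
                  n, length(frame) - 4L),
          class = "vge_framing_error")
  if (length(frame) - 4L > n)
    abort("trailing bytes after frame body (use vge_decode_stream for concatenated frames)",
          class = "vge_framing_error")
  parse_body(frame[seq.int(5L, length.out = n)])
}

parse_body <- function(body) {
  obj <- tryCatch(
    jsonlite::fromJSON(rawToChar(body), simplifyVector = FALSE),
    error = function(e) abort(paste0("malformed frame body: ", conditionMessage(e)),
                              class = "vge_decode_error")
  )
  if (!is.list(obj) || !all(c("kind", "correlation_id", "payload") %in% names(obj)))
    abort("frame body lacks kind/correlation_id/payload",
          class = "vge_decode_error")
  if (!is_string(obj$kind) || !(obj$kind %in% .message_kinds))
    abort(sprintf("unknown message kind '%s'", format(obj$kind)),
          class = "vge_decode_error")
  vge_message(obj$kind, canonicalize(obj$payload), obj$correlation_id)
}

#' Decode a byte stream of concatenated frames
#'
#' Frames are self-delimiting, so any concatenation of complete frames
#' splits back into the same message sequence in order.
#'
#' @param bytes Raw vector of zero or more complete frames.
#' @return List of `vge_message`s.
#' @export
vge_decode_stream <- function(bytes) {
  msgs <- list()
  while (length(bytes) > 0) {
    if (length(bytes) < 4L)
      abort("truncated stream: dangling length prefix", class = "vge_framing_error")
    n <- frame_length(bytes[1:4])
    if (length(bytes) - 4L < n)
      abort("truncated stream: incomplete final frame", class = "vge_framing_error")
    msgs[[length(msgs) + 1L]] <- parse_body(bytes[seq.int(5L, length.out = n)])
    bytes <- bytes[-seq_len(4L + n)]
  }
  msgs
}

# --- frame I/O on connections (socket backend) ------------------------------

frame_write <- function(con, msg) {
  writeBin(vge_encode(msg), con)
  flush(con)
  invisible(msg)
}

# read one frame from a blocking connection; NULL on clean EOF before any byte
frame_read <- function(con) {
  prefix <- read_exact(con, 4L, allow_eof = TRUE)
  if (is.null(prefix)) return(NULL)
  n <- frame_length(prefix)
  parse_body(read_exact(con, n))
}

read_exact <- function(con, n, allow_eof = FALSE) {
  if (n == 0L) return(raw())
  buf <- raw()
  while (length(buf) < n) {
    got <- readBin(con, "raw", n - length(buf))
    if (length(got) == 0L) {
      if (allow_eof && length(buf) == 0L) return(NULL)
      abort("connection closed mid-frame", class = "vge_framing_error")
    }
    buf <- c(buf, got)
  }
  buf
}
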