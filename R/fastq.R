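#' Generate synthetic FASTQ reads
#'
#' Writes deterministic random reads in strict 4-line FASTQ. Defaults match
#' the shape of a short-read whole-genome sequencing run: 152 bp,
#' paired-end. Paired output yields `<prefix>_R1.fastq` / `<prefix>_R2.fastq`
#' with identical record counts and mate-consistent identifiers
#' (`@<prefix>.<i>/1` and `@<prefix>.<i>/2`). The same seed always produces
#' byte-identical files.
#'
#' Only the data's *shape* is emulated: bases are i.i.d. uniform and
#' qualities i.i.d. over a plausible Phred range, so these reads have no
#' genome, no error profile and no duplicate structure — they exist to feed
#' the splitter and a pluggable aligner command, not to benchmark aligners.
#'
#' @param n_reads Number of records per file (>= 0).
#' @param read_len Bases per read (>= 1).
#' @param paired Write two mate files instead of one.
#' @param seed Integer seed; the generator uses its own RNG stream and does
#'   not disturb the caller's.
#' @param out_dir Output directory (created if needed).
#' @param prefix File and read-identifier prefix.
#' @return Tibble with one row per file: `mate`, `path`, `n_records`.
#' @export
#' @examples
#' generate_fastq(10, seed = 1, out_dir = tempfile("fq"))
generate_fastq <- function(n_reads, read_len = 152L, paired = TRUE, seed = 1L,
                           out_dir = ".", prefix = "sample") {
  stopifnot(is_count(n_reads), is_count(read_len, min = 1L), is_count(seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mates <- if (paired) 1:2 else 1L
  paths <- file.path(out_dir, if (paired)
    sprintf("%s_R%d.fastq", prefix, mates) else sprintf("%s.fastq", prefix))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  quals <- strsplit(rawToChar(as.raw(33 + 20:40)), "")[[1]]  # Phred 20-40
  for (m in seq_along(mates)) {
    if (n_reads == 0) { writeLines(character(), paths[m]); next }
    seqs <- vapply(seq_len(n_reads), function(i)
      paste(sample(bases, read_len, replace = TRUE), collapse = ""), "")
    qual <- vapply(seq_len(n_reads), function(i)
      paste(sample(quals, read_len, replace = TRUE), collapse = ""), "")
    ids <- if (paired) sprintf("@%s.%d/%d", prefix, seq_len(n_reads), mates[m])
           else sprintf("@%s.%d", prefix, seq_len(n_reads))
    lines <- character(4L * n_reads)
    lines[seq(1, by = 4, length.out = n_reads)] <- ids
    lines[seq(2, by = 4, length.out = n_reads)] <- seqs
    lines[seq(3, by = 4, length.out = n_reads)] <- "+"
    lines[seq(4, by = 4, length.out = n_reads)] <- qual
    writeLines(lines, paths[m])
  }
  tibble(mate = mates, path = paths, n_records = n_reads)
}

#' Balanced record-aligned chunk plan
#'
#' Distributes `total_records` over `n_chunks` so counts differ by at most
#' one and earlier chunks are never smaller than later ones
#' (`floor`/`ceiling` split, remainders to the front).
#'
#' @param total_records Record count (>= n_chunks; empty chunks are
#'   refused).
#' @param n_chunks Number of chunks (>= 1).
#' @return Tibble: `chunk`, `n_records`, `first_record`, `last_record`.
#' @export
#' @examples
#' chunk_plan(10, 3)  # 4, 3, 3
chunk_plan <- function(total_records, n_chunks) {
  stopifnot(is_count(total_records), is_count(n_chunks, min = 1L))
  if (total_records < n_chunks)
    abort(sprintf("cannot split %d record(s) into %d non-empty chunks",
                  total_records, n_chunks),
          class = "fastq_split_error")
  base <- total_records %/% n_chunks
  extra <- total_records %% n_chunks
  counts <- rep(base, n_chunks) + as.integer(seq_len(n_chunks) <= extra)
  last <- cumsum(counts)
  tibble(chunk = seq_len(n_chunks), n_records = counts,
         first_record = last - counts + 1L, last_record = last)
}

#' Split a FASTQ file into record-aligned chunks
#'
#' The scatter step of the demo pipeline: cuts a strict 4-line FASTQ into
#' `n_chunks` files on record boundaries per [chunk_plan()], so
#' concatenating the chunks in order reproduces the input byte for byte.
#' Splitting the two mate files of a paired run with the same `n_chunks`
#' keeps pairing: chunk *k* of each mate holds the same ordinal record
#' range.
#'
#' @param fastq_path Input FASTQ (uncompressed, 4-line records, no wrapped
#'   sequences — wrapping is rejected, not guessed at).
#' @param n_chunks Number of chunks (>= 1; must not exceed the record
#'   count).
#' @param out_dir Output directory (created if needed).
#' @return Tibble: `chunk`, `path`, `n_records`. Chunk files are named
#'   `<stem>.chunk<k>.fastq` with `k` 1-based and zero-padded to the width
#'   of `n_chunks`.
#' @export
split_fastq <- function(fastq_path, n_chunks, out_dir = dirname(fastq_path)) {
  stopifnot(is_string(fastq_path), is_count(n_chunks, min = 1L))
  lines <- readLines(fastq_path)
  n_rec <- validate_fastq_lines(lines, fastq_path)
  plan <- chunk_plan(n_rec, n_chunks)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.(fastq|fq)$", "", basename(fastq_path))
  width <- nchar(as.character(n_chunks))
  paths <- file.path(out_dir, sprintf("%s.chunk%0*d.fastq", stem, width,
                                      plan$chunk))
  for (i in seq_len(n_chunks)) {
    sel <- seq.int(4L * (plan$first_record[i] - 1L) + 1L,
                   4L * plan$last_record[i])
    writeLines(lines[sel], paths[i])
  }
  tibble(chunk = plan$chunk, path = paths, n_records = plan$n_records)
}

# strict 4-line validation; errors carry the offending line number
validate_fastq_lines <- function(lines, path) {
  n <- length(lines)
  if (n %% 4L != 0L)
    abort(sprintf("%s: %d lines is not a multiple of 4 (truncated record near line %d)",
                  path, n, n), class = "fastq_parse_error")
  n_rec <- n %/% 4L
  if (n_rec == 0L) return(0L)
  id_l <- seq(1, by = 4, length.out = n_rec)
  sep_l <- id_l + 2L
  bad_id <- which(!startsWith(lines[id_l], "@"))
  if (length(bad_id) > 0)
    abort(sprintf("%s: line %d: identifier must start with '@'",
                  path, id_l[bad_id[1]]), class = "fastq_parse_error")
  bad_sep <- which(!startsWith(lines[sep_l], "+"))
  if (length(bad_sep) > 0)
    abort(sprintf("%s: line %d: separator must start with '+' (wrapped sequences are not supported)",
                  path, sep_l[bad_sep[1]]), class = "fastq_parse_error")
  bad_len <- which(nchar(lines[id_l + 1L]) != nchar(lines[id_l + 3L]))
  if (length(bad_len) > 0)
    abort(sprintf("%s: line %d: sequence and quality lengths differ",
                  path, id_l[bad_len[1]] + 3L), class = "fastq_parse_error")
  n_rec
}

#' Count records in a strict 4-line FASTQ
#'
#' @param fastq_path Input FASTQ.
#' @return Integer record count (validates the file as a side effect).
#' @export
count_fastq_records <- function(fastq_path) {
  validate_fastq_lines(readLines(fastq_path), fastq_path)
}
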