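#' Describe one sample for the demo pipeline
#'
#' @param fastq Character vector of one (single-end) or two (paired-end)
#'   FASTQ paths.
#' @param n_chunks Chunks to split each input file into (>= 1). There is no
#'   universal right value: pick roughly a few chunks per worker so the
#'   align stage keeps every worker busy.
#' @param out_dir Directory for chunks and aligner output.
#' @param aligner_cmd Command template run once per chunk, with placeholders
#'   `{input}`, `{output}` and `{task_id}`. The default is a stub that
#'   writes a TSV line (chunk name, record count, checksum) per chunk, so
#'   the whole pipeline runs offline; substitute e.g. a `bwa mem` command
#'   template to align for real. The real aligner is never bundled or
#'   required.
#' @param name Sample label used for submission basenames.
#' @return A list of class `"sample_config"`.
#' @export
sample_config <- function(fastq, n_chunks, out_dir,
                          aligner_cmd = stub_aligner_cmd(), name = "sample") {
  stopifnot(is.character(fastq), length(fastq) %in% 1:2,
            is_count(n_chunks, min = 1L), is_string(out_dir),
            is_string(aligner_cmd), is_string(name))
  missing <- fastq[!file.exists(fastq)]
  if (length(missing) > 0)
    abort(paste0("input FASTQ not found: ", paste(missing, collapse = ", ")),
          class = "pipeline_error")
  structure(list(fastq = fastq, n_chunks = as.integer(n_chunks),
                 out_dir = out_dir, aligner_cmd = aligner_cmd, name = name),
            class = "sample_config")
}

#' @rdname sample_config
#' @export
stub_aligner_cmd <- function() {
  paste0('n=$(($(wc -l < "{input}") / 4)); ',
         'c=$(cksum < "{input}" | cut -d" " -f1); ',
         'printf "%s\\t%s\\t%s\\n" "$(basename "{input}")" "$n" "$c" > "{output}"')
}

#' Run the two-stage split/align pipeline for one sample
#'
#' The demonstration workload: stage 1 (`<name>_fastq_splitter`) is an
#' array job with one element per input file — two elements for a
#' paired-end sample — each splitting one whole file into `n_chunks`
#' record-aligned chunks; stage 2 (`<name>_aligner`) is an array job with
#' one element per chunk, running `aligner_cmd` on it.
#'
#' The only ordering mechanism is that [vge_task()] blocks: stage 2 is not
#' even *submitted* until every stage-1 element has finished, exactly as a
#' pipeline script orders its stages by writing one call after the other.
#'
#' @param config A [sample_config()] (or path to a YAML file of its
#'   fields).
#' @param endpoint A [vge_engine()] or `"host:port"` of a served farm. The
#'   engine must use the `"shell"` executor — the stages do real work.
#' @param fail_fast If any stage-1 element fails, skip stage 2 (default);
#'   otherwise stage 2 runs on whatever chunks exist.
#' @return Tibble with one row per stage: `stage`, `basename`, `max_task`,
#'   `n_ok`, `n_fail`, `elapsed`. Attribute `"chunks"` holds the chunk
#'   manifest tibble.
#' @export
simple_pipeline <- function(config, endpoint, fail_fast = TRUE) {
  if (is_string(config)) {
    vals <- yaml::read_yaml(config)
    config <- do.call(sample_config, vals)
  }
  stopifnot(inherits(config, "sample_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: one array element per input file
  split_manifest <- file.path(cfg$out_dir, sprintf("%s_inputs.txt", cfg$name))
  writeLines(normalizePath(cfg$fastq), split_manifest)
  t0 <- now_s()
  res1 <- vge_task(splitter_script(split_manifest, cfg$n_chunks, cfg$out_dir),
                   max_task = length(cfg$fastq),
                   basename = sprintf("%s_fastq_splitter", cfg$name),
                   endpoint = endpoint)
  t1 <- now_s()
  report <- tibble(stage = "fastq_splitter",
                   basename = sprintf("%s_fastq_splitter", cfg$name),
                   max_task = length(cfg$fastq),
                   n_ok = sum(res1$exit_code == 0L),
                   n_fail = sum(res1$exit_code != 0L),
                   elapsed = t1 - t0)
  if (fail_fast && any(res1$exit_code != 0L)) {
    attr(report, "chunks") <- tibble(chunk = integer(), path = character())
    return(report)
  }

  # stage 2: one array element per chunk produced
  chunk_paths <- sort(list.files(cfg$out_dir, "\\.chunk[0-9]+\\.fastq$",
                                 full.names = TRUE))
  chunk_manifest <- file.path(cfg$out_dir, sprintf("%s_chunks.txt", cfg$name))
  writeLines(normalizePath(chunk_paths), chunk_manifest)
  res2 <- vge_task(aligner_script(chunk_manifest, cfg$aligner_cmd),
                   max_task = length(chunk_paths),
                   basename = sprintf("%s_aligner", cfg$name),
                   endpoint = endpoint)
  t2 <- now_s()
  report <- bind_rows(report, tibble(
    stage = "aligner", basename = sprintf("%s_aligner", cfg$name),
    max_task = length(chunk_paths),
    n_ok = sum(res2$exit_code == 0L), n_fail = sum(res2$exit_code != 0L),
    elapsed = t2 - t1))
  attr(report, "chunks") <- tibble(chunk = seq_along(chunk_paths),
                                   path = chunk_paths)
  report
}

# each array element looks its input up by VGE_TASK_ID in a manifest file,
# so the script is identical for every element of the submission
splitter_script <- function(manifest, n_chunks, out_dir) {
  paste(
    "#!/bin/sh",
    "set -e",
    sprintf('in=$(sed -n "${VGE_TASK_ID}p" %s)', shQuote(manifest)),
    paste0("Rscript -e 'a <- commandArgs(TRUE);",
           " taskfarm::split_fastq(a[[1]], as.integer(a[[2]]), a[[3]])' ",
           sprintf('"$in" %d %s', n_chunks, shQuote(out_dir))),
    sep = "\n")
}

aligner_script <- function(manifest, aligner_cmd) {
  body <- aligner_cmd
  body <- gsub("{input}", "$in", body, fixed = TRUE)
  body <- gsub("{output}", "$out", body, fixed = TRUE)
  body <- gsub("{task_id}", "$VGE_TASK_ID", body, fixed = TRUE)
  paste(
    "#!/bin/sh",
    "set -e",
    sprintf('in=$(sed -n "${VGE_TASK_ID}p" %s)', shQuote(manifest)),
    'out="$in.aln.tsv"',
    body,
    sep = "\n")
}

#' End-to-end demo on synthetic data
#'
#' Generates paired-end samples, starts an in-process farm, runs the
#' split/align pipeline for every sample, and writes the run artifacts
#' (chunks, stub alignments, worker logs, `timeline.tsv`, `summary.tsv`)
#' under `out_dir`.
#'
#' @param n_samples Number of samples.
#' @param n_reads Reads per mate file.
#' @param read_len Read length in bp.
#' @param n_chunks Chunks per input file.
#' @param workers Worker count.
#' @param out_dir Output directory.
#' @param seed Seed for the data generator.
#' @return A list: `reports` (per-sample stage reports), `timeline`
#'   ([vge_timeline]), `summary` (`vge_summary`), `out_dir`.
#' @export
run_demo <- function(n_samples = 2, n_reads = 60, read_len = 152,
                     n_chunks = 3, workers = 4, out_dir = tempfile("demo"),
                     seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eng <- vge_engine(farm_config(worker_count = workers,
                                log_dir = file.path(out_dir, "logs")))
  reports <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    fq <- generate_fastq(n_reads, read_len, paired = TRUE, seed = seed + s - 1,
                         out_dir = file.path(out_dir, sprintf("sample%02d", s)),
                         prefix = sprintf("sample%02d", s))
    cfg <- sample_config(fq$path, n_chunks = n_chunks,
                         out_dir = file.path(out_dir, sprintf("sample%02d", s)),
                         name = sprintf("sample%02d", s))
    reports[[s]] <- simple_pipeline(cfg, eng)
  }
  tl <- engine_timeline(eng)
  timeline_export(tl, file.path(out_dir, "timeline.tsv"))
  summary <- engine_shutdown(eng)
  list(reports = reports, timeline = tl, summary = summary, out_dir = out_dir)
}
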