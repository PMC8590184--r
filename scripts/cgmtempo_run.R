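#!/usr/bin/env Rscript
# Thin command-line wrapper over the cgmtempo package.
#
#   Rscript scripts/cgmtempo_run.R simulate --seed 42 --patients 47 --out dir/
#   Rscript scripts/cgmtempo_run.R run --traces dir/ --metadata meta.csv \
#       [--exclusions ex.csv] [--threshold 3.5] [--max-gap-min 7.5] \
#       [--window 03:00-07:00 ...] [--thresholds 3.9,3.5,3.0] --out outdir/
#
# `simulate` writes one normalized CSV per patient plus metadata.csv and
# ground_truth.json; `run` reads normalized CSVs and writes the full report
# bundle.

suppressPackageStartupMessages(library(cgmtempo))

usage <- function() {
  cat("usage: cgmtempo_run.R <simulate|run> [options]\n")
  quit(status = 2)
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) usage()
cmd <- args[1L]
args <- args[-1L]

getopt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0L) return(default)
  args[i[length(i)] + 1L]
}
getopt_all <- function(flag) {
  i <- which(args == flag)
  if (length(i) == 0L) return(character())
  args[i + 1L]
}

parse_window <- function(txt, label = txt) {
  m <- regmatches(txt, regexec("^(\\d{1,2}):00-(\\d{1,2}):00$", txt))[[1]]
  if (length(m) != 3L) stop("window must look like HH:00-HH:00, got ", txt)
  clock_window(as.integer(m[2]), as.integer(m[3]), label)
}

if (cmd == "simulate") {
  out <- getopt("--out"); if (is.null(out)) usage()
  cfg <- simulation_config(
    n_patients = as.integer(getopt("--patients", "47")),
    window_multiplier = as.numeric(getopt("--multiplier", "2.5")),
    dropout_prob = as.numeric(getopt("--dropout", "0.02")),
    seed = as.integer(getopt("--seed", "1")))
  sim <- simulate_cohort(cfg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (tr in sim$traces) {
    write_cgm_csv(tr, file.path(out, paste0(tr$patient_id, ".csv")))
  }
  write.csv(sim$metadata, file.path(out, "metadata.csv"),
            row.names = FALSE, quote = FALSE)
  truth <- lapply(sim$truth, function(x) {
    x$events$start <- format(x$events$start, "%Y-%m-%dT%H:%M", tz = "UTC")
    x
  })
  jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat("wrote", length(sim$traces), "traces to", out, "\n")
} else if (cmd == "run") {
  tr_dir <- getopt("--traces"); out <- getopt("--out")
  if (is.null(tr_dir) || is.null(out)) usage()
  files <- list.files(tr_dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "metadata.csv"]
  if (length(files) == 0L) stop("no trace CSVs in ", tr_dir)
  traces <- lapply(files, parse_cgm_csv, dialect = "normalized")
  md_path <- getopt("--metadata",
                    if (file.exists(file.path(tr_dir, "metadata.csv")))
                      file.path(tr_dir, "metadata.csv"))
  metadata <- if (!is.null(md_path)) read_metadata(md_path)
  ex_path <- getopt("--exclusions")
  exclusions <- if (!is.null(ex_path)) read_exclusions(ex_path)
  cfg <- detection_config(
    threshold = as.numeric(getopt("--threshold", "3.5")),
    max_gap_minutes = as.numeric(getopt("--max-gap-min", "7.5")))
  win_txt <- getopt_all("--window")
  windows <- if (length(win_txt)) lapply(win_txt, parse_window)
             else list(clock_window(3, 7, "early hours"))
  thresholds <- as.numeric(strsplit(getopt("--thresholds", "3.9,3.5,3.0"),
                                    ",")[[1]])
  run_full_analysis(traces, metadata, exclusions, cfg, windows, thresholds,
                    out_dir = out)
  cat("report bundle written to", out, "\n")
} else usage()
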