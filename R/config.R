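# Run configuration: a flat key = value text file with optional [sections]
# (sections only group keys visually; keys are globally unique). Unknown
# keys are rejected so typos cannot silently fall back to defaults.

RUN_CONFIG_KEYS <- c(
  "lr", "momentum", "weight_decay", "batch_size", "epochs", "alpha", "beta",
  "adversarial_ratio", "corr_lr_mult", "seed", "preset", "attention",
  "subtraction", "use_decouple", "use_corr", "d_a", "s", "b",
  "data_dir", "out_dir", "n_ids", "reps_per_cell", "protocol",
  "augment_train", "image_size", "gain_range", "bias_range", "noise_sigma",
  "rotation_deg", "multiplier", "split")

NUMERIC_KEYS <- c("lr", "momentum", "weight_decay", "batch_size", "epochs",
                  "alpha", "beta", "adversarial_ratio", "corr_lr_mult",
                  "seed", "d_a", "s", "b", "n_ids", "reps_per_cell",
                  "image_size", "gain_range", "bias_range", "noise_sigma",
                  "rotation_deg", "multiplier")
LOGICAL_KEYS <- c("use_decouple", "use_corr", "augment_train")

#' Read a run configuration file
#'
#' Flat `key = value` lines, `#` comments and `[section]` headers allowed;
#' unknown keys are rejected.
#'
#' @param path config file path.
#' @return named list of typed values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[.*\\]$", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% RUN_CONFIG_KEYS) stop("unknown config key: ", key)
    out[[key]] <- parse_config_value(key, val)
  }
  out
}

parse_config_value <- function(key, val) {
  if (key %in% NUMERIC_KEYS) {
    x <- suppressWarnings(as.numeric(val))
    if (is.na(x)) stop("config key ", key, " must be numeric, got: ", val)
    x
  } else if (key %in% LOGICAL_KEYS) {
    if (!tolower(val) %in% c("true", "false", "0", "1"))
      stop("config key ", key, " must be logical, got: ", val)
    tolower(val) %in% c("true", "1")
  } else val
}

# resolved config + seed + package version written next to run outputs
write_run_stamp <- function(dir, values, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "run_config.txt")
  con <- file(path, "wb")
  writeLines(c(
    sprintf("# resolved run configuration"),
    sprintf("# ovineid version %s",
            as.character(utils::packageVersion("ovineid"))),
    sprintf("seed = %d", as.integer(seed)),
    vapply(names(values), function(k)
      sprintf("%s = %s", k, as.character(values[[k]])), "")),
    con, useBytes = TRUE)
  close(con)
  invisible(path)
}

log_event <- function(level, event, ...) {
  extra <- c(...)
  kv <- if (length(extra))
    paste(names(extra), unname(extra), sep = "=", collapse = " ") else ""
  message(sprintf("%s %s %s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, event, kv))
}
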