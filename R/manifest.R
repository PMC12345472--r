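# Dataset manifests: one CSV (plus a JSONL twin) listing every image with its
# identity, age, box and split assignment under one of two protocols.

MANIFEST_COLS <- c("path", "sheep_id", "age_months", "x", "y", "w", "h",
                   "split", "origin")

new_manifest <- function(records, protocol) {
  m <- structure(list(records = records, protocol = protocol),
                 class = "dataset_manifest")
  validate_manifest(m)
  m
}

#' Split counts of a manifest
#' @param m a `dataset_manifest`.
#' @return named integer vector with counts for train/val/test.
#' @export
manifest_counts <- function(m) {
  stopifnot(inherits(m, "dataset_manifest"))
  tab <- table(factor(m$records$split, levels = c("train", "val", "test")))
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.dataset_manifest <- function(x, ...) {
  ct <- manifest_counts(x)
  cat(sprintf("<dataset_manifest> %d records (%s protocol): train=%d val=%d test=%d\n",
              nrow(x$records), x$protocol, ct["train"], ct["val"], ct["test"]))
  invisible(x)
}

validate_manifest <- function(m) {
  r <- m$records
  missing <- setdiff(MANIFEST_COLS, names(r))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  if (!m$protocol %in% c("age_based", "id_based"))
    stop("unknown protocol: ", m$protocol)
  if (nrow(r) == 0) return(invisible(m))
  if (any(r$age_months < 1 | r$age_months > 12))
    stop("age out of range: age_months must be in 1..12")
  if (!all(r$split %in% c("train", "val", "test")))
    stop("unknown split label")
  if (m$protocol == "age_based") {
    ok <- (r$split == "train" & r$age_months <= 4) |
          (r$split == "val" & r$age_months >= 5 & r$age_months <= 8) |
          (r$split == "test" & r$age_months >= 9)
    if (!all(ok))
      stop("age-based split violation: train ages must be 1-4, val 5-8, test 9-12")
  } else {
    sets <- split(r$sheep_id, r$split)
    ids <- lapply(sets, unique)
    if (length(intersect(ids$train, ids$val)) ||
        length(intersect(ids$train, ids$test)) ||
        length(intersect(ids$val, ids$test)))
      stop("id-based split violation: an individual appears in two splits")
  }
  invisible(m)
}

#' Write a manifest as CSV and JSONL
#'
#' Writes `path` (CSV) and its JSONL twin (same basename, `.jsonl`), UTF-8,
#' fixed column order, deterministic bytes.
#'
#' @param m a `dataset_manifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  validate_manifest(m)
  r <- m$records[, MANIFEST_COLS, drop = FALSE]
  con <- file(path, open = "wb")
  writeLines(paste(MANIFEST_COLS, collapse = ","), con, useBytes = TRUE)
  writeLines(sprintf("# protocol: %s", m$protocol), con, useBytes = TRUE)
  if (nrow(r)) {
    lines <- do.call(paste, c(lapply(r, as.character), list(sep = ",")))
    writeLines(lines, con, useBytes = TRUE)
  }
  close(con)
  jpath <- sub("\\.csv$", ".jsonl", path)
  if (identical(jpath, path)) jpath <- paste0(path, ".jsonl")
  jcon <- file(jpath, open = "wb")
  writeLines(sprintf('{"protocol":"%s"}', m$protocol), jcon, useBytes = TRUE)
  if (nrow(r)) {
    for (i in seq_len(nrow(r))) {
      writeLines(jsonlite::toJSON(as.list(r[i, ]), auto_unbox = TRUE), jcon,
                 useBytes = TRUE)
    }
  }
  close(jcon)
  invisible(path)
}

#' Read and validate a manifest
#'
#' Reads the CSV dialect written by [write_manifest()], checks every
#' invariant (column presence, age range, split rules for the protocol) and
#' preserves row order.
#'
#' @param path CSV manifest path.
#' @return a `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  protocol <- "age_based"
  pl <- grep("^# protocol:", lines, value = TRUE)
  if (length(pl)) protocol <- trimws(sub("^# protocol:", "", pl[1]))
  body <- lines[!startsWith(lines, "#")]
  r <- utils::read.csv(text = paste(body, collapse = "\n"),
                       stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(r))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  new_manifest(r[, MANIFEST_COLS, drop = FALSE], protocol)
}

#' Load one split of a generated dataset into memory
#'
#' Reads the PNGs of the requested split into the `H x W x C x N` tensor
#' layout used by the networks.
#'
#' @param m a `dataset_manifest`.
#' @param dir directory the manifest paths are relative to.
#' @param split one of `"train"`, `"val"`, `"test"`, or `"all"` for the
#'   whole cohort.
#' @param crop_to_box crop each image to its face box and resize back to
#'   the frame size before stacking — the standard face-recognition
#'   pipeline (detect, crop, embed). `FALSE` returns raw frames.
#' @return list with `x` (`H x W x 3 x N` array), `sheep_id` (factor),
#'   `age_months` (integer), `box` (`N x 4` matrix), `path` (character).
#' @export
load_split <- function(m, dir, split = c("train", "val", "test", "all"),
                       crop_to_box = TRUE) {
  split <- match.arg(split)
  r <- if (split == "all") m$records
       else m$records[m$records$split == split, , drop = FALSE]
  if (nrow(r) == 0) stop("split '", split, "' is empty")
  first <- png::readPNG(file.path(dir, r$path[1]))
  H <- dim(first)[1]; W <- dim(first)[2]
  x <- array(0, dim = c(H, W, 3, nrow(r)))
  for (i in seq_len(nrow(r))) {
    p <- png::readPNG(file.path(dir, r$path[i]))
    if (length(dim(p)) == 2) p <- array(rep(p, 3), dim = c(dim(p), 3))
    p <- p[, , 1:3, drop = FALSE]
    if (crop_to_box) {
      p <- crop_resize(p, as.numeric(r[i, c("x", "y", "w", "h")]), c(H, W))
    }
    x[, , , i] <- p
  }
  list(x = x, sheep_id = factor(r$sheep_id), age_months = as.integer(r$age_months),
       box = as.matrix(r[, c("x", "y", "w", "h")]), path = r$path)
}

#' Crop an image to a box and resize
#'
#' Bilinear crop-and-resize, the standard preprocessing between face
#' detection and embedding.
#'
#' @param img `H x W x 3` array.
#' @param box `c(x, y, w, h)` in pixels.
#' @param size output `c(H, W)`.
#' @return resized `size[1] x size[2] x 3` array.
#' @export
crop_resize <- function(img, box, size) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x0 <- max(1, box[1]); y0 <- max(1, box[2])
  x1 <- min(W, box[1] + box[3] - 1); y1 <- min(H, box[2] + box[4] - 1)
  crop <- img[y0:y1, x0:x1, , drop = FALSE]
  out <- array(0, c(size[1], size[2], dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- upsample_bilinear(crop[, , ch], size[1], size[2])
  }
  out
}
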