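# Readers and writers: 8-bit PNG/TIFF images, annotation and detection
# CSV (header image_id,x,y with x = column, y = row, 0-based,
# real-valued), versioned checkpoints, YAML experiment configs.

#' Write / read an 8-bit RGB image
#'
#' Format chosen from the file extension (`.png`, `.tif`/`.tiff`).
#' Grayscale images read back are replicated to 3 channels with a warning.
#'
#' @param image `H x W x 3` array with values 0..255.
#' @param path file path.
#' @return `read_image` returns an `H x W x 3` integer array (0..255).
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  u <- image / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(u, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(u, path)
  else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  u <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image extension: ", ext)
  if (length(dim(u)) == 2) {
    warning("grayscale image replicated to 3 channels")
    u <- array(rep(u, 3), c(dim(u), 3))
  }
  if (dim(u)[3] > 3) u <- u[, , 1:3]
  img <- round(u * 255)
  storage.mode(img) <- "integer"
  img
}

#' Read point annotations from CSV
#'
#' Expects a header `image_id,x,y`; `x` is the column index and `y` the
#' row index, 0-based and real-valued. Rows are grouped by `image_id`.
#' Malformed rows are reported with their line numbers; negative
#' coordinates are rejected.
#'
#' @param path CSV file path.
#' @return named list mapping `image_id` to an n x 2 matrix of (row, col)
#'   centers (empty mapping for a header-only file).
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:3], c("image_id", "x", "y")))
    stop("annotation CSV must have header image_id,x,y")
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop("malformed coordinate rows at lines: ",
         paste(bad + 1L, collapse = ", "))
  neg <- which(x < 0 | y < 0)
  if (length(neg))
    stop("negative coordinates at lines: ",
         paste(neg + 1L, collapse = ", "))
  out <- lapply(split(seq_len(nrow(df)), df$image_id), function(i)
    cbind(y[i], x[i]))
  out[unique(df$image_id)]
}

#' Write point annotations or detections to CSV
#'
#' @param centers_by_id named list mapping image_id to an n x 2 matrix of
#'   (row, col) points, or a `detection_set` list with scores.
#' @param path output CSV path.
#' @param scores_by_id optional named list of per-point scores; adds a
#'   `score` column.
#' @return the path, invisibly.
#' @export
write_annotations <- function(centers_by_id, path, scores_by_id = NULL) {
  rows <- list()
  for (id in names(centers_by_id)) {
    m <- as_centers(centers_by_id[[id]])
    if (nrow(m) == 0) next
    r <- data.frame(image_id = id, x = m[, 2], y = m[, 1])
    if (!is.null(scores_by_id)) r$score <- scores_by_id[[id]]
    rows[[length(rows) + 1]] <- r
  }
  df <- if (length(rows)) do.call(rbind, rows)
  else {
    d <- data.frame(image_id = character(0), x = numeric(0),
                    y = numeric(0))
    if (!is.null(scores_by_id)) d$score <- numeric(0)
    d
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

CHECKPOINT_VERSION <- 1L

#' Save / load a network checkpoint
#'
#' A checkpoint stores the weights, the architecture spec, the proximity
#' encoding, and the training seed, under a format version.
#'
#' @param network a `proxi_net`.
#' @param path file path (RDS).
#' @param encoding the [proximity_params()] the network was trained with.
#' @param seed the training seed.
#' @return `load_checkpoint` returns a list with `network`, `encoding`,
#'   `seed`, `version`.
#' @export
save_checkpoint <- function(network, path, encoding = proximity_params(),
                            seed = NA_integer_) {
  stopifnot(inherits(network, "proxi_net"))
  saveRDS(list(version = CHECKPOINT_VERSION, network = network,
               encoding = encoding, seed = seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version > CHECKPOINT_VERSION)
    stop("unsupported checkpoint version")
  ck
}

#' Write a manifest of artifact content hashes
#'
#' @param dir directory whose regular files are hashed (md5).
#' @param path output file (default `manifest.txt` inside `dir`).
#' @return the path, invisibly.
#' @export
write_manifest <- function(dir, path = file.path(dir, "manifest.txt")) {
  files <- setdiff(list.files(dir, recursive = TRUE),
                   basename(path))
  h <- tools::md5sum(file.path(dir, files))
  writeLines(sprintf("%s  %s", unname(h), files), path)
  invisible(path)
}
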