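# Frame-stack file I/O.
#
# Two lossless on-disk forms are supported:
#
#  * "tiff" -- a standard multi-page TIFF (one 8-bit RGB page per frame),
#    with acquisition metadata in a YAML sidecar "<path>.meta.yaml".
#  * "raw"  -- a raw-RGB binary dialect: unsigned 8-bit samples, ordered
#    frame-major (t), then row-major within the frame, channel-interleaved
#    (R, G, B per pixel); geometry and metadata live in the mandatory YAML
#    sidecar "<path>.meta.yaml" (keys: height, width, n_frames, fps,
#    pixel_pitch, subject_id, format).
#
# Lossy video containers are deliberately not read or written here; inputs
# in such formats should be transcoded to multi-page TIFF first.

.sidecar_path <- function(path) paste0(path, ".meta.yaml")

.guess_fmt <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext %in% c("raw", "rgb8", "bin")) "raw"
  else stop("cannot infer format from extension '", ext,
            "'; pass fmt = \"tiff\" or \"raw\"")
}

#' Write a frame stack to disk
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param path output file path.
#' @param fmt \code{"auto"} (infer from extension), \code{"tiff"} or
#'   \code{"raw"}. Both formats are lossless for 8-bit data and both write a
#'   YAML metadata sidecar at \code{<path>.meta.yaml}.
#' @return \code{path}, invisibly.
#' @export
write_frame_stack <- function(stack, path, fmt = c("auto", "tiff", "raw")) {
  fmt <- match.arg(fmt)
  validate_frame_stack(stack)
  if (fmt == "auto") fmt <- .guess_fmt(path)
  d <- dim(stack$frames)
  if (fmt == "tiff") {
    pages <- lapply(seq_len(d[1]), function(t) stack$frames[t, , , ] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else if (fmt == "raw") {
    # channel fastest, then col, then row, then frame
    perm <- aperm(stack$frames, c(4L, 3L, 2L, 1L))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(round(perm)), con)
  } else stop("unknown format: ", fmt)
  yaml::write_yaml(list(format = fmt, n_frames = d[1], height = d[2],
                        width = d[3], fps = stack$fps,
                        pixel_pitch = stack$pixel_pitch,
                        subject_id = as.character(stack$subject_id)),
                   .sidecar_path(path))
  invisible(path)
}

#' Read a frame stack from disk
#'
#' Reads a multi-page TIFF or raw-RGB binary written by
#' \code{\link{write_frame_stack}} (or produced externally in the documented
#' layout). Acquisition metadata is taken from the YAML sidecar when present;
#' otherwise \code{fps} / \code{pixel_pitch} must be supplied.
#'
#' @param path input file path.
#' @param fmt \code{"auto"}, \code{"tiff"} or \code{"raw"}.
#' @param fps,pixel_pitch fall-back metadata when no sidecar exists.
#' @return A \code{\link{frame_stack}}.
#' @export
read_frame_stack <- function(path, fmt = c("auto", "tiff", "raw"),
                             fps = NULL, pixel_pitch = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto") fmt <- .guess_fmt(path)
  side <- .sidecar_path(path)
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  fps <- fps %||% meta$fps
  pixel_pitch <- pixel_pitch %||% meta$pixel_pitch %||% 0.08
  if (is.null(fps))
    stop("fps not found in sidecar metadata and no default supplied")

  if (fmt == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.array(pages)) pages <- list(pages)
    dims <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
    if (length(unique(dims)) != 1L)
      stop("inconsistent frame geometry across TIFF pages")
    frames <- lapply(pages, function(p) round(p * 255))
  } else if (fmt == "raw") {
    need <- c("height", "width", "n_frames")
    if (!all(need %in% names(meta)))
      stop("raw format requires a sidecar with height, width and n_frames")
    nbytes <- meta$n_frames * meta$height * meta$width * 3
    con <- file(path, "rb")
    on.exit(close(con))
    buf <- readBin(con, "raw", n = nbytes + 1L)
    if (length(buf) != nbytes)
      stop("inconsistent frame geometry: file holds ", length(buf),
           " bytes, sidecar implies ", nbytes)
    perm <- array(as.integer(buf), c(3L, meta$width, meta$height, meta$n_frames))
    fr <- aperm(perm, c(4L, 3L, 2L, 1L))
    return(frame_stack(fr, fps = fps, pixel_pitch = pixel_pitch,
                       subject_id = meta$subject_id %||% NA_character_))
  } else stop("unknown format: ", fmt)

  frame_stack(frames, fps = fps, pixel_pitch = pixel_pitch,
              subject_id = meta$subject_id %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
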