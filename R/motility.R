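#' Binary frame stacks
#'
#' An ordered list of same-shaped 0/1 matrices (1 = larva pixel), the input
#' to the motility statistic. Frames arrive post-stabilization; decoding and
#' fps standardization happen upstream.
#'
#' @param frames list of matrices with identical dimensions.
#' @param fps frames per second (metadata only).
#' @param source_id identifier carried through outputs.
#' @return A `frame_stack`.
#' @export
frame_stack <- function(frames, fps = 60, source_id = NA_character_) {
  if (!length(frames)) eo_stop("empty frame stack", "empty_input")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    eo_stop("all frames must share the same shape", "validation_error")
  structure(list(frames = frames, fps = fps, source_id = source_id),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_stack: %d frames of %dx%d, %g fps>\n",
              length(x$frames), d[1L], d[2L], x$fps))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Binarize a grayscale frame stack
#'
#' Step (1) of the motility measurement: pixels at or above the effective
#' threshold become 1 (larva), the rest 0 (background). With
#' `method = "otsu"` the threshold is computed on the first frame (Otsu's
#' method) and frozen for the whole stack, so motility is not confounded by
#' per-frame threshold drift. A constant first frame yields an all-zero
#' mask with a warning.
#'
#' @param stack a [frame_stack()] of grayscale frames in \[0, 1\], or a list
#'   of matrices.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold cut value for `method = "fixed"`.
#' @return A binary [frame_stack()] with attribute `threshold`.
#' @export
binarize <- function(stack, method = c("otsu", "fixed"), threshold = 0.5) {
  method <- match.arg(method)
  if (!inherits(stack, "frame_stack")) stack <- frame_stack(stack)
  first <- stack$frames[[1L]]
  if (method == "otsu") {
    rng <- range(first)
    if (diff(rng) == 0) {
      eo_warn("constant first frame: degenerate threshold, all-zero masks",
              "degenerate_threshold_warning")
      threshold <- rng[2L] + 1
    } else {
      threshold <- EBImage::otsu(EBImage::Image(first), range = rng)
    }
  }
  out <- lapply(stack$frames, function(f) (f >= threshold) * 1)
  res <- frame_stack(out, fps = stack$fps, source_id = stack$source_id)
  attr(res, "threshold") <- threshold
  res
}

#' Cosine distance between two binary frames
#'
#' Steps (2)-(3): both frames are flattened to vectors and the distance is
#' one minus the cosine of the angle between them,
#' `1 - (a . b) / (|a| |b|)`. Being scale-free, it is indifferent to the
#' larva's pixel count, unlike a Euclidean frame difference. Conventions
#' for empty frames: both empty -> 0 (no observable movement), exactly one
#' empty -> 1 (appearance or disappearance is maximal change).
#'
#' @param a,b binary matrices of the same shape.
#' @return distance in \[0, 1\].
#' @export
frame_cosine_distance <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    eo_stop("frames differ in shape", "validation_error")
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 && nb2 == 0) return(0)
  if (na2 == 0 || nb2 == 0) return(1)
  # single sqrt of the product keeps integer mask norms exact
  1 - sum(a * b) / sqrt(na2 * nb2)
}

#' Average larval motility of a frame stack
#'
#' Step (4): the arithmetic mean of the cosine distances between each frame
#' and its predecessor. 0 for a static stack, 1 when consecutive masks
#' never overlap.
#'
#' @param stack a binary [frame_stack()] with at least two frames.
#' @return mean consecutive-frame cosine distance.
#' @export
average_motility <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (n < 2L) eo_stop("motility needs at least 2 frames",
                      "insufficient_frames")
  d <- vapply(seq_len(n - 1L), function(i)
    frame_cosine_distance(stack$frames[[i]], stack$frames[[i + 1L]]),
    numeric(1))
  mean(d)
}

#' Bioassay endpoint series over essential-oil concentrations
#'
#' Named endpoint series (larval motility M, pupation rate PR, pupae volume
#' V, dead-and-deformed adults DD, ...) aligned to a strictly increasing
#' concentration grid.
#'
#' @param concentration strictly increasing EO concentrations (percent).
#' @param ... equal-length numeric endpoint series, named.
#' @return A `bioassay_series` data.frame.
#' @export
bioassay_series <- function(concentration, ...) {
  series <- list(...)
  if (!length(series) || is.null(names(series)) || any(names(series) == ""))
    eo_stop("endpoint series must be named", "validation_error")
  if (is.unsorted(concentration, strictly = TRUE))
    eo_stop("concentrations must be strictly increasing", "validation_error")
  if (any(lengths(series) != length(concentration)))
    eo_stop("all series must match the concentration grid length",
            "validation_error")
  structure(data.frame(concentration = concentration, series),
            class = c("bioassay_series", "data.frame"))
}

#' @rdname bioassay_series
#' @param path CSV with a `concentration` column plus endpoint columns.
#' @export
read_bioassay <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"concentration" %in% names(df))
    eo_stop("bioassay file needs a concentration column", "format_error")
  do.call(bioassay_series,
          c(list(concentration = df$concentration),
            df[setdiff(names(df), "concentration")]))
}

#' Windowed Pearson correlations between bioassay endpoints
#'
#' Pearson r for each requested endpoint pair, restricted to observations
#' whose concentration lies in the closed `window` (e.g. the 13-20%
#' concentration band).
#'
#' @param series a [bioassay_series()].
#' @param window closed concentration interval `c(lo, hi)`.
#' @param pairs 2-column character matrix of endpoint pairs; all unordered
#'   pairs by default.
#' @return data.frame (var1, var2, r, n).
#' @export
windowed_pearson <- function(series, window = c(-Inf, Inf), pairs = NULL) {
  stopifnot(inherits(series, "bioassay_series"))
  sel <- series$concentration >= window[1L] & series$concentration <= window[2L]
  if (sum(sel) < 3L)
    eo_stop("fewer than 3 points inside the window", "insufficient_points")
  vars <- setdiff(names(series), "concentration")
  if (is.null(pairs))
    pairs <- t(utils::combn(vars, 2L))
  bad <- setdiff(unique(as.vector(pairs)), vars)
  if (length(bad))
    eo_stop(sprintf("unknown endpoint(s): %s", paste(bad, collapse = ", ")),
            "validation_error")
  r <- apply(pairs, 1L, function(p)
    stats::cor(series[[p[1L]]][sel], series[[p[2L]]][sel]))
  data.frame(var1 = pairs[, 1L], var2 = pairs[, 2L], r = r, n = sum(sel))
}

#' Read a frame stack from disk
#'
#' Either a directory of PNG/TIFF frames (lexicographic filename order =
#' time; color images are averaged to grayscale) or a single packed-array
#' RDS file holding a list of matrices or a height x width x frames array.
#'
#' @param path directory or file path.
#' @param fps frames-per-second metadata.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, fps = 60) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) eo_stop("no frame images in directory", "empty_input")
    frames <- lapply(files, function(f) {
      img <- if (grepl("png$", f, ignore.case = TRUE)) png::readPNG(f)
             else EBImage::imageData(EBImage::readImage(f))
      if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
      img
    })
  } else {
    obj <- readRDS(path)
    frames <- if (is.list(obj)) obj
              else lapply(seq_len(dim(obj)[3L]), function(i) obj[, , i])
  }
  frame_stack(frames, fps = fps, source_id = basename(path))
}

#' @rdname read_frame_stack
#' @param stack a [frame_stack()] to write as numbered PNGs.
#' @param dir output directory (created if needed).
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames))
    png::writePNG(stack$frames[[i]],
                  file.path(dir, sprintf("frame_%04d.png", i)))
  invisible(dir)
}
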