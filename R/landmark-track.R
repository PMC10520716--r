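#' Construct a landmark track
#'
#' A landmark track is a timestamped series of the 14 facial keypoints (see
#' [landmark_roles()]) in image-frame pixel coordinates, y increasing
#' downward.
#'
#' @param t Numeric vector of timestamps (seconds), strictly increasing.
#' @param xy Numeric matrix `length(t) x 28` with columns `<role>_x`,
#'   `<role>_y` for every role in [landmark_roles()].
#' @param valid Optional logical vector marking frames with usable
#'   coordinates; defaults to frames with no NA coordinate.
#' @return Object of class `landmark_track` with fields `t`, `xy`,
#'   `valid`, `frame_rate` (Hz, inferred from the median timestamp step)
#'   and `normalized` (FALSE until [normalize_track()]).
#' @export
landmark_track <- function(t, xy, valid = NULL) {
  t <- as.numeric(t)
  if (length(t) < 1) stop("empty track")
  if (any(diff(t) <= 0)) stop("format error: timestamps not strictly increasing")
  expected <- track_columns()
  if (is.null(colnames(xy)) || !all(expected %in% colnames(xy))) {
    miss <- setdiff(expected, colnames(xy))
    stop("format error: missing keypoint column(s): ",
         paste(utils::head(miss, 4), collapse = ", "))
  }
  xy <- as.matrix(xy[, expected, drop = FALSE])
  storage.mode(xy) <- "double"
  if (nrow(xy) != length(t)) stop("xy rows must match timestamps")
  if (is.null(valid)) valid <- stats::complete.cases(xy)
  fr <- if (length(t) > 1) 1 / stats::median(diff(t)) else NA_real_
  structure(list(t = t, xy = xy, valid = as.logical(valid),
                 frame_rate = fr, normalized = FALSE),
            class = "landmark_track")
}

track_columns <- function() {
  as.vector(t(outer(landmark_roles(), c("x", "y"), paste, sep = "_")))
}

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf(
    "landmark_track: %d frames, %.1f s span, %.1f fps, %d valid%s\n",
    length(x$t), diff(range(x$t)), x$frame_rate, sum(x$valid),
    if (x$normalized) ", canthal-normalized" else ""))
  invisible(x)
}

#' Read a landmark track CSV
#'
#' Expects a header row with a `t` column (seconds) and 28 coordinate
#' columns `<role>_x`, `<role>_y` for the canonical roles. Frames with NA
#' coordinates are kept but masked invalid. An optional `role_map` renames
#' nonstandard column prefixes to canonical roles.
#'
#' @param path CSV path.
#' @param role_map Optional named character vector `c(source_role = canonical_role)`.
#' @return A [landmark_track()].
#' @export
read_landmark_track <- function(path, role_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"t" %in% names(df)) stop("format error: no timestamp column 't' in ", path)
  if (!is.null(role_map)) {
    for (src in names(role_map)) {
      names(df) <- sub(paste0("^", src, "_"), paste0(role_map[[src]], "_"),
                       names(df))
    }
  }
  landmark_track(df$t, as.matrix(df[, setdiff(names(df), "t")]))
}

#' Write a landmark track CSV
#'
#' @param track A [landmark_track()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmark_track <- function(track, path) {
  df <- data.frame(t = track$t, track$xy, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# x/y column index helpers for a role
role_x <- function(role) paste0(role, "_x")
role_y <- function(role) paste0(role, "_y")

role_point <- function(track, role) {
  track$xy[, c(role_x(role), role_y(role)), drop = FALSE]
}

point_dist <- function(a, b) {
  sqrt(rowSums((a - b)^2))
}
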