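#' Detect candidate spots as local maxima
#'
#' Peaks are local maxima over a `(2 * min_distance + 1)^2` neighborhood
#' with intensity above a threshold, followed by non-maximum suppression
#' so no two peaks lie within `min_distance` px of each other (the
#' brighter wins). The threshold is either absolute or robust,
#' `median + k * MAD`, estimated per plane.
#'
#' @param plane preprocessed numeric matrix.
#' @param threshold either a single number (absolute) or a list
#'   `list(method = "robust", k = 6)`.
#' @param min_distance neighborhood radius, px (default 2).
#' @return data.frame `row`, `col` (0-based integer peak), `intensity`.
#' @export
detectSpots <- function(plane, threshold = list(method = "robust", k = 6),
                        min_distance = 2L) {
  thr <- if (is.numeric(threshold)) {
    threshold
  } else {
    k <- if (is.null(threshold$k)) 6 else threshold$k
    stats::median(plane) + k * stats::mad(plane)
  }
  pk <- cpp_local_maxima(plane, thr, as.integer(min_distance))
  data.frame(row = as.integer(pk[, "row"]), col = as.integer(pk[, "col"]),
             intensity = pk[, "value"])
}

#' Sub-pixel spot localization by radial symmetry
#'
#' Refines an integer peak to the radial center of the local intensity
#' distribution: the point minimizing the weighted squared distance to
#' the gradient lines of the window (gradient-line least squares, weights
#' the squared gradient magnitude). Peaks too close to the border fall
#' back to the intensity centroid of the clipped window and are flagged.
#'
#' @param plane numeric matrix.
#' @param peak integer vector `(row, col)`, 0-based.
#' @param window odd window size (default 7).
#' @return list `x`, `y` (0-based sub-pixel), `method` one of
#'   `"radial"`, `"centroid"`, `"degenerate"`.
#' @export
refineRadialCenter <- function(plane, peak, window = 7L) {
  stopifnot(window %% 2 == 1)
  h <- (window - 1L) %/% 2L
  r0 <- peak[1] - h; r1 <- peak[1] + h
  c0 <- peak[2] - h; c1 <- peak[2] + h
  nr <- nrow(plane); nc <- ncol(plane)
  if (r0 < 0 || c0 < 0 || r1 > nr - 1 || c1 > nc - 1) {
    rr <- max(r0, 0):min(r1, nr - 1); cc <- max(c0, 0):min(c1, nc - 1)
    win <- plane[rr + 1L, cc + 1L, drop = FALSE]
    tot <- sum(win)
    if (tot <= 0) return(list(x = peak[2], y = peak[1], method = "degenerate"))
    wy <- rowSums(win); wx <- colSums(win)
    return(list(x = sum(cc * wx) / tot, y = sum(rr * wy) / tot,
                method = "centroid"))
  }
  win <- plane[(r0:r1) + 1L, (c0:c1) + 1L]
  # gradients on the dual grid: 2x2 cell differences at midpoints
  m <- window - 1L
  a <- win[1:m, 1:m]; b <- win[1:m, 2:(m + 1L)]
  d <- win[2:(m + 1L), 1:m]; e <- win[2:(m + 1L), 2:(m + 1L)]
  gx <- (b + e - a - d) / 2     # d/dx (columns)
  gy <- (d + e - a - b) / 2     # d/dy (rows)
  wgt <- gx^2 + gy^2
  if (sum(wgt) <= 0)
    return(list(x = peak[2], y = peak[1], method = "degenerate"))
  # midpoint coordinates of each 2x2 cell (absolute, 0-based)
  my <- matrix(rep(r0 + (1:m) - 0.5, m), nrow = m)
  mx <- matrix(rep(c0 + (1:m) - 0.5, each = m), nrow = m)
  # distance of p to the line through (mx,my) with direction g has normal
  # n = (-gy, gx); accumulate the 2x2 normal-projection system
  gn <- sqrt(wgt)
  nx <- -gy / pmax(gn, 1e-12); ny <- gx / pmax(gn, 1e-12)
  Sxx <- sum(wgt * nx * nx); Sxy <- sum(wgt * nx * ny); Syy <- sum(wgt * ny * ny)
  bx <- sum(wgt * (nx * nx * mx + nx * ny * my))
  by <- sum(wgt * (nx * ny * mx + ny * ny * my))
  det <- Sxx * Syy - Sxy * Sxy
  if (abs(det) < 1e-9 * max(Sxx, Syy, 1e-12))
    return(list(x = peak[2], y = peak[1], method = "degenerate"))
  x <- (Syy * bx - Sxy * by) / det
  y <- (Sxx * by - Sxy * bx) / det
  # never move further than the window half-width
  if (abs(x - peak[2]) > h || abs(y - peak[1]) > h)
    return(list(x = peak[2], y = peak[1], method = "degenerate"))
  list(x = x, y = y, method = "radial")
}

#' Call spots across all planes of a registered stack
#'
#' Runs [detectSpots()] and [refineRadialCenter()] on every
#' (round, channel) plane and assembles the spot table used by the
#' decoder. Coordinates are 0-based with pixel centers at integers,
#' `x` = column, `y` = row.
#'
#' @param stack a registered, preprocessed [ImageStack-class].
#' @param threshold,min_distance see [detectSpots()].
#' @param window see [refineRadialCenter()].
#' @return data.frame sorted by (pseudocolor, y, x) with columns
#'   `spot_id`, `round`, `channel`, `pseudocolor`, `x`, `y`, `intensity`,
#'   `loc_method`.
#' @export
callSpots <- function(stack, threshold = list(method = "robust", k = 6),
                      min_distance = 2L, window = 7L) {
  if (!isRegistered(stack))
    stop("stack must be registered before spot calling; run registerRounds()")
  R <- nRounds(stack); C <- nChannels(stack)
  out <- list()
  for (r in seq_len(R) - 1L) {
    for (ch in seq_len(C) - 1L) {
      plane <- getPlane(stack, r, ch)
      pk <- detectSpots(plane, threshold, min_distance)
      if (nrow(pk) == 0L) next
      ref <- lapply(seq_len(nrow(pk)), function(i) {
        refineRadialCenter(plane, c(pk$row[i], pk$col[i]), window)
      })
      out[[length(out) + 1L]] <- data.frame(
        round = r, channel = ch, pseudocolor = r * C + ch,
        x = vapply(ref, `[[`, 0, "x"), y = vapply(ref, `[[`, 0, "y"),
        intensity = pk$intensity,
        loc_method = vapply(ref, `[[`, "", "method"),
        stringsAsFactors = FALSE)
    }
  }
  spots <- if (length(out)) do.call(rbind, out) else
    data.frame(round = integer(), channel = integer(),
               pseudocolor = integer(), x = numeric(), y = numeric(),
               intensity = numeric(), loc_method = character(),
               stringsAsFactors = FALSE)
  spots <- spots[order(spots$pseudocolor, spots$y, spots$x), , drop = FALSE]
  rownames(spots) <- NULL
  spots$spot_id <- seq_len(nrow(spots))
  spots[, c("spot_id", "round", "channel", "pseudocolor", "x", "y",
            "intensity", "loc_method")]
}
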