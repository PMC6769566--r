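#' Construct a per-pixel malignancy probability map
#'
#' @param specimen_id Specimen identifier.
#' @param entries Data frame with columns `x`, `y`, `probability`
#'   (probabilities in \[0, 1\]), one row per scored pixel.
#' @param masked Optional two-column matrix/data frame of (x, y) pixels
#'   excluded as empty or invalid; must be disjoint from `entries`.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(specimen_id, entries, masked = NULL) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("x", "y", "probability") %in% names(entries)))
  if (nrow(entries) == 0L) stop("probability map must be non-empty")
  if (any(entries$probability < 0 | entries$probability > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  ek <- coord_key(entries$x, entries$y)
  if (anyDuplicated(ek)) stop("duplicate pixels in map entries")
  if (is.null(masked)) {
    masked <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  } else {
    masked <- as.matrix(masked)
    storage.mode(masked) <- "integer"
    colnames(masked) <- c("x", "y")
    if (nrow(masked) && any(coord_key(masked[, 1], masked[, 2]) %in% ek)) {
      stop("masked pixels must be disjoint from scored entries")
    }
  }
  structure(list(specimen_id = as.character(specimen_id),
                 entries = entries[, c("x", "y", "probability")],
                 masked = masked),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map %s: %d scored, %d masked; q3 = %.4f>\n",
              x$specimen_id, nrow(x$entries), nrow(x$masked),
              unname(stats::quantile(x$entries$probability, 0.75))))
  invisible(x)
}

#' Render a probability map as a PNG raster with CSV sidecar
#'
#' Low-probability pixels render green, high-probability pixels red, with a
#' continuous ramp in between — benign tissue therefore appears uniformly
#' green and malignant tissue red, matching how pathologists read these
#' overlays. Masked and absent pixels are fully transparent. A CSV sidecar
#' (`x`, `y`, `probability`) is written next to the image.
#'
#' @param map A [probability_map].
#' @param path Output PNG path; the sidecar replaces the extension with
#'   `.csv`.
#' @param scale Integer magnification factor for the raster (default 1:
#'   one image pixel per MSI pixel).
#' @return `path`, invisibly.
#' @export
render_probability_map <- function(map, path, scale = 1L) {
  stopifnot(inherits(map, "probability_map"))
  scale <- max(1L, as.integer(scale))
  w <- max(map$entries$x, if (nrow(map$masked)) map$masked[, "x"] else 1L)
  h <- max(map$entries$y, if (nrow(map$masked)) map$masked[, "y"] else 1L)
  img <- array(0, dim = c(h, w, 4))  # RGBA, all transparent
  p <- map$entries$probability
  img[cbind(map$entries$y, map$entries$x, 1)] <- p        # red ramps up
  img[cbind(map$entries$y, map$entries$x, 2)] <- 1 - p    # green ramps down
  img[cbind(map$entries$y, map$entries$x, 4)] <- 1
  if (scale > 1L) {
    img <- img[rep(seq_len(h), each = scale),
               rep(seq_len(w), each = scale), , drop = FALSE]
  }
  png::writePNG(img, path)
  csv_path <- paste0(sub("\\.png$", "", path), ".csv")
  utils::write.csv(map$entries, csv_path, row.names = FALSE)
  invisible(path)
}
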