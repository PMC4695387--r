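# Colony-image proximity analysis: per-marker pixel classification at
# normalised intensity cut-offs and nearest-prototroph distance statistics.

#' Construct a multi-channel colony image
#'
#' One grayscale intensity raster per marker (all the same dimensions), the
#' physical pixel edge length in micrometres, and an optional boolean colony
#' mask separating colony pixels from background. When no mask is given one
#' is derived with [default_colony_mask()].
#'
#' @param channels Named list of numeric matrices (non-negative
#'   intensities), names = marker ids. Row 0 is the image top; coordinates
#'   are row/column with distances measured between pixel centres.
#' @param pixel_size_um Micrometres per pixel edge (> 0).
#' @param mask Optional logical matrix of the same dimensions; `TRUE` =
#'   colony pixel.
#' @param background_quantile Quantile used by [default_colony_mask()] when
#'   `mask` is `NULL` (default 0.05).
#' @return An object of class `colony_image`.
#' @export
colony_image <- function(channels, pixel_size_um, mask = NULL,
                         background_quantile = 0.05) {
  if (!is.list(channels) || is.null(names(channels)) ||
      !all(nzchar(names(channels))))
    stop("'channels' must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L)
    stop("all channels must share the same dimensions")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("channel intensities must be non-negative")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  img <- structure(list(channels = channels,
                        pixel_size_um = pixel_size_um, mask = mask),
                   class = "colony_image")
  if (is.null(mask)) {
    img$mask <- default_colony_mask(img, background_quantile)
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dims[[1]]))
      stop("'mask' must be a logical matrix matching the channel dimensions")
  }
  if (!any(img$mask)) stop("colony mask covers no pixels")
  img
}

#' Default colony mask from channel intensities
#'
#' A pixel belongs to the colony when the maximum intensity across channels
#' exceeds the `q` quantile of that maximum image — a conservative
#' background separator for synthetic and well-exposed images. Supply an
#' explicit mask to [colony_image()] to override.
#'
#' @param image A `colony_image` (mask ignored).
#' @param q Background quantile in (0, 1) (default 0.05).
#' @return Logical matrix.
#' @export
default_colony_mask <- function(image, q = 0.05) {
  mx <- Reduce(pmax, image$channels)
  mx > stats::quantile(mx, q)
}

#' @export
print.colony_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<colony_image>", d[1], "x", d[2], "px,",
      length(x$channels), "channel(s) [",
      paste(names(x$channels), collapse = ", "), "],",
      x$pixel_size_um, "um/px,", sum(x$mask), "colony px\n")
  invisible(x)
}

#' Min-max normalise a marker channel over the colony mask
#'
#' Scales intensities so the masked minimum maps to 0 and the masked maximum
#' to 1 — the scale on which the classification cut-offs (0.1-0.4) live. A
#' constant channel cannot be scaled and is returned as all zeros with
#' attribute `degenerate = TRUE`.
#'
#' @param image A [colony_image()].
#' @param marker Channel name.
#' @return Numeric matrix in \[0, 1\] (values outside the mask are also
#'   scaled, and may fall outside \[0, 1\]; only masked pixels are ever
#'   classified).
#' @export
normalize_channel <- function(image, marker) {
  if (!marker %in% names(image$channels))
    stop("no channel for marker '", marker, "'")
  ch <- image$channels[[marker]]
  v <- ch[image$mask]
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    out <- ch * 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (ch - lo) / (hi - lo)
  attr(out, "degenerate") <- FALSE
  out
}

#' Classify colony pixels as prototrophic or auxotrophic
#'
#' Within the colony mask, a pixel whose normalised channel intensity is at
#' least the cut-off is classed as metabolite-producing (prototrophic) for
#' that marker, otherwise as requiring (auxotrophic); pixels outside the
#' mask are background.
#'
#' @param image A [colony_image()].
#' @param marker Channel name.
#' @param cutoff Normalised intensity threshold in (0, 1).
#' @return An object of class `pixel_classification`: list with `labels`
#'   (integer matrix, 0 = background, 1 = prototroph, 2 = auxotroph),
#'   `marker`, `cutoff`, `pixel_size_um`.
#' @export
classify_pixels <- function(image, marker, cutoff) {
  if (length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie strictly in (0, 1)")
  norm <- normalize_channel(image, marker)
  labels <- matrix(0L, nrow(norm), ncol(norm))
  labels[image$mask] <- ifelse(norm[image$mask] >= cutoff, 1L, 2L)
  structure(list(labels = labels, marker = marker, cutoff = cutoff,
                 pixel_size_um = image$pixel_size_um),
            class = "pixel_classification")
}

#' Distance from each auxotrophic pixel to the nearest prototroph
#'
#' Exact Euclidean distance (between pixel centres, in micrometres) from
#' every auxotrophic pixel to its nearest prototrophic pixel, computed with
#' an exact Euclidean distance transform.
#'
#' @param cls A [classify_pixels()] result.
#' @param pixel_size_um Micrometres per pixel (default: taken from `cls`).
#' @param mode `"pixel"` (default) reports one distance per auxotrophic
#'   pixel; `"cell"` reports one distance per connected auxotrophic
#'   component, measured from the component centroid pixel.
#' @return Numeric vector of distances in micrometres, with attribute
#'   `status`: `"ok"`, `"no_producer"` (no prototrophic pixel exists;
#'   distances empty), or `"no_auxotroph"` (no auxotrophic pixel; empty).
#' @export
nearest_prototroph_distances <- function(cls, pixel_size_um = NULL,
                                         mode = c("pixel", "cell")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cls, "pixel_classification"))
  if (is.null(pixel_size_um)) pixel_size_um <- cls$pixel_size_um
  lab <- cls$labels
  if (!any(lab == 1L))
    return(structure(numeric(0), status = "no_producer"))
  if (!any(lab == 2L))
    return(structure(numeric(0), status = "no_auxotroph"))
  # distmap: distance of non-zero pixels to the nearest zero pixel
  dmap <- EBImage::imageData(
    EBImage::distmap(ifelse(lab == 1L, 0, 1), metric = "euclidean"))
  if (mode == "pixel") {
    d <- dmap[lab == 2L] * pixel_size_um
  } else {
    comp <- EBImage::imageData(EBImage::bwlabel(lab == 2L))
    ids <- setdiff(unique(as.vector(comp)), 0)
    d <- vapply(ids, function(id) {
      px <- which(comp == id, arr.ind = TRUE)
      centroid <- round(colMeans(px))
      # nearest component pixel to the centroid carries the distance
      i <- which.min((px[, 1] - centroid[1])^2 + (px[, 2] - centroid[2])^2)
      dmap[px[i, 1], px[i, 2]]
    }, numeric(1)) * pixel_size_um
  }
  structure(as.numeric(d), status = "ok")
}

#' Summary statistics of nearest-prototroph distances
#'
#' Minimum, mean, maximum and the `percentile`-th percentile (linear
#' interpolation between order statistics) of a distance vector, in
#' micrometres — the "how far is the nearest producer" summary per marker
#' and cut-off.
#'
#' @param distances Numeric vector from [nearest_prototroph_distances()].
#' @param percentile Percentile to report (default 90).
#' @return List of class `distance_summary` with `n`, `min_um`, `mean_um`,
#'   `max_um`, `p_um` (the percentile), `percentile`, and `status`.
#' @export
summarize_distances <- function(distances, percentile = 90) {
  status <- attr(distances, "status")
  if (is.null(status)) status <- "ok"
  if (length(distances) == 0L)
    return(structure(list(n = 0L, min_um = NA_real_, mean_um = NA_real_,
                          max_um = NA_real_, p_um = NA_real_,
                          percentile = percentile,
                          status = if (status == "ok") "no_auxotroph"
                                   else status),
                     class = "distance_summary"))
  structure(list(n = length(distances),
                 min_um = min(distances),
                 mean_um = mean(distances),
                 max_um = max(distances),
                 p_um = as.numeric(stats::quantile(distances,
                                                   percentile / 100,
                                                   type = 7, names = FALSE)),
                 percentile = percentile,
                 status = status),
            class = "distance_summary")
}

#' Proximity sweep over markers and cut-offs
#'
#' Runs the full classification + distance pipeline for every marker channel
#' at every cut-off and tabulates the distance summaries — the sweep that
#' shows whether auxotrophs stay within metabolite-exchange range of their
#' producers at any reasonable intensity threshold.
#'
#' @param image A [colony_image()].
#' @param cutoffs Numeric vector of cut-offs in (0, 1) (default
#'   `c(0.1, 0.2, 0.3, 0.4)`).
#' @param percentile Percentile to report (default 90).
#' @param mode Passed to [nearest_prototroph_distances()].
#' @return Data frame with one row per marker x cutoff: `marker`, `cutoff`,
#'   `n_auxotrophic_pixels`, `min_um`, `mean_um`, `max_um`, `p90_um`,
#'   `status`.
#' @export
proximity_sweep <- function(image, cutoffs = c(0.1, 0.2, 0.3, 0.4),
                            percentile = 90, mode = "pixel") {
  rows <- list()
  for (mk in names(image$channels)) {
    for (cf in cutoffs) {
      cls <- classify_pixels(image, mk, cf)
      d <- nearest_prototroph_distances(cls, mode = mode)
      s <- summarize_distances(d, percentile)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, cutoff = cf, n_auxotrophic_pixels = s$n,
        min_um = s$min_um, mean_um = s$mean_um, max_um = s$max_um,
        p90_um = s$p_um, status = s$status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
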