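# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: multinomial genotyping, binomial plasmid
# retention, disk-cell colony images with sector bias, and noisy Richards
# curves. Ground truth is always returned beside the artefact.

#' Generate multinomial genotyping counts
#'
#' Emulates genotyping `n_cells` cells from a colony with true metabotype
#' frequencies `freqs`: a single multinomial draw.
#'
#' @param freqs A `composition` (see [composition_vector()]).
#' @param n_cells Number of cells genotyped (>= 1).
#' @param seed Integer seed; identical seeds give identical counts.
#' @return Named integer vector of counts per metabotype, summing to
#'   `n_cells`.
#' @export
gen_genotyping_counts <- function(freqs, n_cells, seed = NULL) {
  if (!inherits(freqs, "composition"))
    stop("'freqs' must be a composition")
  stopifnot(n_cells >= 1)
  with_seed(seed, {
    cnt <- as.integer(stats::rmultinom(1L, n_cells, as.numeric(freqs)))
    stats::setNames(cnt, names(freqs))
  })
}

#' Generate replica-plating retention observations
#'
#' Each replicate plates `n_cfu` colony-forming units after `g` doublings
#' at true per-division loss rate `m_true`; the number still retaining the
#' plasmid is Binomial(n_cfu, (1 - m_true)^g).
#'
#' @param m_true True per-division loss probability in \[0, 1\].
#' @param g Elapsed doublings (> 0).
#' @param n_cfu CFUs scored per replicate (>= 1).
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @param marker Marker id recorded in the observations (default
#'   `"MARKER"`).
#' @return A [replica_plating()] data frame.
#' @export
gen_replica_plating <- function(m_true, g, n_cfu, n_replicates, seed = NULL,
                                marker = "MARKER") {
  stopifnot(m_true >= 0, m_true <= 1, g > 0, n_cfu >= 1, n_replicates >= 1)
  with_seed(seed, {
    p <- marginal_retention(m_true, g)
    replica_plating(marker,
                    total_cfu = rep(n_cfu, n_replicates),
                    retaining_cfu = stats::rbinom(n_replicates, n_cfu, p),
                    generations = g)
  })
}

#' Specification of a synthetic colony image
#'
#' @param markers A [marker_set()].
#' @param freqs A `composition` giving true metabotype frequencies.
#' @param shape `c(rows, cols)` in pixels.
#' @param pixel_size_um Micrometres per pixel edge.
#' @param cell_radius_px Cell radius in pixels.
#' @param n_cells Number of cells to place.
#' @param sector_bias Angular clustering strength kappa >= 0: 0 places
#'   metabotypes spatially uniformly; larger values weight each marker's
#'   retention towards a marker-specific preferred angle with a von Mises
#'   kernel, mimicking the sectored regions of real colonies.
#' @param intensity_high,intensity_low Channel mean where the covering cell
#'   retains / lacks the marker's plasmid.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List of class `image_spec`.
#' @export
image_spec <- function(markers, freqs, shape = c(200L, 200L),
                       pixel_size_um = 0.8, cell_radius_px = 4,
                       n_cells = 250L, sector_bias = 0,
                       intensity_high = 1000, intensity_low = 100,
                       noise_sd = 0, seed = NULL) {
  stopifnot(inherits(markers, "marker_set"), inherits(freqs, "composition"),
            length(shape) == 2L, all(shape > 0), pixel_size_um > 0,
            cell_radius_px >= 1, n_cells >= 1, sector_bias >= 0,
            intensity_high > intensity_low, intensity_low >= 0,
            noise_sd >= 0)
  structure(list(markers = markers, freqs = freqs, shape = as.integer(shape),
                 pixel_size_um = pixel_size_um,
                 cell_radius_px = cell_radius_px, n_cells = as.integer(n_cells),
                 sector_bias = sector_bias, intensity_high = intensity_high,
                 intensity_low = intensity_low, noise_sd = noise_sd,
                 seed = seed),
            class = "image_spec")
}

#' Generate a synthetic fluorescence colony image with ground truth
#'
#' Cells are drawn as filled disks at positions uniform over a circular
#' colony footprint; each cell's metabotype is drawn from the specified
#' frequencies, optionally re-weighted by a per-marker von Mises kernel on
#' the cell's angular position (sector bias). Each marker channel takes the
#' high intensity on pixels covered by a cell retaining that plasmid and
#' the low intensity on other colony pixels, plus Gaussian noise (clipped
#' at 0). Background outside the footprint is 0 before noise.
#'
#' @param spec An [image_spec()].
#' @return List with `image` (a [colony_image()] whose mask is the colony
#'   footprint) and `truth` (data frame: `cell`, `row`, `col`,
#'   `radius_px`, `metabotype`), plus `producer_truth`, a named list of
#'   logical matrices marking, per marker, the pixels covered by a
#'   plasmid-retaining cell.
#' @export
gen_colony_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  rows <- spec$shape[1]; cols <- spec$shape[2]
  R <- 0.45 * min(rows, cols)
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  if (spec$n_cells * pi * spec$cell_radius_px^2 > pi * R^2)
    stop("infeasible packing: n_cells x cell area exceeds the colony ",
         "footprint capacity")
  space <- names(spec$freqs)
  k <- n_markers(spec$markers)
  bits <- t(vapply(strsplit(space, ""), function(b) b == "1", logical(k)))
  if (k == 1L) bits <- matrix(bits, ncol = 1L)
  pref_angle <- 2 * pi * (seq_len(k) - 1) / k
  with_seed(spec$seed, {
    # uniform positions in the disk
    r <- R * sqrt(stats::runif(spec$n_cells))
    th <- stats::runif(spec$n_cells, 0, 2 * pi)
    py <- cy + r * sin(th)
    px <- cx + r * cos(th)
    # metabotype assignment with per-marker angular weighting
    f <- as.numeric(spec$freqs)
    mt <- character(spec$n_cells)
    for (i in seq_len(spec$n_cells)) {
      wts <- f
      if (spec$sector_bias > 0) {
        for (j in seq_len(k)) {
          vm <- exp(spec$sector_bias * cos(th[i] - pref_angle[j]))
          wts <- wts * ifelse(bits[, j], vm, 1)
        }
      }
      mt[i] <- sample(space, 1L, prob = wts)
    }
    # rasterise
    producer <- lapply(seq_len(k), function(j) matrix(FALSE, rows, cols))
    names(producer) <- spec$markers$id
    covered <- matrix(FALSE, rows, cols)
    rad <- spec$cell_radius_px
    for (i in seq_len(spec$n_cells)) {
      rr <- max(1, floor(py[i] - rad)):min(rows, ceiling(py[i] + rad))
      cc <- max(1, floor(px[i] - rad)):min(cols, ceiling(px[i] + rad))
      d2 <- outer((rr - py[i])^2, (cc - px[i])^2, `+`)
      hit <- d2 <= rad^2
      covered[rr, cc] <- covered[rr, cc] | hit
      ret <- bits[match(mt[i], space), ]
      for (j in which(ret))
        producer[[j]][rr, cc] <- producer[[j]][rr, cc] | hit
    }
    footprint <- {
      d2 <- outer((seq_len(rows) - cy)^2, (seq_len(cols) - cx)^2, `+`)
      d2 <= R^2
    }
    channels <- lapply(producer, function(pm) {
      ch <- matrix(0, rows, cols)
      ch[footprint] <- spec$intensity_low
      ch[pm] <- spec$intensity_high
      if (spec$noise_sd > 0)
        ch <- pmax(ch + matrix(stats::rnorm(rows * cols, 0, spec$noise_sd),
                               rows, cols), 0)
      ch
    })
    img <- colony_image(channels, spec$pixel_size_um, mask = footprint)
    list(image = img,
         truth = data.frame(cell = seq_len(spec$n_cells), row = py,
                            col = px, radius_px = rad, metabotype = mt,
                            angle = th, stringsAsFactors = FALSE),
         producer_truth = producer)
  })
}

#' Generate a noisy Richards growth curve
#'
#' Model values plus additive Gaussian noise, clipped at 0.
#'
#' @param A,mu_max,lambda,nu Richards parameters (see [richards_value()]).
#' @param times Strictly increasing time points (hours).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A [growth_curve()].
#' @export
gen_growth_curve <- function(A, mu_max, lambda, nu, times, noise_sd = 0,
                             seed = NULL) {
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    y <- richards_value(times, A, mu_max, lambda, nu)
    if (noise_sd > 0)
      y <- pmax(y + stats::rnorm(length(times), 0, noise_sd), 0)
    growth_curve(times, y)
  })
}
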