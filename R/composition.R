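# Community composition summaries and observed-vs-predicted comparison.

#' Summarise a genotyped community composition
#'
#' Turns per-metabotype cell counts into the descriptive statistics used to
#' characterise a cross-feeding community: the overall auxotroph fraction,
#' the distribution of auxotrophy numbers (loss bins 0..k), the per-marker
#' auxotrophy abundances, and how concentrated the community is on its most
#' frequent metabotypes.
#'
#' `marker_auxotrophy_abs` is the proportion of all cells lacking each
#' marker. `marker_auxotrophy_share` normalises instead by the total number
#' of auxotrophy instances (a cell lacking two markers contributes twice),
#' so the k shares sum to 1 — the normalisation behind a "non 1:1 ratio of
#' auxotrophy types" breakdown.
#'
#' @param counts Named numeric vector (or named integer) of cell counts per
#'   metabotype mask; total >= 1.
#' @param markers A [marker_set()].
#' @param top_n How many top metabotypes the `top_n_share` statistic covers
#'   (default 8).
#' @return An object of class `composition_summary`: a list with
#'   `frequencies` (a `composition`), `auxotroph_fraction`, `loss_bins`
#'   (named proportions over 0..k losses), `marker_auxotrophy_abs`,
#'   `marker_auxotrophy_share`, `top_n`, `top_n_share`, `n_cells`, and
#'   `no_auxotrophs` (flag; when TRUE the shares are empty).
#' @examples
#' m <- semeco_markers()
#' cnt <- c("1111" = 267, "1101" = 197, "1011" = 111, "0000" = 61)
#' summarize_composition(cnt, m)
#' @export
summarize_composition <- function(counts, markers, top_n = 8L) {
  if (length(counts) == 0L) stop("'counts' must be non-empty")
  if (any(counts < 0)) stop("counts must be non-negative")
  n_cells <- sum(counts)
  if (n_cells < 1) stop("total count must be >= 1")
  comp <- validate_composition(counts, markers)
  k <- n_markers(markers)
  space <- names(comp)
  losses <- k - retained_count(space)
  f <- as.numeric(comp)
  loss_bins <- vapply(0:k, function(l) sum(f[losses == l]), numeric(1))
  names(loss_bins) <- as.character(0:k)
  aux_frac <- 1 - loss_bins["0"]
  names(aux_frac) <- NULL
  bits <- t(vapply(strsplit(space, ""), function(b) b == "1", logical(k)))
  if (k == 1L) bits <- matrix(bits, ncol = 1L)
  lacking <- vapply(seq_len(k), function(i) sum(f[!bits[, i]]), numeric(1))
  names(lacking) <- markers$id
  no_aux <- sum(lacking) == 0
  share <- if (no_aux) stats::setNames(numeric(0), character(0))
           else lacking / sum(lacking)
  rk <- rank_order(f, space)
  top_n <- min(top_n, length(space))
  structure(list(
    frequencies = comp,
    auxotroph_fraction = aux_frac,
    loss_bins = loss_bins,
    marker_auxotrophy_abs = lacking,
    marker_auxotrophy_share = share,
    top_n = as.integer(top_n),
    top_n_share = sum(f[rk[seq_len(top_n)]]),
    n_cells = n_cells,
    no_auxotrophs = no_aux), class = "composition_summary")
}

# Frequency-descending order with the canonical enumeration position as the
# deterministic tie-break.
rank_order <- function(f, space) {
  order(-f, seq_along(space))
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("<composition_summary> n_cells =", x$n_cells, "\n")
  cat("  auxotroph fraction:", sprintf("%.1f%%", 100 * x$auxotroph_fraction),
      "\n  loss bins (%):",
      paste(sprintf("%s:%.1f", names(x$loss_bins), 100 * x$loss_bins),
            collapse = " "), "\n")
  if (!x$no_auxotrophs)
    cat("  auxotrophy shares (%):",
        paste(sprintf("%s:%.1f", names(x$marker_auxotrophy_share),
                      100 * x$marker_auxotrophy_share), collapse = " "), "\n")
  cat("  top", x$top_n, "metabotypes carry",
      sprintf("%.1f%%", 100 * x$top_n_share), "of cells\n")
  invisible(x)
}

#' Compare an observed composition with a model prediction
#'
#' Least-squares comparison of the paired per-metabotype frequencies:
#' squared Pearson correlation, regression slope/intercept
#' (observed ~ predicted), and the per-metabotype residuals
#' (observed - predicted).
#'
#' @param predicted,observed `composition` vectors over the same metabotype
#'   space (see [composition_vector()]).
#' @return An object of class `comparison_result`: list with `r_squared`,
#'   `slope`, `intercept`, `residuals` (named), and `degenerate` (TRUE when
#'   either vector has zero variance, in which case the correlation is
#'   undefined and `r_squared`, `slope`, `intercept` are `NA` — flagged, not
#'   silently propagated).
#' @export
compare_compositions <- function(predicted, observed) {
  if (!identical(names(predicted), names(observed)))
    stop("compositions must share the same metabotype space")
  p <- as.numeric(predicted); o <- as.numeric(observed)
  degenerate <- stats::sd(p) == 0 || stats::sd(o) == 0
  if (degenerate) {
    r2 <- slope <- intercept <- NA_real_
  } else {
    r2 <- stats::cor(p, o)^2
    slope <- stats::cov(p, o) / stats::var(p)
    intercept <- mean(o) - slope * mean(p)
  }
  structure(list(r_squared = r2, slope = slope, intercept = intercept,
                 residuals = stats::setNames(o - p, names(predicted)),
                 degenerate = degenerate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$degenerate)
    cat("<comparison_result> degenerate (zero variance); r^2 undefined\n")
  else
    cat(sprintf("<comparison_result> r^2 = %.3f, slope = %.3f, intercept = %.4f\n",
                x$r_squared, x$slope, x$intercept))
  invisible(x)
}

#' Rank metabotypes by frequency
#'
#' Frequency-descending ranking with a deterministic tie-break (canonical
#' enumeration position), plus the cumulative frequency — the view in which
#' a community "dominated by eight metabotypes" is read off.
#'
#' @param x A `composition_summary` or a `composition`.
#' @param n How many metabotypes to return (default: all).
#' @return Data frame with columns `metabotype`, `frequency`, `cumulative`
#'   (monotone non-decreasing; reaches 1 at n = 2^k).
#' @export
rank_metabotypes <- function(x, n = NULL) {
  f <- if (inherits(x, "composition_summary")) x$frequencies else x
  if (!inherits(f, "composition"))
    stop("'x' must be a composition or composition_summary")
  space <- names(f)
  if (is.null(n)) n <- length(space)
  if (n > length(space)) stop("n exceeds the metabotype space size")
  ord <- rank_order(as.numeric(f), space)[seq_len(n)]
  data.frame(metabotype = space[ord],
             frequency = as.numeric(f)[ord],
             cumulative = cumsum(as.numeric(f)[ord]),
             stringsAsFactors = FALSE)
}
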