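#' Construct a marker set
#'
#' A marker set is the ordered collection of biosynthetic markers carried on
#' independently segregating plasmids. The order is fixed and defines the bit
#' order of every metabotype mask: bit 1 (leftmost character) corresponds to
#' the first marker. The canonical four-marker configuration is
#' [semeco_markers()] with order HIS3, LEU2, URA3, MET15 (H, L, U, M).
#'
#' @param ids Character vector of unique marker identifiers (e.g. `"HIS3"`).
#' @param metabolites Character vector, same length, naming the metabolite
#'   whose biosynthesis each marker restores (e.g. `"histidine"`). Defaults
#'   to a built-in lookup for the common yeast markers, otherwise the
#'   lowercased id.
#' @return An object of class `marker_set`: a data frame with columns `id`
#'   and `metabolite`, one row per marker, in mask bit order.
#' @examples
#' marker_set(c("HIS3", "LEU2"))
#' semeco_markers()
#' @export
marker_set <- function(ids, metabolites = NULL) {
  ids <- as.character(ids)
  k <- length(ids)
  if (k < 1L || k > 8L)
    stop("a marker set must contain between 1 and 8 markers, got ", k)
  if (anyDuplicated(ids))
    stop("marker ids must be unique")
  if (is.null(metabolites)) {
    known <- c(HIS3 = "histidine", LEU2 = "leucine", URA3 = "uracil",
               MET15 = "methionine", MET17 = "methionine", TRP1 = "tryptophan",
               ADE2 = "adenine", LYS2 = "lysine", ura4 = "uracil")
    metabolites <- ifelse(ids %in% names(known), known[ids], tolower(ids))
  }
  metabolites <- as.character(metabolites)
  if (length(metabolites) != k)
    stop("'metabolites' must have one entry per marker")
  if (any(!nzchar(metabolites)))
    stop("metabolite names must be non-empty")
  structure(data.frame(id = ids, metabolite = unname(metabolites),
                       stringsAsFactors = FALSE),
            class = c("marker_set", "data.frame"))
}

#' @describeIn marker_set The canonical four-marker set HIS3, LEU2, URA3,
#'   MET15 complementing the his3/leu2/ura3/met15 deletion background.
#' @export
semeco_markers <- function() {
  marker_set(c("HIS3", "LEU2", "URA3", "MET15"))
}

#' Number of markers in a marker set
#' @param markers A [marker_set()].
#' @return Integer k.
#' @export
n_markers <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  nrow(markers)
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> k =", nrow(x), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# integer value of a mask string, e.g. "1101" -> 13
mask_value <- function(masks) strtoi(masks, base = 2L)

#' Number of plasmids retained in a metabotype mask
#'
#' @param masks Character vector of retention masks (`"1"` = retained).
#' @return Integer vector of retained-plasmid counts.
#' @export
retained_count <- function(masks) {
  vapply(strsplit(masks, ""), function(b) sum(b == "1"), integer(1))
}

check_mask <- function(mask, markers) {
  k <- n_markers(markers)
  if (length(mask) != 1L || !grepl(sprintf("^[01]{%d}$", k), mask))
    stop("metabotype mask must be a ", k, "-character string of 0/1, got '",
         mask, "'")
  mask
}

#' Enumerate all metabotypes of a marker set
#'
#' With k independently segregating plasmids a cell can be in any of the 2^k
#' retention states (metabotypes). Metabotypes are encoded as k-bit mask
#' strings in marker-set order, `"1"` = plasmid retained. The canonical
#' enumeration order is descending retained-plasmid count, then descending
#' mask value, so the full prototroph comes first and the all-lost type last.
#'
#' @param markers A [marker_set()].
#' @return Character vector of 2^k mask strings in canonical order.
#' @examples
#' enumerate_metabotypes(semeco_markers())        # 16 metabotypes
#' enumerate_metabotypes(marker_set(c("ura4", "LEU2")))  # 4 metabotypes
#' @export
enumerate_metabotypes <- function(markers) {
  k <- n_markers(markers)
  vals <- 0:(2^k - 1)
  masks <- vapply(vals, function(v)
    paste(as.integer(bitwAnd(bitwShiftR(v, (k - 1):0), 1L)), collapse = ""),
    character(1))
  masks[order(-retained_count(masks), -vals)]
}

#' Classify a metabotype against its marker set
#'
#' Reports how many plasmids the metabotype has lost, whether it is still a
#' prototroph, and which metabolites it must obtain externally. Metabolites
#' present in the growth medium (`supplemented`) are not externally required
#' in the nutritional sense that matters for growth arrest: a uracil
#' auxotroph on uracil-supplemented media is nutritionally autonomous.
#'
#' @param mask A metabotype mask string.
#' @param markers A [marker_set()].
#' @param supplemented Character vector of metabolite names supplied by the
#'   medium (must be metabolites of the marker set).
#' @return A list with `loss_count`, `is_prototroph`, and
#'   `externally_required` (character vector of metabolite names).
#' @examples
#' m <- semeco_markers()
#' classify_metabotype("1101", m)                  # ura3-delta: needs uracil
#' classify_metabotype("1101", m, supplemented = "uracil")
#' @export
classify_metabotype <- function(mask, markers, supplemented = character()) {
  check_mask(mask, markers)
  if (length(supplemented) &&
      !all(supplemented %in% markers$metabolite))
    stop("unknown supplemented metabolite(s): ",
         paste(setdiff(supplemented, markers$metabolite), collapse = ", "))
  bits <- strsplit(mask, "")[[1]] == "1"
  lost <- markers$metabolite[!bits]
  list(loss_count = sum(!bits),
       is_prototroph = all(bits),
       externally_required = setdiff(lost, supplemented))
}

#' Construct a composition vector
#'
#' A composition vector is a frequency distribution over the full 2^k
#' metabotype space at a given generation (doubling index). Frequencies are
#' stored as a named numeric vector in canonical metabotype order.
#'
#' @param freqs Named numeric vector of non-negative frequencies; names are
#'   metabotype masks. Missing metabotypes are filled with 0.
#' @param markers A [marker_set()].
#' @param generation Non-negative integer doubling index (default 0).
#' @return An object of class `composition`: named numeric vector over all
#'   2^k metabotypes summing to 1, with attributes `markers` and
#'   `generation`.
#' @seealso [validate_composition()] for renormalisation of raw weights.
#' @export
composition_vector <- function(freqs, markers, generation = 0L) {
  space <- enumerate_metabotypes(markers)
  if (is.null(names(freqs)))
    stop("'freqs' must be named by metabotype mask")
  bad <- setdiff(names(freqs), space)
  if (length(bad))
    stop("unknown metabotype mask(s): ", paste(bad, collapse = ", "))
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  f <- stats::setNames(numeric(length(space)), space)
  f[names(freqs)] <- freqs
  s <- sum(f)
  if (abs(s - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(s),
         "); use validate_composition() to renormalise raw weights")
  if (generation < 0) stop("generation must be >= 0")
  structure(f, markers = markers, generation = as.integer(generation),
            class = "composition")
}

#' Validate and renormalise raw metabotype weights
#'
#' Fills in missing metabotypes with weight 0 and renormalises to a proper
#' frequency distribution; the renormalisation factor applied is recorded in
#' the `renorm_factor` attribute.
#'
#' @inheritParams composition_vector
#' @param raw Named numeric vector of non-negative weights (counts or
#'   unnormalised frequencies), named by metabotype mask.
#' @return A `composition` (see [composition_vector()]) with attribute
#'   `renorm_factor` = 1 / sum(raw).
#' @examples
#' m <- marker_set(c("ura4", "LEU2"))
#' validate_composition(c("11" = 1, "10" = 1, "01" = 1, "00" = 1), m)
#' @export
validate_composition <- function(raw, markers, generation = 0L) {
  if (length(raw) == 0L || is.null(names(raw)))
    stop("'raw' must be a non-empty named vector of weights")
  if (any(raw < 0)) stop("weights must be non-negative")
  s <- sum(raw)
  if (s <= 0) stop("weights must contain at least one positive entry")
  out <- composition_vector(raw / s, markers, generation)
  attr(out, "renorm_factor") <- 1 / s
  out
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> k =", n_markers(attr(x, "markers")),
      " generation =", attr(x, "generation"), "\n")
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(round(v[v > 0 | seq_along(v) <= 4], 6))
  invisible(x)
}

#' @export
as.data.frame.composition <- function(x, ...) {
  data.frame(metabotype = names(x), frequency = as.numeric(x),
             generation = attr(x, "generation"), stringsAsFactors = FALSE)
}
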