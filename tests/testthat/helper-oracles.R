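# Independent brute-force oracles. These deliberately take different
# computational routes from the package implementation they check.

# Expected next-generation composition by explicit enumeration of every
# daughter loss pattern of every source metabotype: for each metabotype s
# and each subset of its retained plasmids, a daughter keeps exactly that
# subset with probability prod(kept: 1-m) * prod(lost: m). Division weights
# follow the regime; arrested cells persist undivided.
oracle_step <- function(freq, markers, rates, regime = "neutral",
                        supplemented = character()) {
  space <- names(freq)
  k <- nrow(markers)
  rates <- rates[markers$id]
  mass <- setNames(numeric(length(space)), space)
  for (s in space) {
    f <- freq[[s]]
    if (f == 0) next
    bits <- strsplit(s, "")[[1]] == "1"
    divides <- TRUE
    if (regime == "no_cooperation") {
      lost_mets <- markers$metabolite[!bits]
      divides <- length(setdiff(lost_mets, supplemented)) == 0L
    }
    if (!divides) {
      mass[s] <- mass[s] + f
      next
    }
    ret_idx <- which(bits)
    if (length(ret_idx) == 0L) {
      mass[s] <- mass[s] + 2 * f
      next
    }
    patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(ret_idx)))
    for (p in seq_len(nrow(patterns))) {
      keep <- as.logical(patterns[p, ])
      prob <- prod(ifelse(keep, 1 - rates[ret_idx], rates[ret_idx]))
      dbits <- rep(FALSE, k)
      dbits[ret_idx[keep]] <- TRUE
      dmask <- paste(as.integer(dbits), collapse = "")
      mass[dmask] <- mass[dmask] + 2 * f * prob
    }
  }
  mass / sum(mass)
}

oracle_trajectory <- function(markers, rates, generations,
                              regime = "neutral",
                              supplemented = character()) {
  space <- enumerate_metabotypes(markers)
  freq <- setNames(numeric(length(space)), space)
  freq[1L] <- 1
  out <- matrix(NA_real_, generations + 1L, length(space),
                dimnames = list(0:generations, space))
  out[1L, ] <- freq
  for (g in seq_len(generations)) {
    freq <- oracle_step(as.list(freq), markers, rates, regime, supplemented)
    out[g + 1L, ] <- freq
  }
  out
}

# Textbook sum-formula Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# All-pairs nearest prototroph distance for every auxotroph pixel.
oracle_nn_distances <- function(labels, pixel_size_um = 1) {
  pr <- which(labels == 1L, arr.ind = TRUE)
  ax <- which(labels == 2L, arr.ind = TRUE)
  if (nrow(pr) == 0L || nrow(ax) == 0L) return(numeric(0))
  d2 <- outer(ax[, 1], pr[, 1], `-`)^2 + outer(ax[, 2], pr[, 2], `-`)^2
  sqrt(apply(d2, 1, min)) * pixel_size_um
}
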