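# Segregation-rate estimation from replica-plating retention counts.

#' Assemble replica-plating observations
#'
#' One row per replicate plate: how many colony-forming units (CFUs) were
#' scored in total, how many still retained the marker (grew on the
#' selective plate), and how many doublings g separate the assayed
#' population from the fully retaining founder.
#'
#' @param marker Marker id (recycled).
#' @param total_cfu Integer CFUs scored per replicate.
#' @param retaining_cfu Integer CFUs retaining the marker, `<= total_cfu`.
#' @param generations Elapsed doublings g (> 0, may be non-integer;
#'   recycled).
#' @param replicate Replicate labels (default `"r1"`, `"r2"`, ...).
#' @return A data frame of class `replica_plating` with those five columns.
#' @export
replica_plating <- function(marker, total_cfu, retaining_cfu, generations,
                            replicate = NULL) {
  n <- max(length(total_cfu), length(retaining_cfu))
  if (is.null(replicate)) replicate <- paste0("r", seq_len(n))
  out <- data.frame(replicate = replicate,
                    marker = rep_len(as.character(marker), n),
                    total_cfu = rep_len(as.integer(total_cfu), n),
                    retaining_cfu = rep_len(as.integer(retaining_cfu), n),
                    generations = rep_len(as.numeric(generations), n),
                    stringsAsFactors = FALSE)
  if (any(out$total_cfu < 1)) stop("total_cfu must be >= 1")
  if (any(out$retaining_cfu < 0 | out$retaining_cfu > out$total_cfu))
    stop("retaining_cfu must lie in [0, total_cfu]")
  if (any(out$generations <= 0)) stop("generations must be > 0")
  class(out) <- c("replica_plating", "data.frame")
  out
}

#' Doublings elapsed between two cell counts
#'
#' g = log2(n_final / n_initial); the biomass-doubling count used throughout
#' the segregation model. Need not be an integer.
#'
#' @param n_initial,n_final Positive cell counts (or biomass proxies).
#' @return Number of doublings.
#' @examples
#' doublings_from_counts(1, 2^57)   # 57
#' doublings_from_counts(1, 10)     # 3.3219
#' @export
doublings_from_counts <- function(n_initial, n_final) {
  if (any(n_initial <= 0) || any(n_final <= 0))
    stop("cell counts must be positive")
  log2(n_final / n_initial)
}

#' Estimate per-division segregation rate from replica plating
#'
#' Under per-division loss probability m the fraction of cells still
#' retaining the plasmid after g doublings is F_g = F_0 (1 - m)^g, so each
#' replicate yields `m_hat = 1 - (F_g / F_0)^(1/g)`. Replicates of a marker
#' are pooled by the arithmetic mean; uncertainty is a seeded bootstrap
#' percentile interval obtained by resampling CFUs (binomially, at the
#' replicate's observed retention fraction) within each replicate.
#'
#' Replicates with zero retaining CFUs are degenerate in the log domain and
#' receive a continuity correction ((retaining + 0.5) / (total + 1)) with a
#' warning.
#'
#' @param obs A [replica_plating()] data frame (one or more markers).
#' @param F0 Retention fraction at g = 0 (default 1: cultures start under
#'   selection, every founder cell retains the plasmid).
#' @param n_boot Bootstrap resamples for the interval (default 1000; 0
#'   disables).
#' @param conf Interval coverage (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame of class `rate_estimate`, one row per marker:
#'   `marker`, `m_hat`, `lower`, `upper`, `n_replicates`.
#' @examples
#' obs <- replica_plating("URA3", 1000, 250, generations = 2)
#' estimate_segregation_rate(obs, n_boot = 0)   # m_hat = 0.5
#' @export
estimate_segregation_rate <- function(obs, F0 = 1, n_boot = 1000,
                                      conf = 0.95, seed = NULL) {
  stopifnot(inherits(obs, "data.frame"), nrow(obs) >= 1)
  if (F0 <= 0 || F0 > 1) stop("F0 must be in (0, 1]")
  retaining <- obs$retaining_cfu
  total <- obs$total_cfu
  zero <- retaining == 0
  if (any(zero)) {
    warning("replicate(s) with 0 retaining CFUs: applying continuity ",
            "correction (r + 0.5) / (n + 1)")
    retaining <- ifelse(zero, retaining + 0.5, retaining)
    total <- ifelse(zero, total + 1, total)
  }
  Fg <- retaining / total
  if (any(Fg > F0 + 1e-12))
    stop("observed retention fraction exceeds F0: inconsistent input")
  m_rep <- 1 - pmin(Fg / F0, 1)^(1 / obs$generations)
  per_marker <- split(seq_len(nrow(obs)), obs$marker)
  boot_one <- function(idx) {
    m_bs <- vapply(seq_along(idx), function(j) {
      i <- idx[j]
      r_star <- stats::rbinom(1L, total[i], Fg[i])
      r_star <- if (r_star == 0) 0.5 else r_star
      n_star <- if (r_star == 0.5) total[i] + 1 else total[i]
      1 - min(r_star / n_star / F0, 1)^(1 / obs$generations[i])
    }, numeric(1))
    mean(m_bs)
  }
  res <- with_seed(seed, {
    do.call(rbind, lapply(names(per_marker), function(mk) {
      idx <- per_marker[[mk]]
      m_hat <- mean(m_rep[idx])
      lo <- up <- NA_real_
      if (n_boot > 0) {
        bs <- vapply(seq_len(n_boot), function(b) boot_one(idx), numeric(1))
        qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                              names = FALSE)
        lo <- max(qs[1], 0); up <- min(qs[2], 1)
      }
      data.frame(marker = mk, m_hat = m_hat, lower = lo, upper = up,
                 n_replicates = length(idx), stringsAsFactors = FALSE)
    }))
  })
  class(res) <- c("rate_estimate", "data.frame")
  res
}

#' Equal per-plasmid rates from a total segregation rate
#'
#' Inverts [total_segregation_rate()] under the assumption of k equal
#' per-plasmid rates: returns `1 - (1 - total)^(1/k)`. Used to derive the
#' default per-plasmid rates from the measured 11% total of the four-plasmid
#' community.
#'
#' @param total Total per-division probability of losing >= 1 plasmid, in
#'   \[0, 1).
#' @param k Number of plasmids (>= 1).
#' @return Per-plasmid per-division loss probability.
#' @examples
#' equal_rates_from_total(0.11, 4)   # 0.0287
#' @export
equal_rates_from_total <- function(total, k) {
  stopifnot(k >= 1)
  if (total < 0 || total >= 1)
    stop("'total' must lie in [0, 1)")
  1 - (1 - total)^(1 / k)
}
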