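# Segregation dynamics: deterministic recursion and stochastic branching
# process over the 2^k metabotype space.

#' Validate per-plasmid segregation rates
#'
#' @param rates Named numeric vector of per-division loss probabilities, one
#'   per marker id of `markers`, each in \[0, 1\]. An unnamed vector of
#'   length k is accepted and named in marker order.
#' @param markers A [marker_set()].
#' @return Named numeric vector in marker order.
#' @export
segregation_rates <- function(rates, markers) {
  k <- n_markers(markers)
  if (is.null(names(rates))) {
    if (length(rates) != k)
      stop("unnamed 'rates' must have length k = ", k)
    names(rates) <- markers$id
  }
  missing <- setdiff(markers$id, names(rates))
  if (length(missing))
    stop("missing segregation rate for marker(s): ",
         paste(missing, collapse = ", "))
  rates <- rates[markers$id]
  if (any(rates < 0 | rates > 1))
    stop("segregation rates must lie in [0, 1]")
  rates
}

#' Scenario configuration for a segregation run
#'
#' Encodes the growth/selection regime a community experiences. Under
#' `neutral` and `cooperation` every cell divides regardless of genotype
#' (in the cooperating colony auxotrophs are fed by neighbours, so the two
#' regimes coincide at the composition level). Under `no_cooperation` only
#' cells whose nutritional requirements are fully covered (prototrophs, or
#' auxotrophs whose missing metabolites are all supplemented) divide;
#' arrested cells persist in the census but produce no daughters. Under
#' `fitness_weighted` user-supplied relative growth weights are used.
#'
#' @param regime One of `"neutral"`, `"no_cooperation"`, `"cooperation"`,
#'   `"fitness_weighted"`.
#' @param supplemented Character vector of metabolite names supplied by the
#'   medium.
#' @param fitness Named numeric vector of relative growth weights (>= 0) per
#'   metabotype mask; required iff `regime = "fitness_weighted"`.
#' @param bottleneck Optional `list(interval =, fraction =)`: every
#'   `interval` generations the population is subsampled without replacement
#'   to `fraction` of its size (stochastic runs only; deterministic
#'   frequencies are unaffected by unbiased subsampling and skip it).
#' @param seed Optional integer seed recorded for stochastic runs.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(regime = c("neutral", "no_cooperation",
                                       "cooperation", "fitness_weighted"),
                            supplemented = character(),
                            fitness = NULL, bottleneck = NULL, seed = NULL) {
  regime <- match.arg(regime)
  if (regime == "fitness_weighted") {
    if (is.null(fitness) || is.null(names(fitness)))
      stop("'fitness' (named by metabotype mask) is required for the ",
           "fitness_weighted regime")
    if (any(fitness < 0)) stop("fitness weights must be >= 0")
  } else if (!is.null(fitness)) {
    stop("'fitness' is only used with regime = 'fitness_weighted'")
  }
  if (!is.null(bottleneck)) {
    if (!is.list(bottleneck) ||
        !all(c("interval", "fraction") %in% names(bottleneck)))
      stop("'bottleneck' must be list(interval =, fraction =)")
    if (bottleneck$interval < 1)
      stop("bottleneck interval must be >= 1 generation")
    if (bottleneck$fraction <= 0 || bottleneck$fraction > 1)
      stop("bottleneck surviving fraction must be in (0, 1]")
  }
  structure(list(regime = regime, supplemented = supplemented,
                 fitness = fitness, bottleneck = bottleneck, seed = seed),
            class = "scenario_config")
}

#' Per-generation metabotype transition matrix
#'
#' Entry (s, s') is the probability that a daughter of a cell of metabotype
#' s is of metabotype s': the product over retained plasmids of keeping
#' (1 - m_i) or losing (m_i) each independently. Lost plasmids are never
#' regained, so the matrix is lower-triangular in canonical (loss-count)
#' order and every row sums to 1.
#'
#' @param markers A [marker_set()].
#' @param rates Per-plasmid loss probabilities (see [segregation_rates()]).
#' @return A 2^k x 2^k row-stochastic matrix with metabotype masks as
#'   dimnames.
#' @examples
#' m <- marker_set("URA3")
#' build_transition_matrix(m, c(URA3 = 0.5))
#' @export
build_transition_matrix <- function(markers, rates) {
  rates <- segregation_rates(rates, markers)
  space <- enumerate_metabotypes(markers)
  k <- n_markers(markers)
  bits <- t(vapply(strsplit(space, ""), function(b) b == "1", logical(k)))
  if (k == 1L) bits <- matrix(bits, ncol = 1L)
  n <- length(space)
  T <- matrix(0, n, n, dimnames = list(space, space))
  for (i in seq_len(n)) {
    ret <- bits[i, ]
    for (j in seq_len(n)) {
      dau <- bits[j, ]
      if (any(dau & !ret)) next  # resurrection impossible
      keep <- ret & dau
      lose <- ret & !dau
      T[i, j] <- prod(1 - rates[keep]) * prod(rates[lose])
    }
  }
  T
}

# Division weight per metabotype under a scenario, scaled to [0, 1].
growth_weights <- function(markers, scenario) {
  space <- enumerate_metabotypes(markers)
  w <- stats::setNames(rep(1, length(space)), space)
  if (scenario$regime == "no_cooperation") {
    for (s in space) {
      cl <- classify_metabotype(s, markers, scenario$supplemented)
      w[s] <- as.numeric(length(cl$externally_required) == 0L)
    }
  } else if (scenario$regime == "fitness_weighted") {
    f <- scenario$fitness
    bad <- setdiff(names(f), space)
    if (length(bad))
      stop("fitness names outside metabotype space: ",
           paste(bad, collapse = ", "))
    w[] <- 0
    w[names(f)] <- f
    if (max(w) > 0) w <- w / max(w)
  }
  w
}

#' Advance a composition by one generation
#'
#' Cells of metabotype s divide with weight w(s) determined by the scenario;
#' a dividing cell is replaced by two daughters whose metabotypes follow the
#' transition matrix, while a non-dividing cell persists unchanged. The
#' updated unnormalised mass is
#' `mass(s') = sum_s f(s) * ((1 - w(s)) * [s' == s] + 2 w(s) T[s, s'])`,
#' renormalised to frequencies. Under the neutral regime this reduces
#' exactly to `f' = f %*% T`.
#'
#' @param state A `composition` (see [composition_vector()]).
#' @param transition Matrix from [build_transition_matrix()].
#' @param scenario A [scenario_config()].
#' @param markers A [marker_set()].
#' @return The next-generation `composition`. If no frequency mass lies on
#'   a dividing metabotype the population cannot grow: the returned state
#'   carries attribute `status = "collapsed"` (the no-growth outcome), not
#'   an error.
#' @export
step_population <- function(state, transition, scenario, markers) {
  space <- enumerate_metabotypes(markers)
  stopifnot(identical(names(state), space),
            identical(rownames(transition), space))
  f <- as.numeric(state)
  w <- growth_weights(markers, scenario)
  if (sum(f * w) == 0) {
    out <- composition_vector(stats::setNames(f, space), markers,
                              attr(state, "generation") + 1L)
    attr(out, "status") <- "collapsed"
    return(out)
  }
  mass <- f * (1 - w) + as.numeric((2 * f * w) %*% transition)
  out <- composition_vector(stats::setNames(mass / sum(mass), space),
                            markers, attr(state, "generation") + 1L)
  attr(out, "status") <- "ok"
  out
}

new_trajectory <- function(freq, counts = NULL, markers, scenario, status,
                           seed = NULL) {
  structure(list(freq = freq, counts = counts, markers = markers,
                 scenario = scenario, status = status, seed = seed),
            class = "population_trajectory")
}

#' Deterministic segregation simulation
#'
#' Iterates the expected-composition recursion over generations, starting
#' from 100% prototrophs (or a supplied initial composition). This is the
#' infinite-population limit of the branching process in
#' [simulate_stochastic()]. Deterministic bottlenecks are frequency-neutral
#' (unbiased subsampling does not change expected frequencies) and are
#' skipped.
#'
#' @inheritParams build_transition_matrix
#' @param scenario A [scenario_config()].
#' @param generations Number of doublings G (>= 0).
#' @param init Optional initial `composition`; default all mass on the full
#'   prototroph.
#' @return A `population_trajectory` with a `(G+1) x 2^k` frequency matrix
#'   (rows = generations 0..G) and `status` `"ok"` or `"collapsed"`. After
#'   collapse the composition is frozen for the remaining generations.
#' @examples
#' m <- semeco_markers()
#' r <- equal_rates_from_total(0.11, 4)           # total rate 11%
#' traj <- simulate_deterministic(m, rep(r, 4), generations = 21)
#' 1 - traj$freq["21", "1111"]                    # > 0.90 segregated
#' @export
simulate_deterministic <- function(markers, rates,
                                   scenario = scenario_config(),
                                   generations, init = NULL) {
  stopifnot(generations >= 0)
  space <- enumerate_metabotypes(markers)
  T <- build_transition_matrix(markers, rates)
  if (is.null(init))
    init <- composition_vector(stats::setNames(1, space[1]), markers, 0L)
  stopifnot(identical(names(init), space))
  G <- as.integer(generations)
  freq <- matrix(NA_real_, G + 1L, length(space),
                 dimnames = list(0:G, space))
  freq[1L, ] <- as.numeric(init)
  status <- "ok"
  state <- init
  g <- 1L
  while (g <= G) {
    state <- step_population(state, T, scenario, markers)
    freq[g + 1L, ] <- as.numeric(state)
    if (identical(attr(state, "status"), "collapsed")) {
      status <- "collapsed"
      if (g < G) freq[(g + 2L):(G + 1L), ] <-
          matrix(as.numeric(state), G - g, length(space), byrow = TRUE)
      break
    }
    g <- g + 1L
  }
  new_trajectory(freq, NULL, markers, scenario, status)
}

# Binomial draw that stays valid beyond integer-sized counts: exact rbinom
# for sizes representable as R integers, rounded normal approximation above
# (relative error negligible at >2^31 trials).
rbinom_large <- function(size, prob) {
  if (size <= 0) return(0)
  if (prob <= 0) return(0)
  if (prob >= 1) return(size)
  if (size <= .Machine$integer.max)
    return(as.numeric(stats::rbinom(1L, as.integer(size), prob)))
  mu <- size * prob
  sd <- sqrt(size * prob * (1 - prob))
  min(max(round(stats::rnorm(1L, mu, sd)), 0), size)
}

# Multinomial draw via the binomial chain, valid for very large totals.
rmultinom_large <- function(size, prob) {
  n <- length(prob)
  out <- numeric(n)
  rem <- size
  prem <- sum(prob)
  for (j in seq_len(n - 1L)) {
    if (rem <= 0 || prem <= 0) break
    out[j] <- rbinom_large(rem, min(prob[j] / prem, 1))
    rem <- rem - out[j]
    prem <- prem - prob[j]
  }
  out[n] <- rem
  out
}

# Multivariate hypergeometric subsample: draw 'size' cells without
# replacement from per-class counts.
rmvhyper <- function(counts, size) {
  n <- length(counts)
  out <- numeric(n)
  rem <- size
  pool <- sum(counts) - counts[1]
  for (j in seq_len(n - 1L)) {
    if (rem <= 0) break
    m <- counts[j]
    if (m + pool <= .Machine$integer.max && rem <= .Machine$integer.max) {
      out[j] <- as.numeric(stats::rhyper(1L, as.integer(m),
                                         as.integer(pool), as.integer(rem)))
    } else {
      out[j] <- rbinom_large(rem, m / (m + pool))  # large-pool limit
    }
    rem <- rem - out[j]
    if (j < n) pool <- pool - counts[j + 1L]
  }
  out[n] <- rem
  out
}

#' Stochastic (branching-process) segregation simulation
#'
#' Agent-level model tracked as per-metabotype cell counts: each generation
#' every dividing cell is replaced by two daughters, and each daughter
#' independently loses each retained plasmid i with probability m_i. Under
#' `no_cooperation` nutritionally arrested cells persist undivided; under
#' `fitness_weighted` each cell divides with probability equal to its scaled
#' weight. Bottlenecks subsample cells without replacement (multivariate
#' hypergeometric) every `interval` generations.
#'
#' @inheritParams simulate_deterministic
#' @param n0 Initial number of cells (all full prototrophs unless `init`
#'   gives an initial composition to be multinomially seeded).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return A `population_trajectory` with realised frequencies (`$freq`),
#'   absolute counts (`$counts`), and `status` one of `"ok"`, `"collapsed"`
#'   (no dividing cells remain), or `"extinct"` (0 cells after a
#'   bottleneck). Rows after extinction have zero counts and `NA`
#'   frequencies.
#' @export
simulate_stochastic <- function(markers, rates, scenario = scenario_config(),
                                n0, generations, seed, init = NULL) {
  stopifnot(n0 >= 1, generations >= 0)
  space <- enumerate_metabotypes(markers)
  T <- build_transition_matrix(markers, rates)
  w <- growth_weights(markers, scenario)
  with_seed(seed, {
    counts0 <- stats::setNames(numeric(length(space)), space)
    if (is.null(init)) {
      counts0[1L] <- n0
    } else {
      stopifnot(identical(names(init), space))
      counts0[] <- rmultinom_large(n0, as.numeric(init))
    }
    G <- as.integer(generations)
    cnt <- matrix(NA_real_, G + 1L, length(space),
                  dimnames = list(0:G, space))
    cnt[1L, ] <- counts0
    status <- "ok"
    cur <- counts0
    bn <- scenario$bottleneck
    for (g in seq_len(G)) {
      if (sum(cur) == 0) { cnt[g + 1L, ] <- 0; next }
      if (sum(cur * w) == 0) {
        status <- "collapsed"
        cnt[g + 1L, ] <- cur
        next
      }
      nxt <- stats::setNames(numeric(length(space)), space)
      for (i in seq_along(space)) {
        if (cur[i] == 0) next
        ndiv <- if (w[i] >= 1) cur[i] else rbinom_large(cur[i], w[i])
        nxt <- nxt + rmultinom_large(2 * ndiv, T[i, ])
        nxt[i] <- nxt[i] + (cur[i] - ndiv)  # arrested cells persist
      }
      cur <- nxt
      if (!is.null(bn) && g %% bn$interval == 0L) {
        keep <- round(bn$fraction * sum(cur))
        cur <- stats::setNames(rmvhyper(cur, keep), space)
        if (sum(cur) == 0) status <- "extinct"
      }
      cnt[g + 1L, ] <- cur
    }
    freq <- cnt / rowSums(cnt)
    new_trajectory(freq, cnt, markers, scenario, status, seed = seed)
  })
}

#' Marginal plasmid retention probability
#'
#' Probability that a single plasmid with per-division loss rate m is still
#' present after g doublings: (1 - m)^g. Under the neutral regime this is
#' the exact marginal of the full recursion.
#'
#' @param m Per-division loss probability in \[0, 1\].
#' @param g Number of doublings (>= 0, may be non-integer).
#' @return Retention probability.
#' @examples
#' marginal_retention(0.02, 10)   # 0.8171
#' @export
marginal_retention <- function(m, g) {
  stopifnot(all(m >= 0 & m <= 1), all(g >= 0))
  (1 - m)^g
}

#' Total segregation rate of a plasmid set
#'
#' Per-division probability of losing at least one of the plasmids:
#' `1 - prod(1 - m_i)`. The four-plasmid community of interest has a total
#' rate of 0.11 (retention of all four plasmids 0.89 per division).
#'
#' @param rates Numeric vector of per-plasmid loss probabilities.
#' @return Probability in \[0, 1\].
#' @seealso [equal_rates_from_total()] for the inverse under equal rates.
#' @export
total_segregation_rate <- function(rates) {
  stopifnot(all(rates >= 0 & rates <= 1))
  1 - prod(1 - rates)
}

#' @export
print.population_trajectory <- function(x, ...) {
  G <- nrow(x$freq) - 1L
  cat("<population_trajectory>", G, "generations,",
      ncol(x$freq), "metabotypes, regime =", x$scenario$regime,
      ", status =", x$status, "\n")
  cat("  prototroph frequency: g0 =", signif(x$freq[1L, 1L], 4),
      " gG =", signif(x$freq[G + 1L, 1L], 4), "\n")
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' @param x A `population_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `generation`, `metabotype`, `frequency`
#'   and, for stochastic runs, `count`.
#' @export
as.data.frame.population_trajectory <- function(x, ...) {
  gens <- as.integer(rownames(x$freq))
  out <- data.frame(
    generation = rep(gens, times = ncol(x$freq)),
    metabotype = rep(colnames(x$freq), each = length(gens)),
    frequency = as.numeric(x$freq),
    stringsAsFactors = FALSE)
  if (!is.null(x$counts)) out$count <- as.numeric(x$counts)
  out[order(out$generation), , drop = FALSE]
}
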