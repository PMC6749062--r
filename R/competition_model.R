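# Serial-transfer co-culture competition: forward model for marked-cell
# fractions under a per-generation selection coefficient, and the inverse
# estimator.
#
# The deterministic core is multiplicative in the odds: with a fraction f of
# unmarked (focal) cells, odds = f/(1-f) multiply by (1+s)^g per transfer
# cycle, where g is the number of generations per cycle. At a 1% transfer
# (100-fold dilution) both competitors regrow ~log2(100) = 6.64 generations
# per cycle when their frequencies are comparable.

#' Co-culture configuration
#'
#' @param dilution Fold-dilution at each transfer (default 100, i.e. 1%
#'   volume transferred).
#' @param cycles Number of daily transfer cycles (default 8).
#' @param measured_cycles Cycles at which the marked fraction is read
#'   (default `c(0, 2, 5, 8)`).
#' @param generations_per_cycle Generations of growth per cycle; default
#'   `log2(dilution)`. Set to 10 to reproduce division-rate back-calculations
#'   that assume ~10 doublings per saturated batch.
#' @param events Flow-cytometry events counted per measurement (default
#'   10000); the observed fraction is binomial around the truth.
#' @param replicates Independent co-cultures per strain (default 3).
#' @param misclassification Probability that an event is scored in the wrong
#'   gate (symmetric; default 0).
#' @param initial_fraction Starting unmarked-cell fraction (default 0.5,
#'   an approximately equal inoculum).
#' @return A list of class `coculture_config`.
#' @export
coculture_config <- function(dilution = 100, cycles = 8,
                             measured_cycles = c(0, 2, 5, 8),
                             generations_per_cycle = log2(dilution),
                             events = 10000, replicates = 3,
                             misclassification = 0,
                             initial_fraction = 0.5) {
  stopifnot(dilution > 1, cycles >= 1, generations_per_cycle > 0,
            events >= 1, replicates >= 1,
            misclassification >= 0, misclassification < 0.5,
            initial_fraction > 0, initial_fraction < 1,
            all(measured_cycles >= 0), all(measured_cycles <= cycles))
  structure(as.list(environment()), class = "coculture_config")
}

# True focal fraction after `cycle` transfer cycles at selection s.
true_fraction <- function(s, cycle, cfg) {
  odds0 <- cfg$initial_fraction / (1 - cfg$initial_fraction)
  odds <- odds0 * (1 + s)^(cfg$generations_per_cycle * cycle)
  odds / (1 + odds)
}

#' Simulate a co-culture competition trajectory
#'
#' @param s Per-generation selection coefficient of the focal (unmarked)
#'   strain relative to the marked reference; `|s| < 0.5`.
#' @param cfg A [coculture_config()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `competition_trajectory` with `cycles`, `true`
#'   (true fractions at the measured cycles) and `observed` (replicates x
#'   cycle matrix of measured fractions).
#' @export
simulate_coculture <- function(s, cfg = coculture_config(), seed = NULL) {
  stopifnot(abs(s) < 0.5)
  if (!is.null(seed)) set.seed(seed)
  truth <- true_fraction(s, cfg$measured_cycles, cfg)
  e <- cfg$misclassification
  p_obs <- truth * (1 - e) + (1 - truth) * e
  observed <- matrix(stats::rbinom(cfg$replicates * length(truth),
                                   cfg$events,
                                   rep(p_obs, each = cfg$replicates)) /
                       cfg$events,
                     nrow = cfg$replicates)
  colnames(observed) <- paste0("c", cfg$measured_cycles)
  structure(list(cycles = cfg$measured_cycles, true = truth,
                 observed = observed, s = s),
            class = "competition_trajectory")
}

#' Estimate the selection coefficient from a trajectory
#'
#' Least-squares regression of `ln(odds)` of the mean observed fraction on
#' transfer cycle; the slope `b` converts to a per-generation coefficient as
#' `s = exp(b/g) - 1`. Measurements at 0 or 1 are dropped; at least two
#' usable cycles are required.
#'
#' @param traj A `competition_trajectory`, or a numeric vector of fractions
#'   (one per measured cycle).
#' @param cfg The [coculture_config()] used (supplies `g` and the cycle
#'   labels when `traj` is a bare vector).
#' @return Named vector `c(s_hat, se)`; `se` is delta-method propagated from
#'   the regression slope.
#' @export
estimate_selection <- function(traj, cfg = coculture_config()) {
  if (inherits(traj, "competition_trajectory")) {
    f <- colMeans(traj$observed)
    cyc <- traj$cycles
  } else {
    f <- as.numeric(traj)
    cyc <- cfg$measured_cycles
    if (length(f) != length(cyc))
      stop("fraction vector length does not match measured cycles")
  }
  ok <- f > 0 & f < 1
  f <- f[ok]; cyc <- cyc[ok]
  if (length(f) < 2) stop("fewer than 2 usable measurements strictly inside (0, 1)")
  lo <- log(f / (1 - f))
  fit <- stats::lm(lo ~ cyc)
  b <- unname(stats::coef(fit)[2])
  se_b <- if (length(f) > 2) summary(fit)$coefficients[2, 2] else NA_real_
  g <- cfg$generations_per_cycle
  s_hat <- exp(b / g) - 1
  se <- if (is.na(se_b)) NA_real_ else se_b / g * exp(b / g)
  c(s_hat = s_hat, se = se)
}

#' Selection coefficient required to reach a target fraction
#'
#' Closed-form inverse of the odds-multiplication model from a 50:50 start:
#' `s = exp(ln(f/(1-f)) / (cycle * g)) - 1`. With ~10 generations per cycle a
#' strain at 90% of the co-culture by cycle 8 needs only a ~2.8% faster
#' division rate; with `g = log2(100)` the same endpoint implies ~4.2%.
#'
#' @param f_target Target focal fraction, strictly inside (0, 1).
#' @param cycle Transfer cycle at which the target is reached.
#' @param cfg A [coculture_config()].
#' @return The per-generation selection coefficient.
#' @export
required_s <- function(f_target, cycle, cfg = coculture_config()) {
  if (f_target <= 0 || f_target >= 1) stop("target fraction must be inside (0, 1)")
  stopifnot(cycle >= 1)
  exp(log(f_target / (1 - f_target)) /
        (cycle * cfg$generations_per_cycle)) - 1
}

#' Simulate control co-cultures with emerging beneficial mutants
#'
#' Long neutral control competitions stay at 50:50 until a spontaneous
#' beneficial mutation arises in either competitor and expands. Each cycle a
#' mutant lineage appears in each competitor with probability
#' `mutation_rate`, starting at `mutant_init` of that competitor's cells and
#' thereafter gaining `mutant_s` per generation on everyone else.
#'
#' @param cfg A [coculture_config()]; only `generations_per_cycle` is used.
#' @param mutation_rate Per-cycle probability a beneficial lineage arises in
#'   each competitor.
#' @param mutant_s Per-generation advantage of a mutant lineage.
#' @param cycles Total cycles to run (default 22, measured weekly in the
#'   control design).
#' @param measured_cycles Cycles reported (default `c(0, 8, 15, 22)`).
#' @param mutant_init Initial frequency of a new mutant lineage within its
#'   competitor (default 1e-6).
#' @param seed Integer seed.
#' @return `data.frame` with `cycle` and `fraction` (focal competitor's
#'   fraction, mutants included), plus attribute `mutant_cycles`.
#' @export
simulate_control_divergence <- function(cfg = coculture_config(),
                                        mutation_rate = 0.02,
                                        mutant_s = 0.05, cycles = 22,
                                        measured_cycles = c(0, 8, 15, 22),
                                        mutant_init = 1e-6, seed = NULL) {
  stopifnot(cycles >= max(measured_cycles))
  if (!is.null(seed)) set.seed(seed)
  g <- cfg$generations_per_cycle
  # four lineages: focal wild-type, focal mutant, reference wild-type,
  # reference mutant; relative abundances renormalized each cycle
  ab <- c(fw = 0.5, fm = 0, rw = 0.5, rm = 0)
  fit <- c(fw = 1, fm = 1 + mutant_s, rw = 1, rm = 1 + mutant_s)
  mutant_cycles <- c(focal = NA_integer_, reference = NA_integer_)
  frac <- numeric(cycles + 1)
  frac[1] <- 0.5
  for (cy in seq_len(cycles)) {
    if (ab["fm"] == 0 && stats::runif(1) < mutation_rate) {
      ab["fm"] <- ab["fw"] * mutant_init
      mutant_cycles["focal"] <- cy
    }
    if (ab["rm"] == 0 && stats::runif(1) < mutation_rate) {
      ab["rm"] <- ab["rw"] * mutant_init
      mutant_cycles["reference"] <- cy
    }
    ab <- ab * fit^g
    ab <- ab / sum(ab)
    frac[cy + 1] <- ab["fw"] + ab["fm"]
  }
  out <- data.frame(cycle = measured_cycles,
                    fraction = frac[measured_cycles + 1])
  attr(out, "mutant_cycles") <- mutant_cycles
  out
}

#' Competition trajectories for a table of strain selection coefficients
#'
#' @param s Named numeric vector of per-generation selection coefficients.
#' @param cfg A [coculture_config()].
#' @param seed Integer seed.
#' @return A list with `trajectories` (long `data.frame`: strain, replicate,
#'   cycle, fraction) and `summary` (per strain: mean fraction per measured
#'   cycle, `s_hat`, `se`).
#' @export
compete_strains <- function(s, cfg = coculture_config(), seed = 1L) {
  set.seed(seed)
  strains <- names(s)
  if (is.null(strains)) strains <- sprintf("strain%02d", seq_along(s))
  traj_rows <- list(); summ_rows <- list()
  for (i in seq_along(s)) {
    tr <- simulate_coculture(s[i], cfg)
    long <- expand.grid(replicate = seq_len(cfg$replicates),
                        cycle = cfg$measured_cycles)
    long$fraction <- as.vector(tr$observed)
    long$strain <- strains[i]
    traj_rows[[i]] <- long[, c("strain", "replicate", "cycle", "fraction")]
    est <- estimate_selection(tr, cfg)
    mean_f <- colMeans(tr$observed)
    summ_rows[[i]] <- data.frame(strain = strains[i],
                                 t(as.matrix(mean_f)),
                                 s_hat = est[["s_hat"]], se = est[["se"]])
  }
  list(trajectories = do.call(rbind, traj_rows),
       summary = do.call(rbind, summ_rows))
}
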