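# Analysis layer: event-time distributions, persistence-length estimation and
# bending-rigidity calibration, packing fraction, intracapsid nematic order.

#' Event-time distribution of an ensemble
#'
#' Histogram of completed event times plus an explicit terminal bin for
#' replicates that hit the `max_steps` budget (timeouts are binned at the
#' budget edge, never dropped - an all-timeout ensemble is a pure spike
#' there). Summary statistics are reported both over completed runs only and
#' with timeouts censored at the budget.
#'
#' @param records a list of `run_record`s or an `ensemble_result`.
#' @param breaks histogram breaks in MD steps (default: 12 equal bins up to
#'   the budget).
#' @return An object of class `event_time_distribution` with fields
#'   `histogram` (counts/mids), `timeout_count`, `event_times`, and summary
#'   statistics `mean_completed`, `median_completed`, `sem_completed`,
#'   `mean_censored`.
#' @export
event_time_distribution <- function(records, breaks = NULL) {
  if (inherits(records, "ensemble_result")) records <- records$records
  records <- Filter(function(r) r$status != "failed", records)
  if (!length(records))
    .pp_error("phagepack_invalid_value", "need at least one record")
  ev <- vapply(records, function(r) r$event_time %||% NA_real_, numeric(1))
  budget <- max(vapply(records, function(r) r$max_steps, numeric(1)))
  completed <- ev[!is.na(ev)]
  if (is.null(breaks)) breaks <- seq(0, budget, length.out = 13)
  h <- if (length(completed))
    graphics::hist(completed, breaks = breaks, plot = FALSE)
  else list(counts = integer(length(breaks) - 1),
            mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
            breaks = breaks)
  censored <- ev
  censored[is.na(censored)] <- budget
  structure(
    list(histogram = list(counts = h$counts, mids = h$mids,
                          breaks = h$breaks),
         timeout_count = sum(is.na(ev)),
         budget = budget,
         event_times = ev,
         mean_completed = if (length(completed)) mean(completed) else NA_real_,
         median_completed = if (length(completed)) median(completed) else NA_real_,
         sem_completed = if (length(completed) > 1)
           sd(completed) / sqrt(length(completed)) else NA_real_,
         mean_censored = mean(censored)),
    class = "event_time_distribution"
  )
}

#' @export
print.event_time_distribution <- function(x, ...) {
  n <- length(x$event_times)
  cat(sprintf("event_time_distribution: %d run(s), %d timeout(s) at budget %g\n",
              n, x$timeout_count, x$budget))
  if (!is.na(x$mean_completed))
    cat(sprintf("  completed: mean %.4g, median %.4g MD steps\n",
                x$mean_completed, x$median_completed))
  cat(sprintf("  censored-at-budget mean: %.4g MD steps\n", x$mean_censored))
  invisible(x)
}

#' Sample decorrelated free-chain conformations
#'
#' Langevin (BAOAB) sampling of the bead-spring chain with no capsid and no
#' solvent - equilibrium conformational statistics do not depend on the
#' dynamics, so this cheap thermostat stands in for the full SRD machinery
#' during calibration.
#'
#' @param n_beads chain length.
#' @param params an [interaction_params()].
#' @param reduced_temperature T*.
#' @param n_conformations total number of stored conformations.
#' @param stride MD steps between stored conformations.
#' @param n_equil discarded equilibration steps per replica.
#' @param friction Langevin friction, 1/tau.
#' @param dt MD time step.
#' @param seed integer seed.
#' @param n_replicas number of independent trajectories (each initialized
#'   from a fresh worm-like-chain draw) over which the conformations are
#'   split; more replicas means less serial correlation per sample.
#' @return An `n_beads` x 3 x `n_conformations` array.
#' @export
sample_free_chain <- function(n_beads = 100, params = interaction_params(),
                              reduced_temperature = 1,
                              n_conformations = 500, stride = 2000,
                              n_equil = 2e4, friction = 1, dt = 0.005,
                              seed = 1, n_replicas = 1) {
  n_replicas <- max(1L, as.integer(n_replicas))
  per <- diff(round(seq(0, n_conformations, length.out = n_replicas + 1)))
  chunks <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    if (per[r] == 0) next
    chunks[[r]] <- cpp_langevin_chain(
      as.integer(n_beads), unclass(params), reduced_temperature, friction,
      dt, as.double(n_equil), as.integer(per[r]), as.double(stride),
      as.double(derive_seed(seed, 7000 + r)), 7)
  }
  chunks <- Filter(Negate(is.null), chunks)
  out <- array(unlist(chunks), dim = c(n_beads, 3, n_conformations))
  out
}

.bond_correlations <- function(conformations, max_s) {
  d <- dim(conformations)
  nb <- d[1] - 1
  max_s <- min(max_s, nb - 1)
  corr <- matrix(NA_real_, dim(conformations)[3], max_s)
  blen <- numeric(dim(conformations)[3])
  for (m in seq_len(d[3])) {
    p <- conformations[, , m]
    bv <- p[-1, , drop = FALSE] - p[-d[1], , drop = FALSE]
    bn <- sqrt(rowSums(bv^2))
    u <- bv / bn
    blen[m] <- mean(bn)
    for (s in seq_len(max_s))
      corr[m, s] <- mean(rowSums(u[1:(nb - s), , drop = FALSE] *
                                   u[(1 + s):nb, , drop = FALSE]))
  }
  list(corr = corr, bond_length = mean(blen))
}

#' Persistence length from bond-direction correlations
#'
#' Fits the exponential decay `<cos theta(s)> = exp(-s b / l_p)` of the
#' bond-direction correlation over contour separations `s` (in bonds, with
#' `b` the mean bond length) by log-linear least squares on the fit window,
#' and bootstraps over conformations for a standard error. Non-decaying
#' correlations (a rigid rod) yield an infinite estimate, flagged in the
#' result.
#'
#' @param conformations an N x 3 x M array of chain conformations (at least
#'   100 decorrelated samples recommended).
#' @param fit_window contour separations (bonds) used in the fit.
#' @param n_boot bootstrap resamples.
#' @return An object of class `lp_estimate`: list with `lp` (sigma), `se`,
#'   `bond_length`, `correlation` (the mean decay curve), `fit_window` and
#'   `flag` (`"ok"` or `"non_decaying"`).
#' @export
persistence_length_estimate <- function(conformations, fit_window = 1:15,
                                        n_boot = 200) {
  stopifnot(length(dim(conformations)) == 3, dim(conformations)[2] == 3)
  bc <- .bond_correlations(conformations, max(fit_window))
  fit_one <- function(rows) {
    cs <- colMeans(bc$corr[rows, , drop = FALSE])
    s <- fit_window[fit_window <= length(cs)]
    cs <- cs[s]
    pos <- cs > 0
    if (sum(pos) < 3) return(NA_real_)
    # weights ~ C(s)^2: the sampling noise is homoscedastic in C, so on the
    # log scale the large-s points are the noisiest
    slope <- coef(lm(log(cs[pos]) ~ s[pos], weights = cs[pos]^2))[2]
    if (slope >= -1e-8) return(Inf)
    -bc$bond_length / slope
  }
  M <- nrow(bc$corr)
  lp <- fit_one(seq_len(M))
  boots <- vapply(seq_len(n_boot), function(i) {
    set.seed(i)
    fit_one(sample.int(M, M, replace = TRUE))
  }, numeric(1))
  finite <- boots[is.finite(boots)]
  structure(
    list(lp = unname(lp),
         se = if (length(finite) > 1) sd(finite) else NA_real_,
         bond_length = bc$bond_length,
         correlation = colMeans(bc$corr),
         fit_window = fit_window,
         n_conformations = M,
         flag = if (!is.finite(lp)) "non_decaying" else "ok"),
    class = "lp_estimate"
  )
}

#' @export
print.lp_estimate <- function(x, ...) {
  if (x$flag == "non_decaying")
    cat("lp_estimate: non-decaying bond correlations (rigid-rod limit)\n")
  else
    cat(sprintf("lp_estimate: l_p = %.2f +/- %.2f sigma (b = %.3f, %d conformations)\n",
                x$lp, x$se, x$bond_length, x$n_conformations))
  invisible(x)
}

#' Mean cosine of the joint angle for an ideal semiflexible chain
#'
#' Closed form of the Boltzmann average of `cos theta` for a single joint
#' with energy `kappa (1 - cos theta)` at temperature T*:
#' `coth(k) - 1/k` with `k = kappa / T*` (the Langevin function of the
#' reduced stiffness). Used as the analytic oracle for ideal-chain bending
#' statistics.
#'
#' @param kappa bending constant, epsilon.
#' @param reduced_temperature T*.
#' @return Expected `cos theta`.
#' @export
ideal_chain_mean_cos <- function(kappa, reduced_temperature = 1) {
  k <- kappa / reduced_temperature
  ifelse(k < 1e-8, k / 3, 1 / tanh(k) - 1 / k)
}

#' Calibrate the bending rigidity to a target persistence length
#'
#' Monotone bisection on the bending constant: each trial runs a cheap
#' free-chain Langevin sampling and measures l_p by the bond-correlation fit,
#' until the achieved l_p is within `tolerance` of the target. The
#' first-order worm-like-chain relation `kappa ~ l_p T* / b` initializes the
#' bracket.
#'
#' @param target_lp target persistence length, sigma (must exceed the bond
#'   length).
#' @param tolerance acceptable |l_p - target|, sigma.
#' @param params base [interaction_params()] (the bending constant is
#'   overridden during the search).
#' @param reduced_temperature T*.
#' @param n_beads,n_conformations,stride,n_equil sampling controls per trial.
#' @param n_replicas independent trajectories per trial (see
#'   [sample_free_chain()]).
#' @param max_iter bisection iteration cap.
#' @param seed integer seed.
#' @return List with `kappa` (calibrated bending constant), `achieved_lp`,
#'   `se`, and the search `trace` (data frame kappa/lp).
#' @export
calibrate_bending_rigidity <- function(target_lp = 10, tolerance = 0.5,
                                       params = interaction_params(),
                                       reduced_temperature = 1,
                                       n_beads = 100, n_conformations = 320,
                                       stride = 2500, n_equil = 1e4,
                                       n_replicas = 40, max_iter = 12,
                                       seed = 1) {
  if (target_lp <= b_equil)
    .pp_error("phagepack_invalid_value",
              "target persistence length must exceed the bond length")
  kappa0 <- target_lp * reduced_temperature / b_equil
  lo <- 0.2 * kappa0
  hi <- 2.0 * kappa0
  # common random numbers across trials: the same three seed streams are
  # reused at every kappa, so sampling noise is shared along the bisection
  # path (monotone search) while averaging three independent streams keeps
  # the stream-level bias small
  measure <- function(kappa, s) {
    p <- params
    p$bend_kappa <- kappa
    ests <- lapply(1:3, function(k)
      persistence_length_estimate(
        sample_free_chain(n_beads, p, reduced_temperature,
                          n_conformations, stride, n_equil,
                          seed = derive_seed(seed, 100 + k),
                          n_replicas = n_replicas),
        n_boot = 10))
    lp <- mean(vapply(ests, `[[`, numeric(1), "lp"))
    list(lp = lp, se = sd(vapply(ests, `[[`, numeric(1), "lp")) / sqrt(3))
  }
  trace <- data.frame(kappa = numeric(0), lp = numeric(0))
  lp_lo <- measure(lo, 1)$lp
  lp_hi <- measure(hi, 2)$lp
  trace <- rbind(trace, data.frame(kappa = c(lo, hi), lp = c(lp_lo, lp_hi)))
  if (!(lp_lo < target_lp && lp_hi > target_lp))
    .pp_error("phagepack_nonbracketing",
              "search bounds [%g, %g] do not bracket the target (l_p %g, %g)",
              lo, hi, lp_lo, lp_hi)
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    est <- measure(mid, 10 + it)
    trace <- rbind(trace, data.frame(kappa = mid, lp = est$lp))
    best <- list(kappa = mid, achieved_lp = est$lp, se = est$se)
    if (abs(est$lp - target_lp) <= tolerance) break
    if (est$lp < target_lp) lo <- mid else hi <- mid
  }
  c(best, list(trace = trace, target_lp = target_lp, tolerance = tolerance))
}

#' Packing fraction of the capsid
#'
#' Total bead volume divided by the capsid sphere volume:
#' `N (sigma/2)^3 / R^3`. For N = 100 beads of diameter sigma in a sphere of
#' radius 3.02 sigma this evaluates to ~0.45.
#'
#' @param n_beads number of beads.
#' @param bead_diameter bead diameter, sigma.
#' @param capsid_radius capsid radius, sigma.
#' @return Packing fraction (dimensionless).
#' @export
packing_fraction <- function(n_beads, bead_diameter = 1,
                             capsid_radius = 3.02) {
  stopifnot(n_beads >= 0, bead_diameter > 0, capsid_radius > 0)
  n_beads * (pi / 6) * bead_diameter^3 /
    ((4 / 3) * pi * capsid_radius^3)
}

#' Intracapsid nematic order of the packed chain
#'
#' Largest eigenvalue of the nematic order tensor
#' `Q = <3/2 u u' - 1/2 I>` over the directions `u` of bonds whose two
#' endpoints both lie inside the capsid: 0 for an isotropic arrangement,
#' 1 for perfectly aligned bonds. A quantitative proxy for the visual
#' "ordered vs disordered" distinction between packed conformations.
#'
#' @param state a [system_state()], `run_record` (final conformation) or
#'   N x 3 position matrix.
#' @param assembly a [capsid_assembly()].
#' @return Scalar order parameter with attribute `"n_bonds"` (number of
#'   interior bonds used).
#' @export
intracapsid_order_metric <- function(state, assembly) {
  pos <- if (inherits(state, "system_state")) state$pos
         else if (inherits(state, "run_record")) state$final_pos
         else rbind_pos(state)
  reg <- classify_position(pos, assembly)
  inside <- reg == "inside_capsid"
  both_in <- inside[-length(inside)] & inside[-1]
  if (sum(both_in) < 2)
    .pp_error("phagepack_invalid_value",
              "need at least 2 bonds with both endpoints inside the capsid")
  bv <- pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]
  bv <- bv[both_in, , drop = FALSE]
  u <- bv / sqrt(rowSums(bv^2))
  Q <- 1.5 * crossprod(u) / nrow(u) - 0.5 * diag(3)
  s <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  attr(s, "n_bonds") <- nrow(u)
  s
}
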