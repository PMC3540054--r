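# Experiment drivers: initial configurations, equilibration, packing and
# ejection runs, and replicate ensembles with mean +/- SEM curves.
#
# Seed discipline: every replicate derives independent streams from the
# master seed via derive_seed(master, replicate * 10 + stage), stage 1 =
# placement, 2 = solvent, 3 = equilibration, 4 = production.

b_equil <- 0.97 # equilibrium bond length of the FENE + WCA pair, sigma

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 12), f)
  unname(tools::md5sum(f))
}

# self-avoiding worm-like-chain coil used for the outside chain: joint
# angles drawn from the exact bending Boltzmann weight at the run's kappa
# and T*, so the placed coil carries no stored elastic stress (a stiff
# artificial rod would recoil violently on release). Rejects the capsid
# interior, the wall shell, the tail cylinder and clashes with placed beads.
.grow_coil <- function(start, dir, n, assembly, placed, kappa_tilde, seed) {
  set.seed(seed)
  out <- matrix(NA_real_, n, 3)
  R <- assembly$capsid_radius
  kt <- max(kappa_tilde, 1e-8)
  blocked <- function(p) {
    r <- sqrt(sum(p^2))
    if (r < R + 0.6) return(TRUE)
    if (assembly$tail) {
      rho <- sqrt(p[1]^2 + p[2]^2)
      if (p[3] > R - 0.5 && p[3] < R + assembly$tail_length + 0.6 &&
          rho < assembly$tail_radius + 2.6)
        return(TRUE)
    }
    FALSE
  }
  wlc_step <- function(dir) {
    # cos(theta) from the inverse CDF of exp(kt * cos) sin(theta) d theta
    u <- runif(1)
    ct <- min(1, max(-1, 1 + log(u + (1 - u) * exp(-2 * kt)) / kt))
    st <- sqrt(1 - ct^2)
    phi <- runif(1, 0, 2 * pi)
    e1 <- if (abs(dir[3]) < 0.9) c(-dir[2], dir[1], 0) else c(0, -dir[3], dir[2])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
            dir[3] * e1[1] - dir[1] * e1[3],
            dir[1] * e1[2] - dir[2] * e1[1])
    ct * dir + st * (cos(phi) * e1 + sin(phi) * e2)
  }
  cur <- start
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:300) {
      d <- wlc_step(dir)
      cand <- cur + b_equil * d
      all_pts <- rbind(placed, out[seq_len(i - 1), , drop = FALSE])
      if (!blocked(cand) &&
          (nrow(all_pts) == 0 ||
           min(rowSums(sweep(all_pts, 2, cand)^2)) >= 0.9^2)) {
        out[i, ] <- cand
        dir <- d
        cur <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      .pp_error("phagepack_placement_failure",
                "could not place outside bead %d after bounded retries", i)
  }
  out
}

#' Initial state for a packing run
#'
#' Places bead 1 just inside the capsid below the pore, threads the next few
#' beads single-file out through the pore (and tail, when present), and grows
#' the remainder as a clash-free persistent coil outside. Bead velocities are
#' Maxwell-Boltzmann at the target temperature and the solvent is initialized
#' uniformly at the same temperature.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed (placement and solvent streams are derived
#'   from it; default: the config's seed).
#' @return A [system_state()] with occupancy `(1, 0)`: one bead inside, the
#'   rest outside.
#' @export
build_initial_packing_state <- function(config, seed = config$seed) {
  assembly <- assembly_from_config(config)
  N <- config$n_beads
  R <- assembly$capsid_radius
  # thread single-file until one bead is clear of the pore/tail region (the
  # coil grower rejects candidates inside it)
  top_z <- R + (if (assembly$tail) assembly$tail_length + 0.6 else 0.55)

  pos <- matrix(NA_real_, N, 3)
  pos[1, ] <- c(0, 0, R - 0.8)  # just inside, below the pore
  i <- 2
  z <- R - 0.8 + b_equil
  while (i <= N) {
    pos[i, ] <- c(0, 0, z)
    i <- i + 1
    if (z > top_z) break
    z <- z + b_equil
  }
  if (i <= N) {
    pos[i:N, ] <- .grow_coil(pos[i - 1, ], c(0, 0, 1), N - i + 1, assembly,
                             pos[seq_len(i - 1), , drop = FALSE],
                             config$interaction$bend_kappa /
                               config$reduced_temperature,
                             derive_seed(seed, 1))
  }
  set.seed(derive_seed(seed, 11))
  vel <- matrix(rnorm(3 * N, sd = sqrt(config$reduced_temperature)), N, 3)
  solvent <- init_solvent(srd_from_config(config), config$reduced_temperature,
                          derive_seed(seed, 2))
  system_state(pos, vel, solvent, step = 0, dt = config$integrator$dt,
               box_edge = config$srd$box_edge)
}

# Deterministic fully-packed configuration: the chain wound as an
# arc-length-parameterized spiral over concentric shells inside the capsid,
# starting at the pole under the pore (bead N, last in) and winding inward.
# Each shell is [start-pole point, theta-capped spiral, end-pole point];
# consecutive shells connect pole-to-pole on the same side (gap = shell
# spacing = bond length), and the polar caps keep ring radii large enough
# that no two sites come closer than ~0.92 sigma.
.spiral_shell <- function(r, b, from_top) {
  s <- if (from_top) 1 else -1
  if (r < 0.7) return(matrix(c(0, 0, s * r), 1, 3))
  # cap angle: pole-to-ring chord and ring radius both >= ~b
  thc <- max(2 * asin(min(1, b / (2 * r))), asin(min(1, 0.95 * b / r)))
  turns <- max(2, floor((pi - 2 * thc) * r / b))
  n_grid <- max(4000, turns * 600)
  u <- seq(0, 1, length.out = n_grid)
  th <- thc + u * (pi - 2 * thc)
  ph <- u * turns * 2 * pi
  p <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), s * r * cos(th))
  ds <- sqrt(rowSums((p[-1, ] - p[-n_grid, ])^2))
  arc <- c(0, cumsum(ds))
  keep <- integer(0)
  next_s <- 0
  for (j in seq_len(n_grid)) {
    if (arc[j] >= next_s) {
      # stop at spiral closure: never emit a site within 0.95 b of an
      # earlier one (degenerate equatorial rings close on themselves)
      if (length(keep) > 1 &&
          min(rowSums(sweep(p[keep[-length(keep)], , drop = FALSE], 2,
                            p[j, ])^2)) < (0.95 * b)^2)
        break
      keep <- c(keep, j)
      next_s <- arc[j] + b
    }
  }
  rbind(c(0, 0, s * r), p[keep, , drop = FALSE], c(0, 0, -s * r))
}

#' Construct a fully packed state
#'
#' Deterministic packed configuration: the chain is wound as a spiral over
#' concentric shells inside the capsid (shell spacing equal to the bond
#' length, so the configuration is clash-free by construction), with bead N -
#' the last bead packed - at the pole just under the pore. Used to seed
#' ejection runs without paying for a full packing run; `run_pack_then_eject()`
#' provides the sequential alternative.
#'
#' @inheritParams build_initial_packing_state
#' @return A [system_state()] with all `n_beads` bead centers inside the
#'   capsid sphere.
#' @export
build_packed_state <- function(config, seed = config$seed) {
  assembly <- assembly_from_config(config)
  N <- config$n_beads
  R <- assembly$capsid_radius
  # adaptive site spacing: start at the relaxed bond length and compress
  # (mild LJ overlap, relaxed during equilibration) until the winding fits
  total <- 0
  for (b_pack in c(0.97, 0.93, 0.89, 0.86)) {
    shells <- c()
    r <- R - 0.55
    while (r > 0.35) {
      shells <- c(shells, r)
      r <- r - b_pack
    }
    pts <- list()
    total <- 0
    for (j in seq_along(shells)) {
      sp <- .spiral_shell(shells[j], b_pack, from_top = (j %% 2 == 1))
      pts[[j]] <- sp
      total <- total + nrow(sp)
      if (total >= N) break
    }
    if (total < N && length(shells) && shells[length(shells)] > 0.95 * b_pack) {
      pts[[length(pts) + 1]] <- matrix(0, 1, 3)  # center site
      total <- total + 1
    }
    if (total >= N) break
  }
  if (total < N)
    .pp_error("phagepack_placement_failure",
              "capsid capacity exceeded: %d sites for %d beads", total, N)
  path <- do.call(rbind, pts)[seq_len(N), , drop = FALSE]
  bl <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-N, , drop = FALSE])^2))
  dm <- as.matrix(dist(path))
  diag(dm) <- Inf
  if (any(bl > 1.4) || min(dm) < 0.8)
    .pp_error("phagepack_placement_failure",
              "packed-spiral construction violated spacing (bond %.2f, min %.2f)",
              max(bl), min(dm))
  pos <- path[N:1, , drop = FALSE]  # bead N at the spiral start (pore pole)
  set.seed(derive_seed(seed, 12))
  vel <- matrix(rnorm(3 * N, sd = sqrt(config$reduced_temperature)), N, 3)
  solvent <- init_solvent(srd_from_config(config), config$reduced_temperature,
                          derive_seed(seed, 2))
  system_state(pos, vel, solvent, step = 0, dt = config$integrator$dt,
               box_edge = config$srd$box_edge)
}

#' Initial state for an ejection run
#'
#' Starting from a fully packed state (a completed packing run's final state,
#' or a constructed one from [build_packed_state()] when `packed_state` is
#' `NULL`), the chain is slid along its own contour so that the terminal
#' bead sits just past the capsid wall: outside the pore for a tailless
#' capsid (occupancy `(N - 1, 0)`), or in the tube lumen just above the
#' pore when the tail is present (occupancy `(N - 1, 1)`) - in both cases
#' the capsid holds N - 1 beads and the entire genome must still
#' translocate, through the full tail when one is attached.
#'
#' @inheritParams build_initial_packing_state
#' @param packed_state optional [system_state()] with all beads inside.
#' @return A [system_state()] ready for [equilibrate()] with the terminal
#'   bead anchored.
#' @export
build_initial_ejection_state <- function(config, packed_state = NULL,
                                         seed = config$seed) {
  assembly <- assembly_from_config(config)
  N <- config$n_beads
  R <- assembly$capsid_radius
  if (is.null(packed_state)) packed_state <- build_packed_state(config, seed)
  if (!all(sqrt(rowSums(packed_state$pos^2)) < R))
    .pp_error("phagepack_invalid_value",
              "packed_state must have every bead center inside the capsid")

  top_z <- packed_state$pos[N, 3]
  # one bead is moved just past the capsid wall: outside the pore (tailless)
  # or into the tube just above the pore (tailed) - either way the capsid
  # holds N - 1 beads and the whole genome still has to translocate
  zs <- R + assembly$wall_range + 0.05
  k <- length(zs)
  if (k >= N)
    .pp_error("phagepack_invalid_value", "chain shorter than the exit path")
  pos <- matrix(NA_real_, N, 3)
  pos[seq_len(N - k), ] <- packed_state$pos[(k + 1):N, , drop = FALSE]
  pos[(N - k + 1):N, ] <- cbind(0, 0, zs)

  state <- packed_state
  state$pos <- pos
  set.seed(derive_seed(seed, 13))
  state$vel <- matrix(rnorm(3 * N, sd = sqrt(config$reduced_temperature)), N, 3)
  state$step <- 0
  state
}

#' Equilibrate with an anchored bead
#'
#' Advances `equilibration_steps` MD steps with the motor off and the
#' designated anchor bead held fixed (packing: the single bead inside;
#' ejection: the terminal bead outside). The anchor is released on return.
#'
#' @param state a [system_state()].
#' @param config a [sim_config()].
#' @param anchor index of the bead to pin.
#' @param seed integer seed for the equilibration stream.
#' @return The equilibrated `system_state`.
#' @export
equilibrate <- function(state, config, anchor = 1, seed = config$seed) {
  hybrid_advance(state, config, config$equilibration_steps, motor_on = FALSE,
                 seed = derive_seed(seed, 3), anchor = anchor,
                 sample_stride = config$equilibration_steps)
}

.make_record <- function(state, config, mode, replicate_id, seed, start_step) {
  ts <- attr(state, "timeseries")
  ts$step <- ts$step - start_step
  ev <- attr(state, "event_step")
  status <- if (is.na(ev)) "timeout" else "completed"
  structure(
    list(replicate_id = replicate_id, mode = mode, timeseries = ts,
         event_time = if (is.na(ev)) NA_real_ else ev - start_step,
         status = status, seed = seed, config_hash = config_hash(config),
         max_steps = config$max_steps, n_beads = config$n_beads,
         dt = state$dt, final_pos = state$pos,
         mean_T = attr(state, "mean_T")),
    class = "run_record"
  )
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("run_record: %s replicate %s, %s%s\n", x$mode,
              format(x$replicate_id), x$status,
              if (x$status == "completed")
                sprintf(" at step %g (t = %g tau)", x$event_time,
                        x$event_time * x$dt) else ""))
  invisible(x)
}

#' Run a packing experiment
#'
#' Switches the motor on and advances until every bead center is inside the
#' capsid sphere (status `"completed"`, with the event time recorded) or the
#' `max_steps` budget is exhausted (status `"timeout"`).
#'
#' @param state an equilibrated packing [system_state()].
#' @param config a [sim_config()].
#' @param seed integer seed for the production stream.
#' @param replicate_id identifier stored in the record.
#' @return A `run_record`; the final state is attached as attribute
#'   `"state"`.
#' @export
run_packing <- function(state, config, seed = config$seed, replicate_id = 1L) {
  start <- state$step
  state <- hybrid_advance(state, config, config$max_steps, motor_on = TRUE,
                          seed = derive_seed(seed, 4),
                          sample_stride = config$sampling_stride,
                          stop_on = "packed")
  rec <- .make_record(state, config, "packing", replicate_id, seed, start)
  attr(rec, "state") <- state
  rec
}

#' Run an ejection experiment
#'
#' The feeding force is identically zero; the run advances until no bead
#' center remains inside the capsid or tail (status `"completed"`) or the
#' `max_steps` budget is exhausted (status `"timeout"`, the signature of
#' tail-trapped chains).
#'
#' @param state an equilibrated ejection [system_state()].
#' @inheritParams run_packing
#' @return A `run_record` with the final state attached as attribute
#'   `"state"`.
#' @export
run_ejection <- function(state, config, seed = config$seed, replicate_id = 1L) {
  start <- state$step
  state <- hybrid_advance(state, config, config$max_steps, motor_on = FALSE,
                          seed = derive_seed(seed, 4),
                          sample_stride = config$sampling_stride,
                          stop_on = "ejected")
  rec <- .make_record(state, config, "ejection", replicate_id, seed, start)
  attr(rec, "state") <- state
  rec
}

.one_replicate <- function(config, mode, r, master, ejection_source) {
  seed_r <- derive_seed(master, 1000 + r)
  if (mode == "packing") {
    st <- build_initial_packing_state(config, seed_r)
    st <- equilibrate(st, config, anchor = 1, seed = seed_r)
    run_packing(st, config, seed = seed_r, replicate_id = r)
  } else {
    packed <- if (ejection_source == "pack") {
      pk <- build_initial_packing_state(config, seed_r)
      pk <- equilibrate(pk, config, anchor = 1, seed = seed_r)
      attr(run_packing(pk, config, seed = seed_r, replicate_id = r), "state")
    } else NULL
    st <- build_initial_ejection_state(config, packed, seed_r)
    st <- equilibrate(st, config, anchor = config$n_beads, seed = seed_r)
    run_ejection(st, config, seed = seed_r, replicate_id = r)
  }
}

#' Run a replicate ensemble
#'
#' Runs `n_replicates` independent packing or ejection replicates (seeds
#' derived from the master seed) and aggregates them on a common time grid:
#' mean beads-inside(-plus-tail for ejection, reported separately) with the
#' standard error of the mean at every grid point, using
#' last-observation-carried-forward for completed replicates (a completed
#' packing run contributes N thereafter, a completed ejection run 0).
#'
#' @param config a [sim_config()].
#' @param mode `"packing"` or `"ejection"`.
#' @param n_replicates number of replicates (default from config).
#' @param seed master seed (default from config).
#' @param ejection_source `"construct"` seeds ejection from the deterministic
#'   packed configuration of [build_packed_state()]; `"pack"` runs a full
#'   packing first (the sequential protocol).
#' @param progress logical; print one line per replicate.
#' @return An `ensemble_result`: list with `records`, `grid` (data frame
#'   step/time/mean/sem/n_active), `event_times` (NA for timeouts),
#'   `completion_fraction`, `mode` and the config.
#' @export
run_ensemble <- function(config, mode = c("packing", "ejection"),
                         n_replicates = config$n_replicates,
                         seed = config$seed,
                         ejection_source = c("construct", "pack"),
                         progress = FALSE) {
  mode <- match.arg(mode)
  ejection_source <- match.arg(ejection_source)
  stopifnot(n_replicates >= 1)
  records <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    records[[r]] <- tryCatch(
      .one_replicate(config, mode, r, seed, ejection_source),
      error = function(e) {
        warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)),
                call. = FALSE)
        structure(list(replicate_id = r, mode = mode, status = "failed",
                       error = conditionMessage(e)), class = "run_record")
      })
    if (progress)
      message(sprintf("replicate %d/%d: %s", r, n_replicates,
                      records[[r]]$status))
  }
  aggregate_ensemble(records, config, mode)
}

#' Aggregate run records into an ensemble result
#'
#' @param records list of `run_record`s (failed replicates are reported and
#'   excluded from the curves).
#' @param config the shared [sim_config()].
#' @param mode `"packing"` or `"ejection"`.
#' @return An `ensemble_result`.
#' @export
aggregate_ensemble <- function(records, config, mode) {
  ok <- vapply(records, function(r) r$status != "failed", logical(1))
  used <- records[ok]
  if (!length(used))
    .pp_error("phagepack_invalid_value", "all replicates failed")
  N <- config$n_beads
  stride <- config$sampling_stride
  tmax <- max(vapply(used, function(r) max(r$timeseries$step), numeric(1)))
  grid <- seq(0, tmax, by = stride)
  locf <- function(rec, what) {
    ts <- rec$timeseries
    val <- ts$beads_inside + if (what == "total") ts$beads_in_tail else 0
    idx <- findInterval(grid, ts$step)
    out <- val[pmax(idx, 1)]
    if (rec$status == "completed") {
      after <- grid > rec$event_time
      out[after] <- if (mode == "packing") N else 0
    }
    out
  }
  curves <- vapply(used, locf, numeric(length(grid)),
                   what = if (mode == "ejection") "total" else "inside")
  curves <- matrix(curves, nrow = length(grid))
  m <- rowMeans(curves)
  sem <- if (ncol(curves) > 1) apply(curves, 1, sd) / sqrt(ncol(curves))
         else rep(0, length(grid))
  ev <- vapply(used, function(r) r$event_time %||% NA_real_, numeric(1))
  n_active <- vapply(grid, function(g)
    as.numeric(sum(is.na(ev) | ev > g)), numeric(1))
  structure(
    list(records = records,
         grid = data.frame(step = grid, time = grid * config$integrator$dt,
                           mean = m, sem = sem, n_active = n_active),
         event_times = ev,
         completion_fraction = mean(!is.na(ev)),
         n_failed = sum(!ok), mode = mode, config = config),
    class = "ensemble_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ensemble_result <- function(x, ...) {
  ev <- x$event_times
  cat(sprintf(
    "ensemble_result: %s, %d replicate(s)%s, completion fraction %.2f\n",
    x$mode, length(x$records),
    if (x$n_failed) sprintf(" (%d failed)", x$n_failed) else "",
    x$completion_fraction))
  if (any(!is.na(ev)))
    cat(sprintf("  completed event time: mean %.3g, median %.3g MD steps (n = %d)\n",
                mean(ev, na.rm = TRUE), median(ev, na.rm = TRUE),
                sum(!is.na(ev))))
  if (any(is.na(ev)))
    cat(sprintf("  %d replicate(s) hit the max_steps budget (timeout)\n",
                sum(is.na(ev))))
  invisible(x)
}

#' @export
plot.ensemble_result <- function(x, ...) {
  g <- x$grid
  ylab <- if (x$mode == "packing") "beads packed"
          else "beads remaining (capsid + tail)"
  graphics::plot(g$time, g$mean, type = "l",
                 xlab = "time (tau)", ylab = ylab, ...)
  graphics::arrows(g$time, g$mean - g$sem, g$time, g$mean + g$sem,
                   length = 0, col = "grey60")
  graphics::lines(g$time, g$mean)
  invisible(x)
}

#' Mean event time of an ensemble
#'
#' @param x an `ensemble_result`.
#' @param timeouts how to treat replicates that hit the budget:
#'   `"censor_at_budget"` counts them at `max_steps` (a lower bound on the
#'   true mean), `"exclude"` averages completed replicates only.
#' @return Mean event time in MD steps.
#' @export
mean_event_time <- function(x, timeouts = c("censor_at_budget", "exclude")) {
  timeouts <- match.arg(timeouts)
  ev <- x$event_times
  if (timeouts == "censor_at_budget")
    ev[is.na(ev)] <- x$config$max_steps
  mean(ev, na.rm = TRUE)
}

#' Run the sequential pack-then-eject protocol
#'
#' One replicate of the full protocol: build the packing initial state,
#' equilibrate with the first bead anchored, pack with the motor on, slide
#' the terminal bead back outside, re-equilibrate with it anchored, then
#' eject with the motor off.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return List with the packing and ejection `run_record`s.
#' @export
run_pack_then_eject <- function(config, seed = config$seed) {
  st <- build_initial_packing_state(config, seed)
  st <- equilibrate(st, config, anchor = 1, seed = seed)
  pk <- run_packing(st, config, seed = seed)
  if (pk$status != "completed")
    return(list(packing = pk, ejection = NULL))
  ej_state <- build_initial_ejection_state(config, attr(pk, "state"), seed)
  ej_state <- equilibrate(ej_state, config, anchor = config$n_beads,
                          seed = derive_seed(seed, 5))
  ej <- run_ejection(ej_state, config, seed = derive_seed(seed, 6))
  list(packing = pk, ejection = ej)
}
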