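# Trajectory and results I/O. Trajectories are multi-frame XYZ (universal
# viewer support, tiny bead counts); time series and ensemble curves are
# CSV; run manifests and summaries are JSON.

#' Write a multi-frame XYZ trajectory
#'
#' One frame per sampled [system_state()]. Element tags encode the bead role
#' (`C` polymer, `N` first bead, `O` anchor); the comment line carries the MD
#' step and the occupancy counts. Solvent particles are excluded unless
#' requested.
#'
#' @param states a [system_state()] or list of them.
#' @param path output file path.
#' @param assembly optional [capsid_assembly()] used for the occupancy
#'   comment.
#' @param anchor optional anchored bead index (tagged `O`).
#' @param include_solvent logical; append solvent particles as `H` entries.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(states, path, assembly = NULL, anchor = NA,
                             include_solvent = FALSE) {
  if (inherits(states, "system_state")) states <- list(states)
  if (!length(states))
    .pp_error("phagepack_invalid_value", "need at least one frame")
  con <- file(path, "w")
  on.exit(close(con))
  for (st in states) {
    n <- nrow(st$pos)
    ns <- if (include_solvent && !is.null(st$solvent)) nrow(st$solvent$pos) else 0
    occ <- if (!is.null(assembly)) count_occupancy(st, assembly)
           else c(inside = NA, tail = NA)
    writeLines(as.character(n + ns), con)
    writeLines(sprintf("step=%g beads_inside=%s beads_in_tail=%s", st$step,
                       occ[["inside"]], occ[["tail"]]), con)
    tags <- rep("C", n)
    tags[1] <- "N"
    if (!is.na(anchor)) tags[anchor] <- "O"
    writeLines(sprintf("%s %.8f %.8f %.8f", tags, st$pos[, 1], st$pos[, 2],
                       st$pos[, 3]), con)
    if (ns > 0)
      writeLines(sprintf("H %.8f %.8f %.8f", st$solvent$pos[, 1],
                         st$solvent$pos[, 2], st$solvent$pos[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path an XYZ file written by [write_trajectory()].
#' @return List of frames, each a list with `pos` (n x 3 matrix), `tags`,
#'   `step` and the raw `comment`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path))
    .pp_error("phagepack_missing_file", "no such file: %s", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    rows <- strsplit(lines[(i + 2):(i + 1 + n)], " +")
    pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    tags <- vapply(rows, `[`, "", 1)
    step <- suppressWarnings(as.numeric(sub(".*step=([0-9eE.+-]+).*", "\\1",
                                            comment)))
    frames[[length(frames) + 1]] <-
      list(pos = pos, tags = tags, step = step, comment = comment)
    i <- i + 2 + n
  }
  frames
}

#' Write per-replicate or ensemble time series as CSV
#'
#' A `run_record` yields columns `step, time, beads_inside, beads_in_tail`;
#' an `ensemble_result` yields `time, mean, sem, n_active`. Deterministic
#' column order, C locale numerals.
#'
#' @param x a `run_record` or `ensemble_result`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(x, path) {
  if (inherits(x, "run_record")) {
    if (x$status == "failed" || !nrow(x$timeseries))
      .pp_error("phagepack_invalid_value", "record has no time series")
    df <- data.frame(step = x$timeseries$step,
                     time = x$timeseries$step * x$dt,
                     beads_inside = x$timeseries$beads_inside,
                     beads_in_tail = x$timeseries$beads_in_tail)
  } else if (inherits(x, "ensemble_result")) {
    df <- x$grid[, c("time", "mean", "sem", "n_active")]
  } else {
    .pp_error("phagepack_invalid_value",
              "x must be a run_record or ensemble_result")
  }
  write.csv(format(df, trim = TRUE, scientific = FALSE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run bit-for-bit with the same build:
#' full config echo, master and derived seeds, package version, timestamps
#' and an inventory (with MD5 checksums) of the output files.
#'
#' @param config the [sim_config()] used.
#' @param out_dir directory whose files are inventoried.
#' @param seeds named list/vector of seeds used.
#' @param extra optional named list merged into the manifest.
#' @param path output path (default `manifest.json` in `out_dir`).
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(config, out_dir, seeds = list(),
                               extra = list(),
                               path = file.path(out_dir, "manifest.json")) {
  files <- setdiff(list.files(out_dir, full.names = TRUE), path)
  inventory <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f)),
         bytes = file.size(f)))
  manifest <- c(list(
    package = "phagepack",
    version = as.character(utils::packageVersion("phagepack")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    config_hash = config_hash(config),
    seeds = seeds,
    files = inventory
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  invisible(path)
}
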