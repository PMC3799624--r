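# Reading/writing of plain-text radial scan files (Beckman XL-A style
# two-header-line dialect), list files, run configurations, and batch
# summary tables; sorting of raw files into per-(cell, gain) scan sets.

#' A single radial scan
#'
#' One timestamped radius-to-signal trace from the fluorescence detector.
#'
#' @param radii strictly increasing radii, cm (uniform ~0.002 cm spacing in
#'   typical acquisitions)
#' @param signal detector counts, one per radius
#' @param time elapsed time since start of centrifugation, s
#' @param rpm rotor speed
#' @param temperature cell temperature, degrees C
#' @param cell integer sector id
#' @param gain amplifier gain (typically 1, 2, 4 or 8)
#' @param channel channel label
#' @param se optional per-point standard errors (third file column)
#' @param focal_um optional focal depth, micrometers
#' @param title free-text title line
#' @return object of class `radial_scan`
#' @export
radial_scan <- function(radii, signal, time, rpm, temperature = 20,
                        cell = 1L, gain = 1, channel = "A", se = NULL,
                        focal_um = NA_real_, title = NULL) {
  radii <- as.numeric(radii); signal <- as.numeric(signal)
  if (length(radii) < 1) stop("scan must contain at least one point")
  if (length(signal) != length(radii))
    stop("signal and radii must have equal length")
  if (is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing")
  if (time < 0) stop("time must be >= 0")
  if (gain <= 0) stop("gain must be > 0")
  if (!is.null(se) && length(se) != length(radii))
    stop("se must match radii in length")
  structure(list(radii = radii, signal = signal, se = se, time = time,
                 rpm = rpm, temperature = temperature, cell = as.integer(cell),
                 gain = gain, channel = as.character(channel),
                 focal_um = focal_um, title = title),
            class = "radial_scan")
}

#' @export
print.radial_scan <- function(x, ...) {
  cat(sprintf(
    "<radial_scan> cell %d gain %g channel %s | %d points, r = [%.4f, %.4f] cm | t = %g s, %g rpm\n",
    x$cell, x$gain, x$channel, length(x$radii), min(x$radii), max(x$radii),
    x$time, x$rpm))
  invisible(x)
}

#' An ordered collection of scans from one sector and gain
#'
#' @param scans list of [radial_scan()] objects sharing cell and gain; sorted
#'   ascending by time (times must be distinct)
#' @param meta optional named list (e.g. `focal_um`, `pmt`, `run`)
#' @return object of class `scan_set`
#' @export
scan_set <- function(scans, meta = list()) {
  if (length(scans) < 1) stop("scan_set needs at least one scan")
  if (!all(vapply(scans, inherits, TRUE, "radial_scan")))
    stop("all elements must be radial_scan objects")
  cells <- vapply(scans, `[[`, 0L, "cell")
  gains <- vapply(scans, `[[`, 0, "gain")
  if (length(unique(cells)) > 1) stop("scans mix cells within one scan_set")
  if (length(unique(gains)) > 1) stop("scans mix gains within one scan_set")
  times <- vapply(scans, `[[`, 0, "time")
  scans <- scans[order(times)]
  times <- sort(times)
  if (anyDuplicated(times)) stop("scan times must be strictly increasing")
  structure(list(scans = scans, meta = meta), class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  t <- scanset_times(x)
  cat(sprintf("<scan_set> cell %d gain %g | %d scans, t = [%g, %g] s\n",
              x$scans[[1]]$cell, x$scans[[1]]$gain, length(x$scans),
              min(t), max(t)))
  invisible(x)
}

#' @rdname scan_set
#' @param x a `scan_set`
#' @export
scanset_times <- function(x) vapply(x$scans, `[[`, 0, "time")

# internal: common radius grid + signal matrix (radii x scans)
scanset_matrix <- function(x) {
  stopifnot(inherits(x, "scan_set"))
  r0 <- x$scans[[1]]$radii
  same <- vapply(x$scans, function(s)
    length(s$radii) == length(r0) && max(abs(s$radii - r0)) < 1e-9, TRUE)
  if (!all(same)) stop("scans in set do not share a common radius grid")
  list(radii = r0,
       times = scanset_times(x),
       Y = vapply(x$scans, `[[`, numeric(length(r0)), "signal"))
}

# internal: pull "key value" tokens such as "gain 4" out of a title line
title_token <- function(title, key) {
  m <- regmatches(title, regexec(paste0("\\b", key, "\\s+([-0-9.eE]+)"), title))[[1]]
  if (length(m) == 2) as.numeric(m[2]) else NA_real_
}

#' Read a radial scan file
#'
#' Parses the de-facto AUC interchange text format: a free title line, a
#' header line of `type cell temperature rpm time [w2t]` fields, then
#' whitespace-separated columns of radius (cm), signal (counts) and an
#' optional third column of per-point standard errors. Amplifier gain,
#' channel and focal depth, which the classic header has no field for, are
#' recognized as `gain G`, `channel X` and `focal Z` tokens in the title
#' line (gain defaults to 1).
#'
#' @param path path to a scan file
#' @return a [radial_scan()]
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("scan file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3)
    stop("malformed scan file (need title, header, data): ", path)
  title <- lines[1]
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(hdr) < 5)
    stop("malformed header line 2 (need 'type cell temp rpm time'): ",
         lines[2])
  hv <- suppressWarnings(as.numeric(hdr[2:5]))
  if (any(is.na(hv)))
    stop("malformed header line 2 (non-numeric field): ", lines[2])
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  cols <- strsplit(trimws(body), "\\s+")
  ncol <- lengths(cols)
  if (any(ncol < 2)) {
    bad <- which(ncol < 2)[1]
    stop("malformed data line ", bad + 2, " (need >= 2 columns): ", body[bad])
  }
  num <- suppressWarnings(lapply(cols, as.numeric))
  if (any(vapply(num, anyNA, TRUE)))
    stop("non-numeric data value in scan file: ", path)
  radii <- vapply(num, `[[`, 0, 1)
  signal <- vapply(num, `[[`, 0, 2)
  se <- if (all(ncol >= 3)) vapply(num, `[[`, 0, 3) else NULL
  gain <- title_token(title, "gain"); if (is.na(gain)) gain <- 1
  focal <- title_token(title, "focal")
  ch <- regmatches(title, regexec("\\bchannel\\s+(\\S+)", title))[[1]]
  channel <- if (length(ch) == 2) ch[2] else "A"
  radial_scan(radii, signal, time = hv[4], rpm = hv[3], temperature = hv[2],
              cell = as.integer(hv[1]), gain = gain, channel = channel,
              se = se, focal_um = focal, title = title)
}

#' Write a radial scan file
#'
#' Writes the format read by [read_scan()], with 12 significant digits so a
#' read-back round trip is lossless well beyond detector precision.
#'
#' @param scan a [radial_scan()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "radial_scan"))
  title <- scan$title
  if (is.null(title))
    title <- sprintf("fds scan cell %d gain %.10g channel %s%s", scan$cell,
                     scan$gain, scan$channel,
                     if (is.finite(scan$focal_um))
                       sprintf(" focal %.10g", scan$focal_um) else "")
  omega2t <- (scan$rpm * pi / 30)^2 * scan$time
  hdr <- sprintf("R %d %.6g %.10g %.10g %.8e", scan$cell, scan$temperature,
                 scan$rpm, scan$time, omega2t)
  if (is.null(scan$se)) {
    body <- sprintf("%.12g %.12g", scan$radii, scan$signal)
  } else {
    body <- sprintf("%.12g %.12g %.12g", scan$radii, scan$signal, scan$se)
  }
  writeLines(c(title, hdr, body), path)
  invisible(path)
}

#' Sort raw scan files into per-(cell, gain) scan sets
#'
#' Reads every file, groups by the (cell, gain) pair, and orders each group
#' by elapsed time -- the bookkeeping step that precedes serial analysis of
#' an FDS run acquired at several gains. Unparsable files are skipped with a
#' message; mixed rotor speeds within one group are kept but flagged with a
#' warning. Optionally writes one list file per group.
#'
#' @param paths character vector of scan-file paths
#' @param out_dir if non-`NULL`, directory into which one list file per group
#'   (`cellC_gainG.list`) is written
#' @return named list of [scan_set()] objects, names `"cellC_gainG"`
#' @export
sort_by_gain <- function(paths, out_dir = NULL) {
  scans <- list(); files <- character(0)
  for (p in paths) {
    s <- tryCatch(read_scan(p), error = function(e) {
      message("skipping unparsable scan file ", p, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(s)) { scans[[length(scans) + 1]] <- s; files <- c(files, p) }
  }
  if (length(scans) == 0) stop("no parseable scan files")
  key <- sprintf("cell%d_gain%.10g",
                 vapply(scans, `[[`, 0L, "cell"),
                 vapply(scans, `[[`, 0, "gain"))
  groups <- split(seq_along(scans), key)
  out <- lapply(groups, function(idx) {
    grp <- scans[idx]
    if (length(unique(vapply(grp, `[[`, 0, "rpm"))) > 1)
      warning("mixed rotor speeds within group ", key[idx[1]], " (retained)")
    scan_set(grp)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in names(groups)) {
      idx <- groups[[k]][order(vapply(scans[groups[[k]]], `[[`, 0, "time"))]
      writeLines(c(paste("#", k), normalizePath(files[idx])),
                 file.path(out_dir, paste0(k, ".list")))
    }
  }
  out
}

#' Load a scan set from a list file
#'
#' A list file holds one scan-file path per line (`#` starts a comment);
#' relative paths are resolved against the list file's directory. Scans are
#' filtered to the time window `[t_min, t_max]` and thinned to every k-th
#' scan, the usual way of assembling 50-100 scans that evenly represent a
#' sedimentation process from a much denser acquisition.
#'
#' @param path list-file path
#' @param every_k keep every k-th scan (after time filtering)
#' @param t_min,t_max elapsed-time window, s
#' @return a [scan_set()]
#' @export
load_listfile <- function(path, every_k = 1, t_min = 0, t_max = Inf) {
  stopifnot(every_k >= 1)
  if (!file.exists(path)) stop("list file does not exist: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("list file names no scans: ", path)
  base <- dirname(path)
  full <- ifelse(grepl("^(/|[A-Za-z]:)", lines), lines, file.path(base, lines))
  scans <- lapply(full, read_scan)
  times <- vapply(scans, `[[`, 0, "time")
  keep <- order(times)
  keep <- keep[times[keep] >= t_min & times[keep] <= t_max]
  if (length(keep) == 0)
    stop("no scans within time window [", t_min, ", ", t_max, "] s")
  keep <- keep[seq(1, length(keep), by = every_k)]
  scan_set(scans[keep])
}

#' Thin a scan set in time
#'
#' In-memory counterpart of the [load_listfile()] selection: keeps scans
#' within `[t_min, t_max]` and then every k-th of them, the usual way of
#' assembling a subset that evenly represents the sedimentation process.
#'
#' @param x a [scan_set()]
#' @param every_k keep every k-th scan
#' @param t_min,t_max elapsed-time window, s
#' @return a [scan_set()]
#' @export
thin_scans <- function(x, every_k = 1, t_min = 0, t_max = Inf) {
  stopifnot(inherits(x, "scan_set"), every_k >= 1)
  times <- scanset_times(x)
  keep <- which(times >= t_min & times <= t_max)
  if (length(keep) == 0) stop("no scans within time window")
  keep <- keep[seq(1, length(keep), by = every_k)]
  scan_set(x$scans[keep], meta = x$meta)
}

# fixed machine-parseable summary schema
SUMMARY_COLUMNS <- c("run", "cell", "gain", "focal_um", "rmsd", "s_w",
                     "boundary_amplitude", "ff0", "mw_kDa", "de_dr", "de_dt",
                     "delta", "sigma", "meniscus", "bottom")

#' Write a batch summary table
#'
#' One CSV row per fit with the fixed column set `run, cell, gain, focal_um,
#' rmsd, s_w, boundary_amplitude, ff0, mw_kDa, de_dr, de_dt, delta, sigma,
#' meniscus, bottom`.
#'
#' @param reports list of `fit_report` objects (see [fit_cs()])
#' @param path output CSV path
#' @return invisibly, the summary `data.frame`
#' @export
write_summary <- function(reports, path) {
  rows <- lapply(reports, function(rep) {
    stopifnot(inherits(rep, "fit_report"))
    p <- rep$params
    data.frame(run = rep$meta$run %||% NA, cell = rep$meta$cell %||% NA,
               gain = rep$meta$gain %||% NA,
               focal_um = rep$meta$focal_um %||% NA,
               rmsd = rep$rmsd, s_w = rep$s_w,
               boundary_amplitude = rep$amplitude, ff0 = p[["ff0"]],
               mw_kDa = rep$mw_kDa, de_dr = p[["de_dr"]],
               de_dt = p[["de_dt"]], delta = p[["delta"]],
               sigma = p[["sigma"]], meniscus = p[["meniscus"]],
               bottom = p[["bottom"]])
  })
  df <- do.call(rbind, rows)
  stopifnot(identical(names(df), SUMMARY_COLUMNS))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a run configuration file
#'
#' YAML file of fit settings (solution density g/ml, viscosity poise, vbar
#' ml/g, temperature K, fit limits, s-grid, refinement switches). Recognized
#' keys mirror the arguments of [fit_config()] plus a `conditions` block with
#' `density`, `viscosity`, `vbar`, `temperature`.
#'
#' @param path YAML configuration path
#' @return a fit configuration list (see [fit_config()])
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  cond <- do.call(solution_conditions, y$conditions %||% list())
  y$conditions <- NULL
  do.call(fit_config, c(y, list(conditions = cond)))
}
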