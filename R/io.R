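#' Write a trajectory CSV
#'
#' Dialect: header `fly_id,chamber_id,t_s,x_mm,y_mm,detected`; one row per
#' second; undetected rows have empty coordinate fields and `detected = 0`;
#' UTF-8, LF line endings. Coordinates are serialized with 17 significant
#' digits so `read_trajectory(write_trajectory(x))` is bit-exact.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c("fly_id,chamber_id,t_s,x_mm,y_mm,detected",
             sprintf("%s,%d,%d,%s,%s,%d",
                     traj$fly_id, traj$chamber_id, traj$t_s,
                     fmt_num(traj$x_mm), fmt_num(traj$y_mm),
                     as.integer(traj$detected)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Validates the dialect strictly: known columns only, strictly increasing
#' unit-step time base; malformed or duplicated-time rows are reported with
#' their line numbers.
#'
#' @param path input file.
#' @param body_length_mm body length attribute to attach (default 2.5).
#' @param geometry optional [chamber_geometry()] to attach.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, body_length_mm = 2.5, geometry = NULL) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = list(character = "fly_id"),
                          na.strings = "")
  expected <- c("fly_id", "chamber_id", "t_s", "x_mm", "y_mm", "detected")
  if (!identical(names(dt), expected))
    stop(sprintf("unknown or missing columns: got [%s], expected [%s]",
                 paste(names(dt), collapse = ", "),
                 paste(expected, collapse = ", ")))
  if (nrow(dt) > 1L) {
    dstep <- diff(dt$t_s)
    bad <- which(dstep != 1L)
    if (length(bad))
      stop(sprintf("non-monotone or gapped t_s at line %d (t_s=%d after t_s=%d)",
                   bad[1] + 2L, dt$t_s[bad[1] + 1L], dt$t_s[bad[1]]))
  }
  trajectory(t_s = dt$t_s, x_mm = dt$x_mm, y_mm = dt$y_mm,
             detected = as.logical(dt$detected),
             fly_id = dt$fly_id[1], chamber_id = dt$chamber_id[1],
             body_length_mm = body_length_mm, geometry = geometry)
}

#' Write a Trikinetics-style monitor file
#'
#' Tab-delimited, one line per minute: record index, date (`dd mon yy`),
#' time (`HH:MM:SS`), six status fields (`1 42 0 0 0 0`), a light-sensor
#' field, then 32 integer channels. Emulated flies occupy channels
#' `1..ncol(counts)`; unused channels stay 0.
#'
#' @param counts integer matrix, minutes x channels (<= 32), or a single
#'   [beam_counts()] result (uses its `count` column as channel 1).
#' @param path output file.
#' @param start list `(date, time)` strings for the first minute; defaults
#'   to `"1 Jan 20"`, `"08:00:00"`.
#' @param lights numeric vector (0/1 light sensor per minute) or NULL.
#' @return `path`, invisibly.
#' @export
write_monitor <- function(counts, path,
                          start = list(date = "1 Jan 20", time = "08:00:00"),
                          lights = NULL) {
  if (inherits(counts, "beam_count_series"))
    counts <- matrix(counts$count, ncol = 1)
  counts <- as.matrix(counts)
  if (ncol(counts) > 32L) stop("a monitor has at most 32 channels")
  n_min <- nrow(counts)
  full <- matrix(0L, n_min, 32L)
  full[, seq_len(ncol(counts))] <- as.integer(round(counts))
  t0 <- as.POSIXct(paste(start$date, start$time),
                   format = "%d %b %y %H:%M:%S", tz = "UTC")
  tt <- t0 + 60 * (seq_len(n_min) - 1L)
  date_txt <- sub("^0", "", format(tt, "%d %b %y"))
  time_txt <- format(tt, "%H:%M:%S")
  if (is.null(lights)) lights <- rep(0L, n_min)
  lines <- paste(seq_len(n_min), date_txt, time_txt,
                 1L, 42L, 0L, 0L, 0L, 0L, as.integer(lights),
                 apply(full, 1, paste, collapse = "\t"),
                 sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a Trikinetics-style monitor file
#'
#' @param path input file.
#' @return list with `counts` (integer matrix minutes x 32), `date`, `time`
#'   (character vectors), `lights`. `read_monitor(write_monitor(x))`
#'   restores `x`'s counts exactly.
#' @export
read_monitor <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (length(unique(lens)) != 1L)
    stop(sprintf("ragged monitor file: line %d has %d fields, line 1 has %d",
                 which(lens != lens[1])[1], lens[lens != lens[1]][1], lens[1]))
  if (lens[1] != 42L)
    stop(sprintf("expected 42 tab-delimited fields per line, got %d", lens[1]))
  m <- do.call(rbind, parts)
  counts <- matrix(as.integer(m[, 11:42]), ncol = 32L)
  list(counts = counts, date = m[, 2], time = m[, 3],
       lights = as.integer(m[, 10]))
}

#' Write a matrix as ASCII PGM (P2)
#'
#' Plain-text grayscale image interchange used for synthetic frames and
#' z-stack slices (one file per slice), so every artifact stays a text file.
#'
#' @param img numeric matrix; values clamped to `[0, maxval]` and rounded.
#' @param path output file.
#' @param maxval maximum gray value (default 255; use a larger value for
#'   fluorescence intensities).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  img <- round(pmin(pmax(img, 0), maxval))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", as.integer(maxval)),
               apply(img, 1, paste, collapse = " ")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path input file.
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Read a z-stack stored as numbered PGM slices
#'
#' @param paths character vector of slice files, in z order.
#' @return an `image_stack`.
#' @export
read_stack_pgm <- function(paths) {
  structure(lapply(paths, read_pgm), class = "image_stack")
}

#' Write an `image_stack` as numbered PGM slices
#'
#' @param stack an `image_stack`.
#' @param prefix path prefix; slices become `<prefix>_z01.pgm`, ...
#' @param maxval PGM maximum gray value.
#' @return character vector of written paths, invisibly.
#' @export
write_stack_pgm <- function(stack, prefix, maxval = 1023L) {
  paths <- sprintf("%s_z%02d.pgm", prefix, seq_along(stack))
  for (i in seq_along(stack)) write_pgm(stack[[i]], paths[i], maxval)
  invisible(paths)
}

#' Run configuration
#'
#' Flat key=value settings serialized to a diffable text file; the MD5 hash
#' of the canonical serialization stamps every output so a run can be
#' audited and reproduced.
#'
#' @param ... named scalar settings (numbers, strings, logicals).
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  vals <- list(...)
  if (length(vals) && (is.null(names(vals)) || any(names(vals) == "")))
    stop("all settings must be named")
  stopifnot(all(lengths(vals) == 1L))
  structure(vals[order(names(vals))], class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k,
            if (is.character(v)) sprintf('"%s"', v)
            else if (is.logical(v)) tolower(as.character(v))
            else sprintf("%.17g", v))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- regmatches(lines,
                   regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$",
                           lines))
  out <- list()
  for (p in kv) {
    if (length(p) < 3) next
    key <- p[2]; raw <- trimws(p[3])
    out[[key]] <-
      if (grepl('^".*"$', raw)) sub('^"(.*)"$', "\\1", raw)
      else if (raw %in% c("true", "false")) raw == "true"
      else as.numeric(raw)
  }
  do.call(run_config, out)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}
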