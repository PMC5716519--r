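# All scan files share one dialect: comma-separated, one header row, optional
# leading `# key=value` metadata lines, numbers formatted to 6 significant
# digits. Units are fixed: cm and relative dose.

fmt_num <- function(x) formatC(x, digits = 6, format = "g")

read_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    m <- regmatches(kv, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", kv))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  list(meta = meta, body = lines[!grepl("^#", lines)])
}

read_body_csv <- function(body, path, n_numeric = NULL) {
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"), check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  df
}

check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v) || anyNA(suppressWarnings(as.numeric(v)))) {
    bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
    stop("malformed numeric value in column '", col, "' of ", path,
         " at data row ", bad)
  }
  as.numeric(v)
}

meta_num <- function(meta, key, default) {
  if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
}

#' Read a cross-axis profile from CSV
#'
#' Expects columns `position_cm,dose` after one header row; metadata
#' (`depth`, `ssd`, `field_nominal`, `label`) may be given as leading
#' `# key=value` comment lines or overridden via arguments. Rows are sorted
#' by position; duplicated positions are an error.
#'
#' @param path Path to a CSV file.
#' @param depth,ssd,field_nominal,label Override the file metadata.
#' @return A [beam_profile()].
#' @export
read_profile <- function(path, depth = NULL, ssd = NULL, field_nominal = NULL,
                         label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- read_meta(path)
  df <- read_body_csv(parsed$body, path)
  if (!all(c("position_cm", "dose") %in% names(df)))
    stop(path, " must have columns position_cm,dose")
  x <- check_numeric_col(df, "position_cm", path)
  d <- check_numeric_col(df, "dose", path)
  o <- order(x)
  x <- x[o]; d <- d[o]
  if (anyDuplicated(x))
    stop("duplicate positions in ", path, " (e.g. x = ", x[duplicated(x)][1], ")")
  meta <- parsed$meta
  beam_profile(
    x, d,
    depth = if (!is.null(depth)) depth else meta_num(meta, "depth", NA_real_),
    ssd = if (!is.null(ssd)) ssd else meta_num(meta, "ssd", 100),
    field_nominal = if (!is.null(field_nominal)) field_nominal
                    else meta_num(meta, "field_nominal", NA_real_),
    label = if (!is.null(label)) label
            else if (!is.null(meta$label)) meta$label else "")
}

#' Write a cross-axis profile to CSV
#'
#' Inverse of [read_profile()]; numbers are written with 6 significant
#' digits, metadata as `# key=value` comment lines.
#'
#' @param profile A [beam_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "beam_profile"))
  lines <- character(0)
  if (!is.na(profile$depth)) lines <- c(lines, paste0("# depth=", fmt_num(profile$depth)))
  lines <- c(lines, paste0("# ssd=", fmt_num(profile$ssd)))
  if (!is.na(profile$field_nominal))
    lines <- c(lines, paste0("# field_nominal=", fmt_num(profile$field_nominal)))
  if (nzchar(profile$label)) lines <- c(lines, paste0("# label=", profile$label))
  lines <- c(lines, "position_cm,dose",
             paste(fmt_num(profile$positions), fmt_num(profile$doses), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a depth-dose curve from CSV
#'
#' Expects columns `depth_cm,dose`; a `# normalized=true` metadata line marks
#' a curve already scaled to 100 at dmax.
#'
#' @param path Path to a CSV file.
#' @return A [depth_dose_curve()].
#' @export
read_pdd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- read_meta(path)
  df <- read_body_csv(parsed$body, path)
  if (!all(c("depth_cm", "dose") %in% names(df)))
    stop(path, " must have columns depth_cm,dose")
  z <- check_numeric_col(df, "depth_cm", path)
  d <- check_numeric_col(df, "dose", path)
  o <- order(z)
  norm <- identical(tolower(parsed$meta$normalized %||% "false"), "true")
  depth_dose_curve(z[o], d[o], normalized = norm)
}

#' Write a depth-dose curve to CSV
#' @param curve A [depth_dose_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdd <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  lines <- c(paste0("# normalized=", tolower(as.character(curve$normalized))),
             "depth_cm,dose",
             paste(fmt_num(curve$depths), fmt_num(curve$doses), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a detector-array frame series from CSV
#'
#' First column `frame_index`, one column per detector position (the header
#' gives positions in cm), optional trailing `beam_on` column; frame period
#' and gate window via `# frame_period=` / `# gate_window=` metadata lines.
#'
#' @param path Path to a CSV file.
#' @return A [frame_series()].
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- read_meta(path)
  df <- read_body_csv(parsed$body, path)
  if (names(df)[1] != "frame_index")
    stop(path, " must start with a frame_index column")
  has_beam_on <- "beam_on" %in% names(df)
  pos_cols <- setdiff(names(df), c("frame_index", "beam_on"))
  positions <- suppressWarnings(as.numeric(pos_cols))
  if (anyNA(positions))
    stop("position headers in ", path, " must be numeric (cm)")
  frames <- as.matrix(df[, pos_cols, drop = FALSE])
  colnames(frames) <- NULL
  frame_series(frames, positions,
               frame_period = meta_num(parsed$meta, "frame_period", 0.072),
               beam_on = if (has_beam_on) as.logical(df$beam_on) else NULL,
               gate_window = {
                 gw <- meta_num(parsed$meta, "gate_window", NA_real_)
                 if (is.na(gw)) NULL else gw
               })
}

#' Write a detector-array frame series to CSV
#' @param series A [frame_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(series, path) {
  stopifnot(inherits(series, "frame_series"))
  lines <- paste0("# frame_period=", fmt_num(series$frame_period))
  if (!is.null(series$gate_window))
    lines <- c(lines, paste0("# gate_window=", fmt_num(series$gate_window)))
  header <- paste(c("frame_index", fmt_num(series$positions),
                    if (!is.null(series$beam_on)) "beam_on"), collapse = ",")
  rows <- vapply(seq_len(nrow(series$frames)), function(i) {
    paste(c(i, fmt_num(series$frames[i, ]),
            if (!is.null(series$beam_on)) tolower(as.character(series$beam_on[i]))),
          collapse = ",")
  }, character(1))
  writeLines(c(lines, header, rows), path)
  invisible(path)
}

#' Read a daily-QA log from CSV
#'
#' Columns `date,output_offset_pct` with optional `sym_cp_pct,sym_ip_pct`;
#' tolerance via `# tolerance=` metadata (default 3).
#'
#' @param path Path to a CSV file.
#' @param tolerance Override the tolerance in percent.
#' @return A [qa_series()].
#' @export
read_qa_log <- function(path, tolerance = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- read_meta(path)
  df <- read_body_csv(parsed$body, path)
  if (!all(c("date", "output_offset_pct") %in% names(df)))
    stop(path, " must have columns date,output_offset_pct")
  qa_series(df$date, check_numeric_col(df, "output_offset_pct", path),
            sym_cp = if ("sym_cp_pct" %in% names(df)) check_numeric_col(df, "sym_cp_pct", path),
            sym_ip = if ("sym_ip_pct" %in% names(df)) check_numeric_col(df, "sym_ip_pct", path),
            tolerance = if (!is.null(tolerance)) tolerance
                        else meta_num(parsed$meta, "tolerance", 3))
}

#' Write a daily-QA log to CSV
#' @param series A [qa_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qa_log <- function(series, path) {
  stopifnot(inherits(series, "qa_series"))
  header <- paste(c("date", "output_offset_pct",
                    if (!is.null(series$sym_cp)) "sym_cp_pct",
                    if (!is.null(series$sym_ip)) "sym_ip_pct"), collapse = ",")
  rows <- vapply(seq_along(series$dates), function(i) {
    paste(c(as.character(series$dates[i]), fmt_num(series$output_offset[i]),
            if (!is.null(series$sym_cp)) fmt_num(series$sym_cp[i]),
            if (!is.null(series$sym_ip)) fmt_num(series$sym_ip[i])),
          collapse = ",")
  }, character(1))
  writeLines(c(paste0("# tolerance=", fmt_num(series$tolerance)), header, rows), path)
  invisible(path)
}

#' Resample a profile onto a new position grid
#'
#' Linear interpolation between neighbouring samples; the grid must lie
#' within the sampled range (no extrapolation).
#'
#' @param profile A [beam_profile()].
#' @param grid New positions in cm, strictly increasing, within the sampled
#'   range.
#' @return A [beam_profile()] on `grid`.
#' @export
resample <- function(profile, grid) {
  stopifnot(inherits(profile, "beam_profile"))
  grid <- as.numeric(grid)
  if (any(grid < min(profile$positions)) || any(grid > max(profile$positions)))
    stop("resample grid extends outside the sampled range; extrapolation is not supported")
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("resample grid must be strictly increasing")
  d <- stats::approx(profile$positions, profile$doses, xout = grid)$y
  # built by interpolation from a valid profile, so skip the 5-point
  # minimum: short query grids (even a single position) are legitimate
  structure(list(positions = grid, doses = d, depth = profile$depth,
                 ssd = profile$ssd, field_nominal = profile$field_nominal,
                 label = profile$label),
            class = "beam_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
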