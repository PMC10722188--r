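#' Read a DeepLabCut-style tracking table
#'
#' Parses the three-row scorer/bodyparts/coords column hierarchy DeepLabCut
#' writes for per-frame 2D (or, for reconstructed data, 3D) coordinates.
#' Only the CSV dialect is supported in this build; the HDF5 dialect of the
#' same layout is rejected with an explicit error. Entries whose likelihood
#' column falls below `likelihood_min`, or that are empty, become `NA` gaps
#' for [fill_gaps()] — a stand-in for the manual curation step of the
#' original workflow.
#'
#' @param path CSV file in scorer/bodyparts/coords layout.
#' @param config A [feature_point_config()]; every configured point must be
#'   present in the table (extra bodyparts are ignored).
#' @param fps Frame rate to attach.
#' @param likelihood_min Confidence threshold below which a sample is marked
#'   missing; ignored when the table has no likelihood columns.
#' @param units Coordinate units of the table.
#' @return A [pose_sequence()].
#' @export
read_tracking_table <- function(path, config, fps, likelihood_min = 0.9,
                                units = "px") {
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE))
    stop("HDF5 tracking tables are not supported in this build; ",
         "export the table as CSV", call. = FALSE)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         comment.char = "#")
  if (nrow(raw) < 4L)
    stop("tracking table has no data rows: ", path, call. = FALSE)
  hdr_rows <- raw[1:3, -1, drop = FALSE]
  labels <- tolower(as.character(raw[1:3, 1]))
  if (!identical(labels[2:3], c("bodyparts", "coords")))
    stop("not a scorer/bodyparts/coords table: header rows are '",
         paste(as.character(raw[1:3, 1]), collapse = "', '"), "'", call. = FALSE)
  bodyparts <- as.character(unlist(hdr_rows[2, ]))
  coords <- tolower(as.character(unlist(hdr_rows[3, ])))
  dat <- raw[-(1:3), -1, drop = FALSE]
  num <- matrix(suppressWarnings(as.numeric(as.matrix(dat))), nrow = nrow(dat))

  pts <- point_names(config)
  missing_pts <- setdiff(pts, unique(bodyparts))
  if (length(missing_pts))
    stop("tracking table is missing bodyparts: ",
         paste(missing_pts, collapse = ", "), call. = FALSE)

  has_z <- any(coords == "z" & bodyparts %in% pts)
  dims <- if (has_z) 3L else 2L
  axes <- c("x", "y", "z")[seq_len(dims)]
  nf <- nrow(num)
  co <- array(NA_real_, dim = c(nf, length(pts), dims))
  for (i in seq_along(pts)) {
    for (a in seq_len(dims)) {
      col <- which(bodyparts == pts[i] & coords == axes[a])
      if (length(col) != 1L)
        stop("expected exactly one '", axes[a], "' column for bodypart '",
             pts[i], "', found ", length(col), call. = FALSE)
      co[, i, a] <- num[, col]
    }
    lcol <- which(bodyparts == pts[i] & coords == "likelihood")
    if (length(lcol) == 1L) {
      bad <- !is.na(num[, lcol]) & num[, lcol] < likelihood_min
      co[bad, i, ] <- NA_real_
    }
  }
  pose_sequence(co, config, fps, units = units)
}

#' Write a pose sequence as a DeepLabCut-style CSV table
#'
#' Inverse of [read_tracking_table()]: emits the scorer/bodyparts/coords
#' header hierarchy with full-precision coordinates (round-trips exactly).
#'
#' @param pose A [pose_sequence()].
#' @param path Output CSV path.
#' @param scorer Scorer label for the first header row.
#' @export
write_tracking_table <- function(pose, path, scorer = "beamgait") {
  co <- pose$coords
  d <- dim(co)
  axes <- c("x", "y", "z")[seq_len(d[3])]
  pts <- dimnames(co)[[2]]
  ncol_out <- d[2] * d[3]
  header <- rbind(
    c("scorer", rep(scorer, ncol_out)),
    c("bodyparts", rep(pts, each = d[3])),
    c("coords", rep(axes, times = d[2]))
  )
  flat <- matrix(aperm(co, c(1, 3, 2)), nrow = d[1])  # frames x (dims*pts), axis fastest
  body <- cbind(format(seq_len(d[1]) - 1L, trim = TRUE, scientific = FALSE),
                matrix(num_c(flat), nrow = d[1]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(header, 1, paste, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

# full-precision, locale-independent numeric formatting (17 significant
# digits round-trips doubles exactly through as.numeric)
num_c <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Read calibration line segments
#'
#' The stereo autocalibration is driven by three pairs of parallel line
#' segments traced in both camera views: the upper and lower beam edges
#' (`beam`), the outer goal-box edges (`box_y`), and the goal-box entrance
#' edges (`box_z`). The file is a CSV with columns
#' `view,label,line,x1,y1,x2,y2`; each view needs all three labels, two
#' segments each.
#'
#' @param path CSV file of traced segments.
#' @return A `calibration_lines` object: per view, a named list of
#'   `2 x 2 x 2` arrays (segment, endpoint, xy).
#' @export
read_calibration_lines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("view", "label", "line", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(df)))
    stop("calibration file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  calibration_lines_from_df(df)
}

calibration_labels <- c("beam", "box_y", "box_z")

calibration_lines_from_df <- function(df) {
  views <- c("left", "right")
  if (!setequal(unique(df$view), views))
    stop("calibration file must contain views 'left' and 'right'", call. = FALSE)
  out <- list()
  for (v in views) {
    sub <- df[df$view == v, , drop = FALSE]
    labs <- sort(unique(sub$label))
    if (!setequal(labs, calibration_labels))
      stop("view '", v, "' must contain exactly the 3 labels ",
           paste(calibration_labels, collapse = ", "), "; found ",
           paste(labs, collapse = ", "), call. = FALSE)
    out[[v]] <- list()
    for (lab in calibration_labels) {
      seg <- sub[sub$label == lab, , drop = FALSE]
      seg <- seg[order(seg$line), , drop = FALSE]
      if (nrow(seg) != 2L)
        stop("label '", lab, "' in view '", v, "' needs exactly 2 segments",
             call. = FALSE)
      a <- array(NA_real_, dim = c(2, 2, 2),
                 dimnames = list(NULL, c("p1", "p2"), c("x", "y")))
      for (s in 1:2) {
        a[s, 1, ] <- c(seg$x1[s], seg$y1[s])
        a[s, 2, ] <- c(seg$x2[s], seg$y2[s])
        if (sum((a[s, 1, ] - a[s, 2, ])^2) == 0)
          stop("degenerate zero-length segment: view '", v, "', label '",
               lab, "', line ", seg$line[s], call. = FALSE)
      }
      if (all(a[1, , ] == a[2, , ]))
        stop("identical segments in pair '", lab, "', view '", v, "'",
             call. = FALSE)
      out[[v]][[lab]] <- a
    }
  }
  structure(out, class = "calibration_lines")
}

#' @rdname read_calibration_lines
#' @param lines A `calibration_lines` object.
#' @export
write_calibration_lines <- function(lines, path) {
  rows <- list()
  for (v in names(lines)) {
    for (lab in names(lines[[v]])) {
      a <- lines[[v]][[lab]]
      for (s in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          view = v, label = lab, line = s,
          x1 = a[s, 1, 1], y1 = a[s, 1, 2], x2 = a[s, 2, 1], y2 = a[s, 2, 2])
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.calibration_lines <- function(x, ...) {
  cat("<calibration_lines> views:", paste(names(x), collapse = ", "),
      "| pairs:", paste(names(x[[1]]), collapse = ", "), "\n")
  invisible(x)
}

swc_file_version <- 1L

#' Persist a standard walk cycle
#'
#' The SWC and its cumulative weight must survive a save/load cycle exactly,
#' because progressive refinement across videos keeps folding new cycles
#' into the stored weighted average. The format is a self-describing text
#' file: a versioned key-value header (tau, component count, weight, fps,
#' dims, skeleton hash) followed by a whitespace-separated numeric block of
#' `tau` rows, written with enough digits that every double round-trips
#' bit-exactly.
#'
#' @param swc A [standard_walk_cycle()].
#' @param path Output path.
#' @export
write_swc <- function(swc, path) {
  stopifnot(inherits(swc, "standard_walk_cycle"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# beamgait standard walk cycle",
    paste0("version: ", swc_file_version),
    paste0("tau: ", nrow(swc$values)),
    paste0("n_components: ", ncol(swc$values)),
    paste0("weight: ", num_c(swc$weight)),
    paste0("fps: ", num_c(swc$fps)),
    paste0("dims: ", swc$dims),
    paste0("config_hash: ", config_hash(swc$config)),
    paste0("components: ", paste(colnames(swc$values), collapse = " ")),
    "data:"
  ), con)
  writeLines(apply(matrix(num_c(swc$values), nrow = nrow(swc$values)), 1,
                   paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_swc
#' @param config Skeleton the file must match; an error is raised when the
#'   stored hash disagrees (refining with an incompatible skeleton would
#'   silently scramble components).
#' @export
read_swc <- function(path, config) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (length(txt) == 0L) stop("empty SWC file: ", path, call. = FALSE)
  data_at <- match("data:", txt)
  if (is.na(data_at)) stop("malformed SWC file (no data block): ", path,
                           call. = FALSE)
  hdr <- txt[seq_len(data_at - 1L)]
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1))
  h <- stats::setNames(as.list(vals), keys)
  if (as.integer(h$version) != swc_file_version)
    stop("SWC file version ", h$version, " not supported (expected ",
         swc_file_version, ")", call. = FALSE)
  if (!is.null(config) && h$config_hash != config_hash(config))
    stop("SWC file was built for a different skeleton configuration ",
         "(hash ", h$config_hash, " != ", config_hash(config), ")",
         call. = FALSE)
  tau <- as.integer(h$tau)
  nc <- as.integer(h$n_components)
  num <- as.numeric(unlist(strsplit(txt[(data_at + 1L):length(txt)], " +")))
  if (length(num) != tau * nc)
    stop("SWC data block has ", length(num), " values; expected ",
         tau * nc, call. = FALSE)
  vals <- matrix(num, nrow = tau, byrow = TRUE)
  standard_walk_cycle(vals, config, fps = as.numeric(h$fps),
                      dims = as.integer(h$dims), weight = as.numeric(h$weight))
}

#' Write a speed series as CSV
#'
#' Columns are the canonical `point_axis` components preceded by the 0-based
#' original video frame index of each row.
#'
#' @param speed A [speed_series()].
#' @param path Output path.
#' @export
write_speed_csv <- function(speed, path) {
  df <- data.frame(frame = speed$frame_index - 1L)
  df <- cbind(df, as.data.frame(speed$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file (JSON)
#'
#' Holds the per-experiment settings: skeleton groups, frame rate, beam
#' length and inclination, optional manual culling intervals, search bounds
#' and thresholds. JSON was chosen so the file can be written and parsed
#' without extra dependencies.
#'
#' @param path JSON file.
#' @return A list with a `config` element ([feature_point_config()]) plus the
#'   scalar settings.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- list(
    config = if (!is.null(cfg$groups))
      feature_point_config(as.list(cfg$groups)) else default_mouse_config(),
    fps = cfg$fps %||% 30,
    beam_length_cm = cfg$beam_length_cm %||% 60,
    incline_deg = cfg$incline_deg %||% 0,
    likelihood_min = cfg$likelihood_min %||% 0.9,
    cull_keep = cfg$cull_keep,
    ratio_bounds = cfg$ratio_bounds %||% c(0.5, 2),
    voc_threshold = cfg$voc_threshold %||% 0.5,
    seed = cfg$seed %||% 1L
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
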