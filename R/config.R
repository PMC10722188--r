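#' Feature-point (skeleton) configuration
#'
#' A `feature_point_config` names the tracked anatomical landmarks and
#' partitions them into ordered body-part groups. The default mouse skeleton
#' has 18 points in four groups: 3 head points (left/right ear tips and nose
#' tip), 4 torso points, 7 tail points, and the 4 feet.
#'
#' @param groups Named list; each element is a character vector of point
#'   names. Group order and point order within groups are preserved and fix
#'   the component ordering used by every downstream computation.
#' @return An object of class `feature_point_config`.
#' @examples
#' cfg <- default_mouse_config()
#' n_points(cfg)  # 18
#' @export
feature_point_config <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list of character vectors", call. = FALSE)
  groups <- lapply(groups, as.character)
  pts <- unlist(groups, use.names = FALSE)
  if (length(pts) == 0L)
    stop("configuration has no feature points", call. = FALSE)
  dup <- pts[duplicated(pts)]
  if (length(dup))
    stop("duplicated point names across groups: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  structure(list(groups = groups), class = "feature_point_config")
}

#' @rdname feature_point_config
#' @export
default_mouse_config <- function() {
  feature_point_config(list(
    head = c("left_ear_tip", "right_ear_tip", "nose_tip"),
    body = paste0("body_", 1:4),
    tail = paste0("tail_", 1:7),
    feet = c("foot_FL", "foot_FR", "foot_RL", "foot_RR")
  ))
}

#' @rdname feature_point_config
#' @param config A `feature_point_config`.
#' @export
n_points <- function(config) length(point_names(config))

#' @rdname feature_point_config
#' @export
point_names <- function(config) unlist(config$groups, use.names = FALSE)

#' @rdname feature_point_config
#' @export
group_names <- function(config) names(config$groups)

#' Map each point to its group
#' @param config A `feature_point_config`.
#' @return Character vector, one group name per point, in point order.
#' @export
point_groups <- function(config) {
  rep(names(config$groups), lengths(config$groups))
}

#' Component labels for the stacked speed/coordinate vector
#'
#' Components are laid out point-major, axes fastest:
#' `(x1, y1[, z1], x2, y2[, z2], ...)`, so an 18-point 2D layout has 36
#' components and an 18-point 3D layout has 54.
#'
#' @param config A `feature_point_config`.
#' @param dims 2 or 3.
#' @return Character vector of `point_axis` labels, length `n_points * dims`.
#' @export
component_names <- function(config, dims) {
  stopifnot(dims %in% c(2L, 3L))
  axes <- c("x", "y", "z")[seq_len(dims)]
  as.vector(t(outer(point_names(config), axes, paste, sep = "_")))
}

#' Group membership of each component
#' @inheritParams component_names
#' @return Character vector, one group per component.
#' @export
component_groups <- function(config, dims) {
  rep(point_groups(config), each = dims)
}

#' Axis letter of each component
#' @inheritParams component_names
#' @export
component_axes <- function(config, dims) {
  rep(c("x", "y", "z")[seq_len(dims)], times = n_points(config))
}

#' @export
print.feature_point_config <- function(x, ...) {
  cat("<feature_point_config> ", n_points(x), " points in ",
      length(x$groups), " groups\n", sep = "")
  for (g in names(x$groups))
    cat("  ", format(g, width = 6), ": ", paste(x$groups[[g]], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# FNV-1a 32-bit over the serialized group structure; pure R so the hash is
# stable across machines and sessions. Used to tie SWC files to a skeleton.
#' Short stable hash of a skeleton configuration
#' @param config A `feature_point_config`.
#' @return 8-character lowercase hex string.
#' @export
config_hash <- function(config) {
  s <- paste(vapply(seq_along(config$groups), function(i) {
    paste0(names(config$groups)[i], ":", paste(config$groups[[i]], collapse = ","))
  }, character(1)), collapse = ";")
  # 32-bit FNV-1a using double arithmetic (exact below 2^53)
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- fnv_xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# xor of a 32-bit value (double) with a byte
fnv_xor32 <- function(h, b) {
  lo <- h %% 256
  h - lo + bitwXor(as.integer(lo), as.integer(b))
}
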