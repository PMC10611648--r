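# Canonical column schema for detection-trial tables. Names double as the
# CSV header; all distances in metres, lens height in centimetres, angles in
# degrees (vertical) or radians (sun), speed in metres per second.
trial_columns <- function() {
  c("outcome", "distance_m", "body_size", "camera_model", "lens_height_cm",
    "aiming_distance_m", "vertical_angle_deg", "speed_mps",
    "sun_altitude_rad", "sun_azimuth_rad", "first_x_m", "first_y_m")
}

required_trial_columns <- function() {
  setdiff(trial_columns(), c("first_x_m", "first_y_m"))
}

#' Declared categorical level sets for detection trials
#'
#' Reference levels come first: `large_ungulate` for body size and `HP2X`
#' for camera model are the baselines absorbed by the intercept in the
#' covariate regressions.
#'
#' @return Named list of character level vectors.
#' @export
trial_levels <- function() {
  list(
    body_size = c("large_ungulate", "large", "medium"),
    camera_model = c("HP2X", "PC900")
  )
}

#' Construct and validate a detection-trial table
#'
#' One row per experimental pass: a binary trigger outcome plus the
#' covariates used by the two-stage detection model. Categorical columns are
#' coerced to factors with the declared level sets (reference level first)
#' so downstream model matrices use consistent treatment contrasts.
#'
#' @param data Data frame containing at least the required trial columns
#'   (see `trial_columns()`); the optional mapped first-detection position
#'   columns `first_x_m`, `first_y_m` are added as `NA` when absent.
#' @return A `detection_trials` data frame.
#' @export
detection_trials <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_trial_columns(), names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("first_x_m", "first_y_m")) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }
  data <- data[trial_columns()]
  validate_trials(data)
  lv <- trial_levels()
  data$body_size <- factor(as.character(data$body_size), levels = lv$body_size)
  data$camera_model <- factor(as.character(data$camera_model),
                              levels = lv$camera_model)
  class(data) <- c("detection_trials", "data.frame")
  data
}

# Row-level contract checks; every violation is reported with its row number.
validate_trials <- function(data) {
  fail <- function(rows, what) {
    stop(sprintf("invalid trial data: %s (row %s)", what,
                 paste(utils::head(rows, 5L), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!(data$outcome %in% c(0, 1)))
  if (length(bad)) fail(bad, "outcome must be 0 or 1")
  bad <- which(!is.finite(data$distance_m) | data$distance_m <= 0)
  if (length(bad)) fail(bad, "distance_m must be positive")
  bad <- which(!is.finite(data$lens_height_cm) | data$lens_height_cm <= 0)
  if (length(bad)) fail(bad, "lens_height_cm must be positive")
  bad <- which(!is.finite(data$speed_mps) | data$speed_mps < 0)
  if (length(bad)) fail(bad, "speed_mps must be non-negative")
  bad <- which(!is.na(data$sun_altitude_rad) &
                 abs(data$sun_altitude_rad) > pi / 2 + 1e-9)
  if (length(bad)) fail(bad, "sun_altitude_rad must lie in [-pi/2, pi/2]")
  lv <- trial_levels()
  for (col in names(lv)) {
    bad <- which(!(as.character(data[[col]]) %in% lv[[col]]))
    if (length(bad)) {
      fail(bad, sprintf("%s has undeclared level '%s'", col,
                        as.character(data[[col]])[bad[1L]]))
    }
  }
  invisible(data)
}

#' Generate a full-factorial trial design
#'
#' Expands every combination of the declared factor levels, repeated
#' `replicates` times, in a deterministic order: the first declared factor
#' varies slowest (lexicographic by declared factor order) and replicate
#' blocks are contiguous per combination. The defaults reproduce the
#' balanced 3780-trial layout used in the detection experiment: three
#' body-size proxies, two camera models, three lens heights, three aiming
#' distances, seven trial distances and ten replicates.
#'
#' @param factors Named list mapping factor name to its level vector.
#' @param replicates Positive integer; trials per combination.
#' @return A `trial_design` data frame with one column per factor plus a
#'   `replicate` index.
#' @examples
#' nrow(generate_design())  # 3780
#' generate_design(list(A = 1:2, B = letters[1:3]), replicates = 4)
#' @export
generate_design <- function(factors = default_trial_factors(),
                            replicates = 10L) {
  if (!is.list(factors) || length(factors) == 0L ||
      is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("'factors' must be a non-empty named list of level vectors",
         call. = FALSE)
  }
  if (any(lengths(factors) == 0L)) {
    stop("invalid design: factor '",
         names(factors)[which(lengths(factors) == 0L)[1L]],
         "' has an empty level list", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("'replicates' must be a positive integer", call. = FALSE)
  }
  # expand.grid varies the first factor fastest; reverse so the first
  # declared factor varies slowest, then restore column order.
  grid <- expand.grid(rev(factors), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[names(factors)]
  idx <- rep(seq_len(nrow(grid)), each = replicates)
  out <- grid[idx, , drop = FALSE]
  out$replicate <- rep(seq_len(replicates), times = nrow(grid))
  rownames(out) <- NULL
  attr(out, "factors") <- factors
  attr(out, "replicates") <- replicates
  class(out) <- c("trial_design", "data.frame")
  out
}

#' Factor levels of the standard detection experiment
#'
#' @return Named list of factor levels (body size, camera model, lens
#'   height in cm, aiming distance in m, trial distance in m).
#' @export
default_trial_factors <- function() {
  lv <- trial_levels()
  list(
    body_size = lv$body_size,
    camera_model = lv$camera_model,
    lens_height_cm = c(86, 116, 146),
    aiming_distance_m = c(5, 10, 15),
    distance_m = c(2, 4, 6, 8, 10, 12, 15)
  )
}

#' Read detection trials from CSV
#'
#' Expects the canonical schema (`trial_columns()` as header, UTF-8, `.`
#' decimal separator, empty string for missing optional positions). All row
#' contracts are validated; violations are reported with row numbers.
#'
#' @param path Path to a trial CSV file.
#' @return A `detection_trials` data frame (possibly zero rows).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_trial_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    for (col in c("first_x_m", "first_y_m")) {
      if (!col %in% names(raw)) raw[[col]] <- numeric(0)
    }
    raw <- raw[trial_columns()]
    lv <- trial_levels()
    raw$body_size <- factor(character(0), levels = lv$body_size)
    raw$camera_model <- factor(character(0), levels = lv$camera_model)
    class(raw) <- c("detection_trials", "data.frame")
    return(raw)
  }
  detection_trials(raw)
}

#' Write detection trials to CSV
#'
#' Inverse of [read_trials()]: the write-then-read round trip reproduces
#' all fields, with empty cells for missing optional positions.
#'
#' @param trials A `detection_trials` data frame (or coercible).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- as.data.frame(trials)
  out <- trials[intersect(trial_columns(), names(trials))]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Kernel density surface of mapped first-detection positions
#'
#' Gaussian kernel density estimate of where animals were first detected in
#' front of the camera, on a fixed grid covering the staked experimental
#' plot (x across the field of view, y the distance axis). `bandwidth` is
#' the kernel standard deviation in metres.
#'
#' @param points Two-column matrix or data frame of (x, y) positions in
#'   metres.
#' @param bandwidth Isotropic Gaussian kernel SD in metres (default 1.5).
#' @param xlim,ylim Grid extent in metres.
#' @param step Grid spacing in metres.
#' @return A list with `x`, `y` grid vectors and density matrix `z`
#'   (class `detection_density`); `z` integrates to ~1 over the plot frame.
#' @export
detection_position_density <- function(points, bandwidth = 1.5,
                                       xlim = c(-8, 8), ylim = c(0, 15),
                                       step = 0.1) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) {
    stop("at least one detection position is required", call. = FALSE)
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("'bandwidth' must be positive", call. = FALSE)
  }
  nx <- length(seq(xlim[1], xlim[2], by = step))
  ny <- length(seq(ylim[1], ylim[2], by = step))
  # MASS::kde2d divides its bandwidth argument by 4 before using it as the
  # normal-kernel SD; rescale so `bandwidth` is the SD the caption reports.
  kd <- MASS::kde2d(points[, 1], points[, 2], h = 4 * bandwidth,
                    n = c(nx, ny), lims = c(xlim, ylim))
  structure(list(x = kd$x, y = kd$y, z = kd$z, bandwidth = bandwidth),
            class = "detection_density")
}
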