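# Synthetic specimen phantoms as mass-thickness maps (nm of
# protein-equivalent material). Geometry is analytic and rasterized with
# 4x supersampling so symmetry holds at 1-2 nm/px; no randomness anywhere.
#
# Image convention: matrix row = y (downward), column = x (rightward);
# physical coordinates are centred on the canvas.

#' A 2D scalar field with a physical pixel size
#'
#' Container for mass-thickness phantoms and grayscale micrographs.
#'
#' @param values numeric matrix of non-negative values (rows = y, cols = x).
#' @param pixel_size physical pixel size, nm/px.
#' @export
image_grid <- function(values, pixel_size) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (any(values < 0) || any(!is.finite(values))) {
    stop("values must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be > 0 nm/px", call. = FALSE)
  }
  structure(list(values = values, pixel_size = pixel_size,
                 width = ncol(values), height = nrow(values)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px at %.3g nm/px, range [%.4g, %.4g]\n",
              x$width, x$height, x$pixel_size, min(x$values), max(x$values)))
  invisible(x)
}

# rasterize thickness_fn(x, y) (vectorized, nm coordinates centred on the
# canvas) onto a width x height grid with s x s supersampling
.rasterize <- function(width_px, height_px, pixel_size, thickness_fn,
                       supersample = 4L) {
  s <- as.integer(supersample)
  nx <- width_px * s
  ny <- height_px * s
  fx <- (seq_len(nx) - (nx + 1) / 2) * (pixel_size / s)
  fy <- (seq_len(ny) - (ny + 1) / 2) * (pixel_size / s)
  V <- outer(fy, fx, thickness_fn)
  # block-average s x s
  V <- rowsum(V, rep(seq_len(height_px), each = s))
  V <- t(rowsum(t(V), rep(seq_len(width_px), each = s))) / s^2
  dimnames(V) <- NULL
  image_grid(V, pixel_size)
}

# distance from (x, y) to the segment from (-hx, 0) to (hx, 0)
.dist_to_axis_segment <- function(x, y, hx) {
  cx <- pmin(pmax(x, -hx), hx)
  sqrt((x - cx)^2 + y^2)
}

#' Rod-shaped virion phantom
#'
#' A capsule (rounded-end rod) lying along x: a thin envelope rim, a denser
#' core, and `n_disks` evenly spaced dense discs along the axis standing in
#' for the packaged genome. Default dimensions sit inside the 200-350 nm
#' length / 60-100 nm diameter range typical of the rod virions this model
#' targets, with 30-nm internal discs.
#'
#' @param length total rod length (including end caps), nm; validated
#'   against \[200, 350\] unless `check_range = FALSE`.
#' @param diameter rod diameter, nm.
#' @param envelope envelope rim width, nm.
#' @param n_disks number of internal discs.
#' @param disk_diameter disc diameter, nm.
#' @param pixel_size nm/px.
#' @param canvas c(width_px, height_px); a fitting default is chosen when
#'   `NULL`.
#' @param thickness named vector of mass-thickness tiers (nm):
#'   `envelope`, `core`, `disk`.
#' @param check_range validate `length` against the typical virion range.
#' @return an [image_grid()] mass-thickness map.
#' @export
rod_virus_phantom <- function(length = 250, diameter = 80, envelope = 10,
                              n_disks = 6, disk_diameter = 30,
                              pixel_size = 2, canvas = NULL,
                              thickness = c(envelope = 25, core = 55,
                                            disk = 80),
                              check_range = TRUE) {
  if (check_range && (length < 200 || length > 350)) {
    stop("length outside the typical 200-350 nm range; ",
         "set check_range = FALSE to override", call. = FALSE)
  }
  if (diameter <= 2 * envelope) {
    stop("diameter must exceed twice the envelope width", call. = FALSE)
  }
  hx_env <- length / 2 - diameter / 2   # half-length of the capsule axis
  r_env <- diameter / 2
  r_core <- r_env - envelope
  hx_core <- hx_env  # core capsule shares the axis segment, smaller radius

  # disc centres evenly spread over the core's axial extent
  core_len <- 2 * hx_core + 2 * r_core
  if (n_disks > 0) {
    if (disk_diameter > 2 * r_core) {
      stop("disks do not fit inside the core radially", call. = FALSE)
    }
    span <- core_len - disk_diameter
    centers <- if (n_disks == 1L) 0 else
      seq(-span / 2, span / 2, length.out = n_disks)
    if (n_disks > 1L && (centers[2] - centers[1]) < disk_diameter) {
      stop("disks do not fit: axial spacing smaller than the disk diameter",
           call. = FALSE)
    }
  } else {
    centers <- numeric(0)
  }
  r_disk <- disk_diameter / 2

  fn <- function(y, x) {
    d <- .dist_to_axis_segment(x, y, hx_env)
    t <- ifelse(d <= r_env, thickness[["envelope"]], 0)
    t <- ifelse(d <= r_core, thickness[["core"]], t)
    if (base::length(centers) > 0) {
      indisk <- Reduce(`|`, lapply(centers, function(cx) {
        (x - cx)^2 + y^2 <= r_disk^2
      }))
      t <- ifelse(indisk & d <= r_core, thickness[["disk"]], t)
    }
    t
  }
  if (is.null(canvas)) {
    canvas <- c(ceiling((length + 20) / pixel_size),
                ceiling((diameter + 20) / pixel_size))
  }
  .rasterize(canvas[1L], canvas[2L], pixel_size, fn)
}

#' Star-shaped pentamer phantom
#'
#' A dense central disc with `n_arms` radial arms at equal angular spacing,
#' emulating the star-shaped pentameric antibody (five arms at 72 degrees,
#' outer diameter about 45 nm, 20-nm dense centre).
#'
#' @param outer_diameter tip-to-tip diameter of the star, nm.
#' @param centre_diameter diameter of the dense central disc, nm.
#' @param n_arms number of arms.
#' @param arm_width arm width, nm.
#' @param pixel_size nm/px.
#' @param canvas c(width_px, height_px); default fits the star.
#' @param thickness named tiers (nm): `arm`, `centre`.
#' @param phase rotation of the whole star, rad.
#' @export
star_pentamer_phantom <- function(outer_diameter = 45, centre_diameter = 20,
                                  n_arms = 5, arm_width = 8, pixel_size = 1,
                                  canvas = NULL,
                                  thickness = c(arm = 12, centre = 25),
                                  phase = pi / 2) {
  if (centre_diameter >= outer_diameter) {
    stop("centre_diameter must be smaller than outer_diameter", call. = FALSE)
  }
  if (n_arms < 1) stop("n_arms must be >= 1", call. = FALSE)
  r_out <- outer_diameter / 2
  r_c <- centre_diameter / 2
  r_arm <- arm_width / 2
  arm_len <- r_out - r_arm  # capsule end cap reaches exactly r_out
  angles <- phase + 2 * pi * (seq_len(n_arms) - 1) / n_arms

  fn <- function(y, x) {
    t <- ifelse(x^2 + y^2 <= r_c^2, thickness[["centre"]], 0)
    inarm <- Reduce(`|`, lapply(angles, function(a) {
      # rotate so the arm lies along +x, then capsule distance to [0, arm_len]
      xr <- cos(a) * x + sin(a) * y
      yr <- -sin(a) * x + cos(a) * y
      cx <- pmin(pmax(xr, 0), arm_len)
      (xr - cx)^2 + yr^2 <= r_arm^2
    }))
    ifelse(inarm & t == 0, thickness[["arm"]], t)
  }
  if (is.null(canvas)) {
    side <- ceiling((outer_diameter + 16) / pixel_size)
    canvas <- c(side, side)
  }
  .rasterize(canvas[1L], canvas[2L], pixel_size, fn)
}

#' Dumbbell-shaped particle phantom
#'
#' A barrel core capped on both ends by thicker discs, lying along x;
#' models the dumbbell silhouette of the 26S proteasome (two regulatory
#' caps on the 20S core, total length ~52 nm).
#'
#' @param total_length axial extent, nm.
#' @param cap_diameter end-cap diameter, nm; must exceed `core_diameter`.
#' @param core_diameter barrel diameter, nm.
#' @param pixel_size nm/px.
#' @param canvas c(width_px, height_px).
#' @param thickness named tiers (nm): `core`, `cap`.
#' @export
dumbbell_phantom <- function(total_length = 52, cap_diameter = 17,
                             core_diameter = 12, pixel_size = 1,
                             canvas = NULL,
                             thickness = c(core = 14, cap = 24)) {
  if (cap_diameter <= core_diameter) {
    stop("cap_diameter must exceed core_diameter", call. = FALSE)
  }
  if (total_length <= 2 * cap_diameter) {
    stop("total_length must exceed two cap diameters", call. = FALSE)
  }
  r_cap <- cap_diameter / 2
  r_core <- core_diameter / 2
  cx_cap <- total_length / 2 - r_cap  # cap centres; outer rim at total/2

  fn <- function(y, x) {
    incap <- ((abs(x) - cx_cap)^2 + y^2 <= r_cap^2)
    incore <- (abs(x) <= cx_cap & abs(y) <= r_core)
    ifelse(incap, thickness[["cap"]],
           ifelse(incore, thickness[["core"]], 0))
  }
  if (is.null(canvas)) {
    canvas <- c(ceiling((total_length + 16) / pixel_size),
                ceiling((cap_diameter + 16) / pixel_size))
  }
  .rasterize(canvas[1L], canvas[2L], pixel_size, fn)
}

#' Straight-edge resolution target
#'
#' A binary thickness step along x: columns at and beyond `edge_position`
#' carry `thickness`, earlier columns are empty. Rendered exactly (no
#' supersampling).
#'
#' @param edge_position 1-based column index of the first covered column.
#' @param thickness step height, nm.
#' @param pixel_size nm/px.
#' @param canvas c(width_px, height_px).
#' @export
edge_phantom <- function(edge_position, thickness = 50, pixel_size = 1,
                         canvas = c(128, 128)) {
  w <- as.integer(canvas[1L]); h <- as.integer(canvas[2L])
  if (edge_position < 1 || edge_position > w) {
    stop("edge_position must lie inside the canvas", call. = FALSE)
  }
  if (thickness < 0) stop("thickness must be >= 0", call. = FALSE)
  V <- matrix(0, nrow = h, ncol = w)
  if (thickness > 0) V[, seq(edge_position, w)] <- thickness
  image_grid(V, pixel_size)
}
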