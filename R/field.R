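#' DBS electrode geometry
#'
#' Cylindrical four-contact lead geometry in a right-handed Cartesian mm
#' frame. By default the frame origin is the center of the active contact
#' and the lead axis points along +z; `tip_position` is then derived from
#' the contact layout (tip gap plus `active_contact` full contact pitches
#' plus half a contact length below the origin).
#'
#' @param contact_length_mm Contact length (mm).
#' @param contact_spacing_mm Gap between contacts (mm).
#' @param shaft_radius_mm Lead shaft radius (mm).
#' @param active_contact Active (cathodic) contact index, 0-3.
#' @param encapsulation_thickness_mm Encapsulation layer thickness (mm).
#' @param tip_gap_mm Distance from lead tip to the first contact (mm).
#' @param tip_position Lead tip position (mm), or `NULL` to place the active
#'   contact center at the origin.
#' @param axis_direction Unit vector of the lead axis (normalized
#'   internally).
#' @return Object of class `electrode_spec`.
#' @export
#' @examples
#' e <- electrode_spec()
#' contact_center(e)           # c(0, 0, 0)
#' contact_area_cm2(e)         # ~0.0599 cm^2
electrode_spec <- function(contact_length_mm = 1.5,
                           contact_spacing_mm = 0.5,
                           shaft_radius_mm = 0.635,
                           active_contact = 2L,
                           encapsulation_thickness_mm = 0.5,
                           tip_gap_mm = 1.5,
                           tip_position = NULL,
                           axis_direction = c(0, 0, 1)) {
  stopifnot(contact_length_mm > 0, contact_spacing_mm >= 0,
            shaft_radius_mm > 0, encapsulation_thickness_mm > 0,
            active_contact %in% 0:3)
  axis_direction <- axis_direction / sqrt(sum(axis_direction^2))
  offset <- tip_gap_mm + active_contact * (contact_length_mm + contact_spacing_mm) +
    contact_length_mm / 2
  if (is.null(tip_position)) tip_position <- -offset * axis_direction
  structure(list(contact_length_mm = contact_length_mm,
                 contact_spacing_mm = contact_spacing_mm,
                 shaft_radius_mm = shaft_radius_mm,
                 active_contact = as.integer(active_contact),
                 encapsulation_thickness_mm = encapsulation_thickness_mm,
                 tip_gap_mm = tip_gap_mm,
                 tip_position = tip_position,
                 axis_direction = axis_direction),
            class = "electrode_spec")
}

#' @rdname electrode_spec
#' @param spec An `electrode_spec`.
#' @param contact Contact index (defaults to the active contact).
#' @export
contact_center <- function(spec, contact = spec$active_contact) {
  offset <- spec$tip_gap_mm +
    contact * (spec$contact_length_mm + spec$contact_spacing_mm) +
    spec$contact_length_mm / 2
  spec$tip_position + offset * spec$axis_direction
}

#' @rdname electrode_spec
#' @export
contact_area_cm2 <- function(spec) {
  pi * 2 * spec$shaft_radius_mm * spec$contact_length_mm / 100
}

#' Distance of points from the electrode axis
#'
#' Perpendicular distance (mm) of each row of `points` from the infinite
#' line through the lead, used for electrode-collision tests.
#'
#' @param spec An `electrode_spec`.
#' @param points Numeric matrix (n x 3), mm.
#' @return Numeric vector of distances (mm).
#' @export
axis_distance <- function(spec, points) {
  points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, spec$tip_position)
  t_par <- rel %*% spec$axis_direction
  perp <- rel - t_par %*% t(spec$axis_direction)
  sqrt(rowSums(perp^2))
}

#' Map diffusion tensors to conductivity tensors (load preservation)
#'
#' Each voxel's conductivity tensor shares the eigenvectors of its diffusion
#' tensor; the conductivity eigenvalues are the diffusion eigenvalues scaled
#' so their geometric mean equals `sigma_iso` (volume-normalized load
#' preservation). The determinant of every output tensor is therefore
#' `sigma_iso^3`.
#'
#' @param tensors Numeric matrix (n x 6) of upper-triangle diffusion-tensor
#'   components (xx, xy, xz, yy, yz, zz; units mm^2/s), one voxel per row.
#' @param sigma_iso Reference isotropic conductivity (S/m).
#' @return Matrix (n x 6) of conductivity tensors (S/m) in the same layout.
#' @export
#' @examples
#' conductivity_from_diffusion(rbind(c(1e-3, 0, 0, 1e-3, 0, 1e-3)), 0.2)
conductivity_from_diffusion <- function(tensors, sigma_iso = 0.2) {
  tensors <- matrix(tensors, ncol = 6)
  stopifnot(sigma_iso > 0)
  out <- matrix(NA_real_, nrow(tensors), 6)
  colnames(out) <- c("xx", "xy", "xz", "yy", "yz", "zz")
  for (v in seq_len(nrow(tensors))) {
    d <- tensors[v, ]
    Dm <- matrix(c(d[1], d[2], d[3],
                   d[2], d[4], d[5],
                   d[3], d[5], d[6]), 3, 3)
    eg <- eigen(Dm, symmetric = TRUE)
    if (any(eg$values <= 0))
      stop(sprintf("diffusion tensor in voxel %d is not positive definite", v))
    lam <- sigma_iso * eg$values / exp(mean(log(eg$values)))
    Sm <- eg$vectors %*% diag(lam) %*% t(eg$vectors)
    out[v, ] <- Sm[c(1, 4, 7, 5, 8, 9)]
  }
  out
}

#' Analytic surrogate for the unit static extracellular potential
#'
#' Replaces the finite-element volume-conductor solution with a
#' spherical-equivalent model: the active cylindrical contact is replaced by
#' a sphere of equal surface area (radius `a`), surrounded by a concentric
#' encapsulation shell of the given thickness (outer radius `b`) in an
#' infinite homogeneous medium. The potential is -1 V on the equivalent
#' contact surface, continuous at the shell boundary, and decays as 1/r
#' outside; the access resistance is
#' `(1/4pi) * ((1/sigma_enc) (1/a - 1/b) + 1/(sigma_tissue * b))`.
#'
#' With a 3x3 `sigma_tissue` tensor the far-field potential uses the
#' anisotropic point-source closed form, proportional to
#' `1 / sqrt(r' solve(sigma) r)`, scaled to -1 V on the equivalent surface;
#' the access resistance then uses the geometric mean of the conductivity
#' eigenvalues as the bulk conductivity.
#'
#' @param electrode [electrode_spec()].
#' @param sigma_tissue_S_m Bulk tissue conductivity: scalar (S/m) or
#'   symmetric positive-definite 3x3 tensor.
#' @param sigma_enc_S_m Encapsulation layer conductivity (S/m).
#' @return Object of class `field_model` with elements `kind`, `phi`
#'   (function: n x 3 mm matrix -> potentials in V for -1 V drive),
#'   `access_resistance_ohm`, `sigma_enc_S_m`, and `electrode`.
#' @export
#' @examples
#' f <- build_analytic_field(electrode_spec(), 0.2, 0.1)
#' f$access_resistance_ohm
build_analytic_field <- function(electrode, sigma_tissue_S_m = 0.2,
                                 sigma_enc_S_m = 0.1) {
  stopifnot(inherits(electrode, "electrode_spec"), all(sigma_enc_S_m > 0))
  a_mm <- sqrt(contact_area_cm2(electrode) * 100 / (4 * pi)) # equal-area sphere
  b_mm <- a_mm + electrode$encapsulation_thickness_mm
  a_m <- a_mm * 1e-3
  b_m <- b_mm * 1e-3
  center <- contact_center(electrode)

  aniso <- is.matrix(sigma_tissue_S_m)
  if (aniso) {
    eg <- eigen(sigma_tissue_S_m, symmetric = TRUE)
    if (any(eg$values <= 0)) stop("sigma_tissue tensor must be positive definite")
    sig_t <- exp(mean(log(eg$values)))
    sig_norm <- sigma_tissue_S_m / sig_t  # unit-determinant shape tensor
    sig_norm_inv <- solve(sig_norm)
  } else {
    if (sigma_tissue_S_m <= 0) stop("conductivities must be positive")
    sig_t <- sigma_tissue_S_m
  }

  r_acc <- (1 / (4 * pi)) * ((1 / sigma_enc_S_m) * (1 / a_m - 1 / b_m) +
                               1 / (sig_t * b_m))
  # potential profile for -1 V at r = a (radii in mm below)
  i_tot <- -1 / r_acc # A, cathodic
  phi_shell <- function(r_mm) {
    i_tot / (4 * pi * sigma_enc_S_m * r_mm * 1e-3) +
      i_tot / (4 * pi * b_m) * (1 / sig_t - 1 / sigma_enc_S_m)
  }
  phi_out_iso <- function(r_mm) i_tot / (4 * pi * sig_t * r_mm * 1e-3)

  phi <- function(points) {
    points <- matrix(points, ncol = 3)
    if (any(!is.finite(points))) stop("points must be finite")
    rel <- sweep(points, 2, center)
    if (aniso) {
      reff <- sqrt(rowSums((rel %*% sig_norm_inv) * rel))
      val <- -a_mm / pmax(reff, a_mm)
    } else {
      r <- sqrt(rowSums(rel^2))
      val <- ifelse(r <= a_mm, -1,
                    ifelse(r <= b_mm, phi_shell(r), phi_out_iso(r)))
    }
    as.numeric(val)
  }

  structure(list(kind = if (aniso) "analytic-anisotropic" else "analytic-isotropic",
                 phi = phi, access_resistance_ohm = r_acc,
                 sigma_enc_S_m = sigma_enc_S_m, electrode = electrode),
            class = "field_model")
}

#' @export
print.field_model <- function(x, ...) {
  cat(sprintf("Field model (%s): access resistance %.4g Ohm, sigma_enc %.3g S/m\n",
              x$kind, x$access_resistance_ohm, x$sigma_enc_S_m))
  invisible(x)
}

#' Scale a field model's potentials by a constant
#'
#' Because the static problem is linear, scaling the unit potential by `k`
#' scales every downstream activation threshold by `1/k`.
#'
#' @param field A `field_model`.
#' @param k Scale factor.
#' @return A `field_model` whose evaluator returns `k` times the original.
#' @export
scale_field <- function(field, k) {
  phi0 <- field$phi
  field$phi <- function(points) k * phi0(points)
  field$kind <- paste0(field$kind, "-scaled")
  field
}

#' Export / import a unit potential sampled on a structured grid
#'
#' Plain-text structured-points format: header lines give origin, spacing,
#' dimensions, access resistance and encapsulation conductivity; data lines
#' hold the potential (V, -1 V drive) with x varying fastest, then y, then
#' z. The imported evaluator interpolates trilinearly inside the grid and
#' returns 0 (flagged) outside.
#'
#' @param field A `field_model` to sample.
#' @param path File path.
#' @param origin_mm,spacing_mm,dims Grid origin (mm), spacing (mm, scalar or
#'   length-3), and dimensions (nx, ny, nz).
#' @return `save_field_grid` returns `path` invisibly; `load_field_grid`
#'   returns a `field_model` of kind `"grid"`.
#' @export
save_field_grid <- function(field, path, origin_mm, spacing_mm, dims) {
  spacing_mm <- rep(spacing_mm, length.out = 3)
  stopifnot(all(spacing_mm > 0), all(dims >= 2))
  g <- expand.grid(x = origin_mm[1] + (seq_len(dims[1]) - 1) * spacing_mm[1],
                   y = origin_mm[2] + (seq_len(dims[2]) - 1) * spacing_mm[2],
                   z = origin_mm[3] + (seq_len(dims[3]) - 1) * spacing_mm[3])
  vals <- field$phi(as.matrix(g))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pamsim field grid v1",
               sprintf("# origin_mm: %.17g %.17g %.17g", origin_mm[1],
                       origin_mm[2], origin_mm[3]),
               sprintf("# spacing_mm: %.17g %.17g %.17g", spacing_mm[1],
                       spacing_mm[2], spacing_mm[3]),
               sprintf("# dims: %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("# access_resistance_ohm: %.17g",
                       field$access_resistance_ohm),
               sprintf("# sigma_enc_S_m: %.17g", field$sigma_enc_S_m)), con)
  writeLines(sprintf("%.17g", vals), con)
  invisible(path)
}

#' @rdname save_field_grid
#' @export
load_field_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key, n) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (!length(ln)) stop("malformed grid header: missing ", key)
    v <- as.numeric(strsplit(trimws(sub(paste0("^# ", key, ": *"), "", ln[1])),
                             " +")[[1]])
    if (length(v) != n) stop("malformed grid header: ", key)
    v
  }
  origin <- get("origin_mm", 3)
  spacing <- get("spacing_mm", 3)
  dims <- as.integer(get("dims", 3))
  r_acc <- get("access_resistance_ohm", 1)
  sig_enc <- get("sigma_enc_S_m", 1)
  vals <- as.numeric(lines[!startsWith(lines, "#")])
  if (length(vals) != prod(dims)) stop("grid data length does not match dims")
  arr <- array(vals, dim = dims)

  phi <- function(points) {
    points <- matrix(points, ncol = 3)
    fx <- (points[, 1] - origin[1]) / spacing[1]
    fy <- (points[, 2] - origin[2]) / spacing[2]
    fz <- (points[, 3] - origin[3]) / spacing[3]
    inside <- fx >= 0 & fx <= dims[1] - 1 & fy >= 0 & fy <= dims[2] - 1 &
      fz >= 0 & fz <= dims[3] - 1
    out <- numeric(nrow(points))
    if (any(inside)) {
      i0 <- pmin(floor(fx[inside]), dims[1] - 2); wx <- fx[inside] - i0
      j0 <- pmin(floor(fy[inside]), dims[2] - 2); wy <- fy[inside] - j0
      k0 <- pmin(floor(fz[inside]), dims[3] - 2); wz <- fz[inside] - k0
      at <- function(di, dj, dk) arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
      out[inside] <-
        (1 - wx) * (1 - wy) * (1 - wz) * at(0, 0, 0) +
        wx * (1 - wy) * (1 - wz) * at(1, 0, 0) +
        (1 - wx) * wy * (1 - wz) * at(0, 1, 0) +
        wx * wy * (1 - wz) * at(1, 1, 0) +
        (1 - wx) * (1 - wy) * wz * at(0, 0, 1) +
        wx * (1 - wy) * wz * at(1, 0, 1) +
        (1 - wx) * wy * wz * at(0, 1, 1) +
        wx * wy * wz * at(1, 1, 1)
    }
    attr(out, "outside") <- !inside
    out
  }

  structure(list(kind = "grid", phi = phi, access_resistance_ohm = r_acc,
                 sigma_enc_S_m = sig_enc, electrode = NULL,
                 grid = list(origin_mm = origin, spacing_mm = spacing,
                             dims = dims)),
            class = "field_model")
}

#' Sample the unit potential at a set of points
#'
#' @param field A `field_model`.
#' @param points Numeric matrix (n x 3), mm.
#' @return Potentials (V) for -1 V drive at the active contact. For grid
#'   fields, points outside the grid return 0 and are flagged in the
#'   `outside` attribute.
#' @export
sample_potentials <- function(field, points) {
  stopifnot(inherits(field, "field_model"))
  field$phi(points)
}

#' Compose the space-time extracellular potential
#'
#' Separable composition of a static unit-potential sample with the
#' stimulus amplitude and the normalized tissue waveform: the output at
#' point i and time j is `static[i] * amplitude * waveform$values[j]`.
#'
#' @param static Potentials (V) at the points of interest for -1 V drive.
#' @param amplitude_V Stimulus amplitude (V), >= 0.
#' @param waveform A `tissue_waveform`.
#' @return Matrix (length(static) x length(times)) of potentials (V).
#' @export
compose_spacetime <- function(static, amplitude_V, waveform) {
  stopifnot(amplitude_V >= 0, inherits(waveform, "tissue_waveform"))
  outer(as.numeric(static), amplitude_V * waveform$values)
}
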