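#' Streamline objects
#'
#' An ordered 3D polyline (mm) with its cumulative arc-length table.
#'
#' @param points Numeric matrix (n x 3), n >= 2, finite.
#' @return Object of class `streamline` with elements `points` and
#'   `arc_mm`.
#' @export
streamline <- function(points) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 2) stop("a streamline needs at least 2 points")
  if (any(!is.finite(points))) stop("streamline points must be finite")
  seg <- sqrt(rowSums(diff(points)^2))
  structure(list(points = points, arc_mm = c(0, cumsum(seg))),
            class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("Streamline: %d points, %.2f mm\n", nrow(x$points),
              max(x$arc_mm)))
  invisible(x)
}

#' Total arc length of a streamline (mm)
#' @param s A `streamline`.
#' @export
arc_length <- function(s) max(s$arc_mm)

# linear interpolation of streamline coordinates at arc positions (mm)
.interp_at_arc <- function(s, at) {
  cbind(stats::approx(s$arc_mm, s$points[, 1], at, rule = 2)$y,
        stats::approx(s$arc_mm, s$points[, 2], at, rule = 2)$y,
        stats::approx(s$arc_mm, s$points[, 3], at, rule = 2)$y)
}

#' Synthetic corticofugal streamline bundle
#'
#' Stand-in for probabilistic tractography output: a bundle of smooth
#' curves sweeping from a cortical cap, past the electrode, to a brainstem
#' cap. Each curve is the bundle centerline (a bowed path from `start` to
#' `end`), displaced by a per-streamline Gaussian lateral offset
#' (`bundle_sd_mm`) and corrupted by independent per-point Gaussian jitter
#' (`jitter_sd_mm`) mimicking tractography noise.
#'
#' @param n Number of streamlines.
#' @param bundle_spec List with `start`, `end` (3-vectors, mm), `bow_mm`
#'   (lateral bow of the centerline), `bundle_sd_mm` (per-streamline radial
#'   spread), `n_points` (samples per streamline).
#' @param jitter_sd_mm Per-point jitter standard deviation (mm).
#' @param seed Optional integer seed for reproducibility.
#' @return List of [streamline()] objects.
#' @export
#' @examples
#' sl <- generate_streamlines(3, seed = 1)
#' length(sl)
generate_streamlines <- function(n,
                                 bundle_spec = list(start = c(4, 0, 28),
                                                    end = c(7, 3, -28),
                                                    bow_mm = 3,
                                                    bundle_sd_mm = 1.5,
                                                    n_points = 113),
                                 jitter_sd_mm = 0.3,
                                 seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  start <- bundle_spec$start; end <- bundle_spec$end
  if (sqrt(sum((end - start)^2)) < 1e-9) stop("degenerate bundle: zero length")
  np <- bundle_spec$n_points
  tt <- seq(0, 1, length.out = np)
  main_dir <- (end - start) / sqrt(sum((end - start)^2))
  # two directions orthogonal to the bundle axis
  ref <- if (abs(main_dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- ref - sum(ref * main_dir) * main_dir
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(main_dir[2] * u1[3] - main_dir[3] * u1[2],
          main_dir[3] * u1[1] - main_dir[1] * u1[3],
          main_dir[1] * u1[2] - main_dir[2] * u1[1])
  center <- outer(1 - tt, start) + outer(tt, end) +
    outer(sin(pi * tt) * bundle_spec$bow_mm, u1)
  lapply(seq_len(n), function(i) {
    off <- stats::rnorm(2, 0, bundle_spec$bundle_sd_mm)
    pts <- center + matrix(off[1] * u1 + off[2] * u2, np, 3, byrow = TRUE)
    if (jitter_sd_mm > 0)
      pts <- pts + matrix(stats::rnorm(3 * np, 0, jitter_sd_mm), np, 3)
    streamline(pts)
  })
}

#' Fit a smoothing spline to a streamline
#'
#' Fits an independent cubic smoothing spline to each coordinate as a
#' function of the input arc length, then resamples the smoothed curve at a
#' uniform arc-length step. Smoothing removes the high-frequency point
#' jitter of probabilistic tractography that otherwise injects noise into
#' the second spatial differences of the sampled extracellular potential
#' (the effective driving term of extracellular stimulation).
#'
#' @param s A [streamline()].
#' @param smoothing Smoothing level: `NULL` (default) projects each
#'   coordinate onto a cubic B-spline basis with knots every
#'   `knot_spacing_mm` — a projection, so re-smoothing an already smoothed
#'   streamline leaves it essentially unchanged; a value in `(0, 1]` is
#'   passed as `spar` to [stats::smooth.spline()] (penalized smoothing);
#'   `0` gives an interpolating spline through every input point.
#' @param resample_step_mm Output sampling step along the curve (mm).
#' @param knot_spacing_mm Knot spacing of the default projection basis
#'   (mm); sets the shortest geometric wavelength the smoothed curve keeps.
#' @return A `streamline` resampled on the smoothed curve.
#' @export
fit_smoothing_spline <- function(s, smoothing = NULL, resample_step_mm = 0.5,
                                 knot_spacing_mm = 6) {
  stopifnot(inherits(s, "streamline"))
  if (nrow(s$points) < 4) stop("need at least 4 points to fit a spline")
  densify <- function(cur) {
    # piecewise-linear dense resampling, used only for arc-length
    # measurement and for the interpolating (smoothing = 0) mode
    L <- arc_length(cur)
    at <- seq(0, L, length.out = max(200, 8 * ceiling(L / resample_step_mm)))
    streamline(.interp_at_arc(cur, at))
  }
  respline_arc <- function(cur) {
    # arc length re-measured on a cubic interpolant through the vertices:
    # the chord-sum arc of a sampled smooth curve lags the true arc, and
    # that lag would otherwise shift every vertex parameter between passes
    n <- nrow(cur$points)
    tfine <- seq(1, n, by = 0.1)
    fine <- vapply(1:3, function(j)
      stats::spline(seq_len(n), cur$points[, j], xout = tfine,
                    method = "natural")$y, numeric(length(tfine)))
    cum <- c(0, cumsum(sqrt(rowSums(diff(fine)^2))))
    cum[match(seq_len(n), tfine)]
  }
  fit_pass <- function(cur) {
    # weighted projection of the input vertices onto a cubic B-spline
    # basis. The knot grid is anchored at multiples of the knot spacing
    # (so re-smoothing an already smooth curve reuses the same basis and
    # reproduces it), the endpoints are pinned, and a whisper of ridge
    # keeps the weakly supported basis functions at the far end well posed.
    cur$arc_mm <- respline_arc(cur)
    L <- arc_length(cur)
    # the knot grid (interior knots and upper boundary) is quantized to
    # multiples of the spacing, so the small arc-length drifts that
    # resampling introduces between passes never change the basis
    hi <- knot_spacing_mm * ceiling((L + knot_spacing_mm / 2) /
                                      knot_spacing_mm)
    knots <- seq(knot_spacing_mm, hi - knot_spacing_mm / 2,
                 by = knot_spacing_mm)
    bk <- c(0, hi)
    basis <- splines::bs(cur$arc_mm, knots = knots, intercept = TRUE,
                         Boundary.knots = bk)
    wgt <- rep(1, nrow(basis))
    wgt[c(1, length(wgt))] <- 1e4
    btb <- crossprod(basis * wgt, basis)
    diag(btb) <- diag(btb) + 1e-8 * mean(diag(btb))
    beta <- solve(btb, crossprod(basis * wgt, cur$points))
    dense_at <- seq(0, L, length.out = max(200, 8 * ceiling(L / resample_step_mm)))
    basis_out <- splines::bs(dense_at, knots = knots, intercept = TRUE,
                             Boundary.knots = bk)
    streamline(basis_out %*% beta)
  }
  resample <- function(sm) {
    L_sm <- arc_length(sm)
    # uniform spacing as close to resample_step_mm as divides the length
    # exactly: a short trailing segment would make the end vertex spacing
    # irregular and the arc measurement there noisy
    grid <- seq(0, L_sm,
                length.out = max(3, round(L_sm / resample_step_mm) + 1))
    streamline(.interp_at_arc(sm, grid))
  }
  if (!is.null(smoothing) && smoothing == 0)
    return(resample(densify(s)))
  if (!is.null(smoothing)) {
    L <- arc_length(s)
    dense <- seq(0, L, by = resample_step_mm / 4)
    return(resample(streamline(vapply(1:3, function(j)
      stats::predict(stats::smooth.spline(s$arc_mm, s$points[, j],
                                          spar = smoothing), dense)$y,
      numeric(length(dense))))))
  }
  # two projection passes: the first removes the jitter (whose arc-length
  # inflation distorts the knot parameterization), the second projects
  # with knots on the now-geometric arc length
  resample(fit_pass(fit_pass(s)))
}

#' Double-cable fiber geometry for a given myelin diameter
#'
#' Per-compartment dimensions of the myelinated double-cable axon model:
#' each internode is one node of Ranvier, two myelin attachment segments
#' (MYSA), two paranode main segments (FLUT) and six internodal segments
#' (STIN). For the nine published fiber diameters (5.7-16 um) the published
#' table is used, with linear interpolation between bracketing published
#' diameters for intermediate sizes. Below the published range (e.g. the
#' 1.8 um collateral) diameters, segment lengths and lamellae scale
#' proportionally with the fiber diameter, with the node and MYSA lengths
#' held at their table-constant 1 um and 3 um.
#'
#' @param diameter_um Myelin (fiber) diameter (um).
#' @return Object of class `fiber_geometry`: lengths and diameters (um) per
#'   compartment type, internodal spacing `internode_um`, lamellae count,
#'   and periaxonal space widths (um).
#' @export
#' @examples
#' fiber_geometry(5.7)$internode_um  # 500
fiber_geometry <- function(diameter_um) {
  stopifnot(diameter_um > 0)
  tab <- data.frame(
    d = c(5.7, 7.3, 8.7, 10, 11.5, 12.8, 14, 15, 16),
    node_diam = c(1.9, 2.4, 2.8, 3.3, 3.7, 4.2, 4.7, 5.0, 5.5),
    axon_diam = c(3.4, 4.6, 5.8, 6.9, 8.1, 9.2, 10.4, 11.5, 12.7),
    flut_len = c(35, 38, 40, 46, 50, 54, 56, 58, 60),
    deltax = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
    lamellae = c(80, 100, 110, 120, 130, 135, 140, 145, 150))
  ip <- function(col) {
    if (diameter_um >= tab$d[1])
      stats::approx(tab$d, tab[[col]], diameter_um, rule = 2)$y
    else # proportional scaling below the published table
      tab[[col]][1] * diameter_um / tab$d[1]
  }
  node_len <- 1; mysa_len <- 3
  deltax <- ip("deltax")
  flut_len <- ip("flut_len")
  stin_len <- (deltax - node_len - 2 * mysa_len - 2 * flut_len) / 6
  if (stin_len <= 0) stop("inconsistent geometry: non-positive STIN length")
  structure(list(diameter_um = diameter_um,
                 node_length_um = node_len, node_diameter_um = ip("node_diam"),
                 mysa_length_um = mysa_len, mysa_diameter_um = ip("node_diam"),
                 flut_length_um = flut_len, flut_diameter_um = ip("axon_diam"),
                 stin_length_um = stin_len, stin_diameter_um = ip("axon_diam"),
                 internode_um = deltax,
                 n_lamellae = ip("lamellae"),
                 periaxonal_um = c(node = 0.002, mysa = 0.002,
                                   flut = 0.004, stin = 0.004)),
            class = "fiber_geometry")
}

# arc positions (mm) of node-of-Ranvier centers along a curve of length L_mm
.node_arc_positions <- function(geom, L_mm) {
  step <- geom$internode_um / 1000
  first <- geom$node_length_um / 2000
  pos <- seq(first, L_mm, by = step)
  pos[pos <= L_mm]
}

#' Anatomy context for collateral construction
#'
#' @param stn_mask Matrix (n x 3) of voxel-center coordinates (mm) standing
#'   in for the subthalamic nucleus.
#' @param voxel_size_mm Isotropic voxel edge length (mm).
#' @param electrode [electrode_spec()] used for collision tests and for the
#'   axial frame.
#' @return Object of class `anatomy_context`.
#' @export
anatomy_context <- function(stn_mask, voxel_size_mm = 0.5,
                            electrode = electrode_spec()) {
  stn_mask <- matrix(stn_mask, ncol = 3)
  if (nrow(stn_mask) < 1) stop("STN mask must be non-empty")
  if (voxel_size_mm <= 0) stop("voxel size must be positive")
  structure(list(stn_mask = stn_mask, voxel_size_mm = voxel_size_mm,
                 electrode = electrode),
            class = "anatomy_context")
}

# planar circular arc from A to B bulging along unit vector m_hat
.circular_arc <- function(A, B, m_hat, bulge_frac, step_mm = 0.25) {
  chord <- sqrt(sum((B - A)^2))
  if (bulge_frac <= 0) { # straight-line fallback
    npts <- max(9, ceiling(chord / step_mm) + 1)
    tt <- seq(0, 1, length.out = npts)
    return(outer(1 - tt, A) + outer(tt, B))
  }
  h <- bulge_frac * chord
  R <- chord^2 / (8 * h) + h / 2
  M <- (A + B) / 2
  O <- M - (R - h) * m_hat
  v1 <- A - O; v2 <- B - O
  theta <- acos(max(-1, min(1, sum(v1 * v2) / (R^2))))
  e1 <- v1 / R
  e2p <- v2 - sum(v2 * e1) * e1
  e2 <- e2p / sqrt(sum(e2p^2))
  npts <- max(9, ceiling(R * theta / step_mm) + 1)
  ang <- seq(0, theta, length.out = npts)
  outer(cos(ang), R * e1) + outer(sin(ang), R * e2) +
    matrix(O, npts, 3, byrow = TRUE)
}

#' Attach a subthalamic collateral to a corticofugal streamline
#'
#' Selects a branch node of Ranvier uniformly among the main-path nodes
#' lying within the axial bounds of the STN mask (its extent along the
#' electrode axis), selects a termination voxel uniformly within the mask,
#' and connects them with a planar circular arc lying in the plane spanned
#' by the chord and the electrode axis, bulging away from the electrode.
#' If the arc intersects the electrode shaft a different voxel is drawn, up
#' to `max_attempts` times. Uses the current R random number generator
#' state.
#'
#' @param main A [streamline()] (already smoothed/resampled).
#' @param main_geom [fiber_geometry()] of the corticofugal axon (node
#'   spacing determines candidate branch points).
#' @param anatomy [anatomy_context()].
#' @param arc_bulge Arc sagitta as a fraction of the chord length; 0 gives
#'   a straight-line collateral.
#' @param max_attempts Maximum voxel redraws on electrode collision.
#' @return Object of class `axon_trajectory` with `main`, `collateral` (a
#'   `streamline`), and `branch_node_index` (node index on the main path).
#' @export
build_collateral <- function(main, main_geom, anatomy, arc_bulge = 0.25,
                             max_attempts = 100) {
  stopifnot(inherits(main, "streamline"), inherits(main_geom, "fiber_geometry"),
            inherits(anatomy, "anatomy_context"))
  el <- anatomy$electrode
  axis_of <- function(pts) as.numeric(sweep(matrix(pts, ncol = 3), 2,
                                            el$tip_position) %*%
                                        el$axis_direction)
  stn_ax <- range(axis_of(anatomy$stn_mask))
  node_arc <- .node_arc_positions(main_geom, arc_length(main))
  node_pts <- .interp_at_arc(main, node_arc)
  eligible <- which(axis_of(node_pts) >= stn_ax[1] &
                      axis_of(node_pts) <= stn_ax[2])
  if (!length(eligible))
    stop("no node of Ranvier within the axial bounds of the STN mask")

  branch_idx <- if (length(eligible) == 1) eligible else sample(eligible, 1)
  B <- node_pts[branch_idx, ]

  nvox <- nrow(anatomy$stn_mask)
  for (att in seq_len(max_attempts)) {
    vox <- if (nvox == 1) 1L else sample.int(nvox, 1)
    Tg <- anatomy$stn_mask[vox, ]
    chord <- Tg - B
    n_pl <- c(chord[2] * el$axis_direction[3] - chord[3] * el$axis_direction[2],
              chord[3] * el$axis_direction[1] - chord[1] * el$axis_direction[3],
              chord[1] * el$axis_direction[2] - chord[2] * el$axis_direction[1])
    if (sqrt(sum(n_pl^2)) < 1e-9) {
      # chord parallel to the electrode axis: any perpendicular plane works
      ref <- if (abs(chord[1]) < 0.9 * sqrt(sum(chord^2))) c(1, 0, 0) else c(0, 1, 0)
      n_pl <- c(chord[2] * ref[3] - chord[3] * ref[2],
                chord[3] * ref[1] - chord[1] * ref[3],
                chord[1] * ref[2] - chord[2] * ref[1])
    }
    n_pl <- n_pl / sqrt(sum(n_pl^2))
    m_hat <- c(n_pl[2] * chord[3] - n_pl[3] * chord[2],
               n_pl[3] * chord[1] - n_pl[1] * chord[3],
               n_pl[1] * chord[2] - n_pl[2] * chord[1])
    m_hat <- m_hat / sqrt(sum(m_hat^2))
    M <- (B + Tg) / 2
    rel <- M - el$tip_position
    closest <- el$tip_position + sum(rel * el$axis_direction) * el$axis_direction
    away <- M - closest
    if (sum(away^2) > 1e-12 && sum(m_hat * away) < 0) m_hat <- -m_hat

    arc <- .circular_arc(B, Tg, m_hat, arc_bulge)
    if (all(axis_distance(el, arc) >= el$shaft_radius_mm)) {
      return(structure(list(main = main, collateral = streamline(arc),
                            branch_node_index = branch_idx),
                       class = "axon_trajectory"))
    }
  }
  stop(sprintf("no electrode-free collateral found in %d attempts",
               max_attempts))
}

#' A trajectory without a collateral (internal capsule fiber of passage)
#'
#' @param main A [streamline()].
#' @return An `axon_trajectory` with no collateral.
#' @export
axon_trajectory <- function(main) {
  stopifnot(inherits(main, "streamline"))
  structure(list(main = main, collateral = NULL, branch_node_index = NA_integer_),
            class = "axon_trajectory")
}

#' @export
print.axon_trajectory <- function(x, ...) {
  cat(sprintf("Axon trajectory: main %.1f mm%s\n", arc_length(x$main),
              if (is.null(x$collateral)) ", no collateral" else
                sprintf(", collateral %.1f mm at node %d",
                        arc_length(x$collateral), x$branch_node_index)))
  invisible(x)
}

# walk the 11-compartment repeat along one curve; returns data.frame
# first_node_um: length of the first node (0.5 for collaterals)
.walk_compartments <- function(curve, geom, first_node_um = NULL) {
  L_um <- arc_length(curve) * 1000
  lens <- c(node = geom$node_length_um, mysa = geom$mysa_length_um,
            flut = geom$flut_length_um, stin = geom$stin_length_um)
  diams <- c(node = geom$node_diameter_um, mysa = geom$mysa_diameter_um,
             flut = geom$flut_diameter_um, stin = geom$stin_diameter_um)
  pattern <- c("node", "mysa", "flut", rep("stin", 6), "flut", "mysa")
  type <- character(0); len <- numeric(0)
  pos <- 0; k <- 0
  repeat {
    blk_type <- pattern
    blk_len <- lens[pattern]
    if (k == 0 && !is.null(first_node_um)) blk_len[1] <- first_node_um
    if (pos + blk_len[1] > L_um) break
    # only keep the internode if the *next* node still fits entirely
    if (pos + sum(blk_len) + geom$node_length_um > L_um) {
      type <- c(type, blk_type[1]); len <- c(len, blk_len[1])
      break
    }
    type <- c(type, blk_type); len <- c(len, blk_len)
    pos <- pos + sum(blk_len)
    k <- k + 1
  }
  if (!length(type) || sum(type == "node") < 2)
    stop("trajectory shorter than one internode")
  ends <- cumsum(len)
  mids <- (ends - len / 2) / 1000
  pts <- .interp_at_arc(curve, mids)
  data.frame(type = type, x = pts[, 1], y = pts[, 2], z = pts[, 3],
             length_um = len, diameter_um = unname(diams[type]),
             arc_mm = mids, stringsAsFactors = FALSE)
}

#' Place double-cable compartments along an axon trajectory
#'
#' Walks the 11-compartment repeat (node, MYSA, FLUT, 6 x STIN, FLUT, MYSA)
#' along the arc length of the main streamline starting at its first point,
#' truncating at the last complete node of Ranvier. A collateral, if
#' present, is walked the same way with its first node shortened to 0.5 um
#' and its distal end truncated to end on a node of Ranvier; that terminal
#' node is passive.
#'
#' @param traj An `axon_trajectory`.
#' @param main_geom [fiber_geometry()] for the corticofugal axon
#'   (typically 5.7 um).
#' @param coll_geom [fiber_geometry()] for the collateral (typically
#'   1.8 um).
#' @return Object of class `axon_morphology`: a compartment table
#'   (`$compartments`: type, midpoint, length, diameter, active flag,
#'   section), `branch_parent` (compartment index of the branch node on the
#'   main path, or NA), and the two geometries.
#' @export
compartmentalize <- function(traj, main_geom = fiber_geometry(5.7),
                             coll_geom = fiber_geometry(1.8)) {
  stopifnot(inherits(traj, "axon_trajectory"))
  main_df <- .walk_compartments(traj$main, main_geom)
  main_df$section <- "main"
  main_df$active <- main_df$type == "node"
  branch_parent <- NA_integer_
  df <- main_df
  if (!is.null(traj$collateral)) {
    node_rows <- which(main_df$type == "node")
    if (traj$branch_node_index > length(node_rows))
      stop("branch node index beyond the truncated main path")
    branch_parent <- node_rows[traj$branch_node_index]
    coll_df <- .walk_compartments(traj$collateral, coll_geom,
                                  first_node_um = 0.5)
    coll_df$section <- "collateral"
    coll_df$active <- coll_df$type == "node"
    coll_df$active[max(which(coll_df$type == "node"))] <- FALSE # passive terminal
    df <- rbind(main_df, coll_df)
  }
  rownames(df) <- NULL
  structure(list(compartments = df, branch_parent = branch_parent,
                 main_geom = main_geom, coll_geom = coll_geom),
            class = "axon_morphology")
}

#' @export
print.axon_morphology <- function(x, ...) {
  n <- nrow(x$compartments)
  cat(sprintf("Axon morphology: %d compartments (%d nodes)%s\n", n,
              sum(x$compartments$type == "node"),
              if (is.na(x$branch_parent)) "" else
                sprintf(", collateral at compartment %d", x$branch_parent)))
  invisible(x)
}

#' Sample disjoint fiber populations from a streamline set
#'
#' Draws `n_total` streamlines uniformly without replacement and splits
#' them into a fibers-of-passage set and a hyperdirect set. Uses the
#' current R random number generator state.
#'
#' @param streamlines List of streamlines (or anything subsettable).
#' @param n_total Total number to sample.
#' @param split Two counts summing to `n_total`:
#'   c(fibers_of_passage, hyperdirect).
#' @return List with `fibers_of_passage` and `hyperdirect` index vectors
#'   into `streamlines`.
#' @export
sample_population <- function(streamlines, n_total = 2000,
                              split = c(1000, 1000)) {
  n_avail <- length(streamlines)
  if (sum(split) != n_total) stop("split must sum to n_total")
  if (n_total > n_avail)
    stop(sprintf("requested %d streamlines but only %d available", n_total,
                 n_avail))
  idx <- sample.int(n_avail, n_total, replace = FALSE)
  list(fibers_of_passage = idx[seq_len(split[1])],
       hyperdirect = idx[split[1] + seq_len(split[2])])
}

#' Write / read streamlines as blank-line-separated delimited text
#'
#' One point per row (x y z in mm); blank lines separate streamlines.
#'
#' @param streamlines List of [streamline()] objects.
#' @param path File path.
#' @return `write_streamlines` returns `path` invisibly; `read_streamlines`
#'   returns a list of streamlines.
#' @export
write_streamlines <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pamsim streamlines v1: x_mm y_mm z_mm, blank line between streamlines", con)
  for (s in streamlines) {
    utils::write.table(format(s$points, digits = 17), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  grp <- cumsum(trimws(lines) == "")
  keep <- trimws(lines) != ""
  lapply(split(lines[keep], grp[keep]), function(chunk) {
    streamline(as.matrix(utils::read.table(text = chunk)))
  })
}
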