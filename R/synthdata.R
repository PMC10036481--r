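#' Configuration for the synthetic flocking simulator
#'
#' Builds the parameter set for an agent-based simulation of motile bacteria
#' swimming around a cable bacterium filament. Cells perform a 2-D
#' run-and-tumble walk (exponential run durations, uniform new headings) whose
#' direction is biased towards the nearest point of the filament with a bias
#' amplitude that decays exponentially with distance. Within `boost_radius` of
#' the filament the swimming speed is multiplied by `speed_boost_factor`,
#' mirroring the elevated swimming speeds observed close to filaments. An
#' optional `cut_time` switches attraction and boost off mid-run, emulating a
#' laser cut that disconnects the filament from oxygen.
#'
#' Per-cell base speeds are log-normal across cells (`base_speed_mean`,
#' `base_speed_sd` on the natural scale). On top of the per-cell base speed,
#' the instantaneous speed fluctuates over time following a log-scale
#' Ornstein-Uhlenbeck process with stationary standard deviation
#' `speed_fluctuation_sd` and correlation time `speed_fluctuation_tau`; real
#' cells modulate their speed on a timescale of seconds, and constant-speed
#' tracks would make per-track speed summaries degenerate.
#'
#' The directional bias is implemented as a rotation of the realized swimming
#' direction towards the filament: the displacement direction is the
#' normalized sum of the heading velocity and a virtual radial drift of
#' magnitude `attraction_strength * exp(-d / attraction_length)`, but the
#' realized displacement magnitude is always `speed * frame_interval` (plus
#' Brownian positional noise). Attraction therefore shapes where cells are,
#' not how fast they move; speed differences enter only through
#' `speed_boost_factor`.
#'
#' @param arena_width,arena_height Arena size in micrometres. Boundaries are
#'   reflecting.
#' @param filament_vertices Two-column matrix of polyline vertices (um)
#'   describing the filament; must lie inside the arena.
#' @param n_cells Number of simulated cells.
#' @param frame_interval Sampling interval in seconds (default 0.088 s,
#'   the high-frame-rate video interval).
#' @param n_frames Number of sampled frames.
#' @param base_speed_mean,base_speed_sd Mean and standard deviation (um/s) of
#'   the log-normal distribution of per-cell base swimming speeds.
#' @param speed_fluctuation_sd Log-scale stationary SD of the within-cell
#'   speed fluctuation process (dimensionless; 0 disables it).
#' @param speed_fluctuation_tau Correlation time (s) of the speed fluctuation.
#' @param attraction_strength Amplitude (um/s) of the virtual radial drift at
#'   the filament surface; 0 gives unbiased motility. The drift amplitude is
#'   the same for every cell, so slower swimmers are deflected more strongly
#'   and settle slightly closer to the filament, a mild speed sorting that a
#'   fixed-gain chemotactic response would also produce.
#' @param attraction_length Exponential decay length (um) of the drift.
#' @param speed_boost_factor Speed multiplier applied within `boost_radius`.
#' @param boost_radius Radius (um) of the speed-boost zone; default 20 um,
#'   the distance used to split cells into near/far speed groups.
#' @param tumble_rate Tumble rate (1/s).
#' @param brownian_diffusivity Translational Brownian diffusivity (um^2/s)
#'   added to every step; gives tracked positions realistic jitter.
#' @param cell_size_range Range (um) of per-cell major-axis lengths (uniform);
#'   minor axis is 0.4 x major, so rendered cells are elongated enough to pass
#'   the circularity gate.
#' @param attraction_standoff Distance (um) below which the attractive bias
#'   fades to zero (linearly between `attraction_standoff` and twice that
#'   value), so cells hold a small clearance and contact with the filament
#'   stays rare and brief.
#' @param bias_cap Upper bound (< 1) on the ratio of drift amplitude to
#'   swimming speed: chemotaxis steers the heading but never overpowers it,
#'   so cells close to the filament keep circulating instead of being pinned
#'   to its surface.
#' @param filament_exclusion Exclusion radius (um) around the filament
#'   centerline; cells may approach but not cross it.
#' @param cut_time Time (s) at which attraction and boost are switched off,
#'   or `NA` for no cut.
#' @param keyframe_spacing Spacing (frames) of filament keyframes in the
#'   ground-truth trace (default 50, matching manual annotation practice).
#' @param undulation_sd Per-keyframe random-walk SD (um) of filament vertex
#'   positions; 0 (default) keeps the filament static.
#' @param burn_in Equilibration time (s) simulated before the first recorded
#'   frame, so that recordings start from a formed flock rather than from the
#'   uniform initial condition.
#' @param init_near_filament If `TRUE`, cells start clustered around the
#'   filament (exponential radial offsets) instead of uniformly in the arena;
#'   used for cut experiments, where the flock has assembled long before the
#'   recording and the arena is much larger than the flock.
#' @param boundary `"reflect"` (closed chamber) or `"open"`: with an open
#'   boundary the arena is a field of view inside a much larger medium, and a
#'   cell that swims out is lost (its track ends), as in recorded videos.
#'   Lost cells do not return; the dilute far field makes returns rare in
#'   reality.
#' @param seed Integer seed controlling all randomness of the run.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_flock()], [simulate_cut()], [cut_config()]
#' @export
sim_config <- function(arena_width = 150,
                       arena_height = 150,
                       filament_vertices = rbind(c(10, 75), c(140, 75)),
                       n_cells = 80,
                       frame_interval = 0.088,
                       n_frames = 300,
                       base_speed_mean = 10,
                       base_speed_sd = 2.5,
                       speed_fluctuation_sd = 0.25,
                       speed_fluctuation_tau = 2,
                       attraction_strength = 35,
                       attraction_length = 20,
                       speed_boost_factor = 1.4,
                       boost_radius = 20,
                       tumble_rate = 0.3,
                       brownian_diffusivity = 0.3,
                       bias_cap = 0.8,
                       attraction_standoff = 2,
                       cell_size_range = c(1, 2),
                       filament_exclusion = 0.6,
                       cut_time = NA_real_,
                       keyframe_spacing = 50,
                       undulation_sd = 0,
                       burn_in = 30,
                       init_near_filament = FALSE,
                       boundary = c("reflect", "open"),
                       seed = 1L) {
  cfg <- list(
    arena_width = arena_width, arena_height = arena_height,
    filament_vertices = as.matrix(filament_vertices),
    n_cells = as.integer(n_cells), frame_interval = frame_interval,
    n_frames = as.integer(n_frames),
    base_speed_mean = base_speed_mean, base_speed_sd = base_speed_sd,
    speed_fluctuation_sd = speed_fluctuation_sd,
    speed_fluctuation_tau = speed_fluctuation_tau,
    attraction_strength = attraction_strength,
    attraction_length = attraction_length,
    speed_boost_factor = speed_boost_factor, boost_radius = boost_radius,
    tumble_rate = tumble_rate, brownian_diffusivity = brownian_diffusivity,
    bias_cap = bias_cap, attraction_standoff = attraction_standoff,
    cell_size_range = cell_size_range,
    filament_exclusion = filament_exclusion,
    cut_time = cut_time, keyframe_spacing = as.integer(keyframe_spacing),
    undulation_sd = undulation_sd, burn_in = burn_in,
    init_near_filament = isTRUE(init_near_filament),
    boundary = match.arg(boundary, c("reflect", "open")),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (nm in c("arena_width", "arena_height", "n_cells", "frame_interval",
               "n_frames", "base_speed_mean", "base_speed_sd",
               "speed_fluctuation_tau", "attraction_length",
               "speed_boost_factor", "boost_radius", "tumble_rate",
               "keyframe_spacing", "filament_exclusion", "attraction_standoff"))
    .assert_positive(cfg[[nm]], nm)
  if (!is.numeric(cfg$bias_cap) || cfg$bias_cap <= 0 || cfg$bias_cap >= 1)
    stop("'bias_cap' must lie in (0, 1)", call. = FALSE)
  for (nm in c("attraction_strength", "speed_fluctuation_sd",
               "brownian_diffusivity", "undulation_sd", "burn_in"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  fv <- cfg$filament_vertices
  if (!is.matrix(fv) || ncol(fv) != 2 || nrow(fv) < 2)
    stop("'filament_vertices' must be a matrix with >= 2 rows of (x, y)",
         call. = FALSE)
  if (any(fv[, 1] < 0 | fv[, 1] > cfg$arena_width |
          fv[, 2] < 0 | fv[, 2] > cfg$arena_height))
    stop("filament vertices must lie inside the arena", call. = FALSE)
  if (length(cfg$cell_size_range) != 2 || any(cfg$cell_size_range <= 0) ||
      diff(cfg$cell_size_range) < 0)
    stop("'cell_size_range' must be an increasing positive pair", call. = FALSE)
  if (!is.na(cfg$cut_time)) {
    total <- (cfg$n_frames - 1) * cfg$frame_interval
    if (cfg$cut_time <= 0 || cfg$cut_time >= total)
      stop("'cut_time' must fall within the simulated interval", call. = FALSE)
  }
  invisible(cfg)
}

#' Default configuration for the laser-cut experiment
#'
#' A [sim_config()] preset calibrated for dispersal-time measurements: a
#' sparser cell population in a larger arena so that, once attraction is
#' switched off, the 15-um zone around the filament genuinely empties instead
#' of being constantly re-visited by the bulk population.
#'
#' @param cut_time Cut time in seconds (default 15 s, after the flock has
#'   formed from the uniform initial condition).
#' @param seed Integer seed.
#' @param ... Further arguments overriding [sim_config()] defaults.
#' @return A `sim_config` with `cut_time` set.
#' @export
cut_config <- function(cut_time = 15, seed = 1L, ...) {
  defaults <- list(
    filament_vertices = rbind(c(35, 75), c(115, 75)),
    n_cells = 32, n_frames = 550, cut_time = cut_time,
    init_near_filament = TRUE, burn_in = 5, boundary = "open", seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# nearest-point query against a polyline, vectorized over query points:
# returns distance, unit vector towards the nearest polyline point, and the
# nearest point itself
.polyline_nearest <- function(px, py, poly) {
  n <- length(px)
  best_d2 <- rep(Inf, n)
  best_x <- best_y <- numeric(n)
  for (s in seq_len(nrow(poly) - 1)) {
    ax <- poly[s, 1]; ay <- poly[s, 2]
    bx <- poly[s + 1, 1]; by <- poly[s + 1, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      qx <- rep(ax, n); qy <- rep(ay, n)
    } else {
      t <- ((px - ax) * dx + (py - ay) * dy) / L2
      t <- pmin(1, pmax(0, t))
      qx <- ax + t * dx; qy <- ay + t * dy
    }
    d2 <- (px - qx)^2 + (py - qy)^2
    sel <- d2 < best_d2
    best_d2[sel] <- d2[sel]
    best_x[sel] <- qx[sel]
    best_y[sel] <- qy[sel]
  }
  d <- sqrt(best_d2)
  list(distance = d, nx = best_x, ny = best_y)
}

# core propagation loop shared by simulate_flock() and simulate_cut()
.sim_run <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_cells; T <- cfg$n_frames; dt <- cfg$frame_interval
  W <- cfg$arena_width; H <- cfg$arena_height

  # per-cell constants
  cv2 <- (cfg$base_speed_sd / cfg$base_speed_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(cfg$base_speed_mean) - sdlog^2 / 2
  s_base <- rlnorm(n, meanlog, sdlog)
  major <- runif(n, cfg$cell_size_range[1], cfg$cell_size_range[2])
  minor <- 0.4 * major

  # filament keyframes (static unless undulation_sd > 0)
  kf_idx <- unique(c(seq(0L, T - 1L, by = cfg$keyframe_spacing), T - 1L))
  base_poly <- cfg$filament_vertices
  keyframes <- vector("list", length(kf_idx))
  keyframes[[1]] <- base_poly
  for (k in seq_along(kf_idx)[-1]) {
    prev <- keyframes[[k - 1]]
    if (cfg$undulation_sd > 0) {
      jitter <- matrix(rnorm(length(prev), 0, cfg$undulation_sd), ncol = 2)
      poly <- prev + jitter
      poly[, 1] <- pmin(W, pmax(0, poly[, 1]))
      poly[, 2] <- pmin(H, pmax(0, poly[, 2]))
      keyframes[[k]] <- poly
    } else keyframes[[k]] <- prev
  }
  trace <- filament_trace(keyframes, kf_idx, spacing = cfg$keyframe_spacing)
  static_filament <- cfg$undulation_sd == 0

  # initial state: uniform positions (outside the exclusion zone) or, for
  # cut experiments, a pre-formed flock around the filament; uniform
  # headings, stationary speed-fluctuation state
  if (cfg$init_near_filament) {
    seg <- sqrt(rowSums(diff(base_poly)^2))
    cum <- c(0, cumsum(seg))
    pos <- runif(n, 0, cum[length(cum)])
    fx <- approx(cum, base_poly[, 1], xout = pos, ties = "ordered")$y
    fy <- approx(cum, base_poly[, 2], xout = pos, ties = "ordered")$y
    r <- cfg$filament_exclusion + stats::rexp(n, rate = 1 / 8)
    phi <- runif(n, 0, 2 * pi)
    x <- pmin(W, pmax(0, fx + r * cos(phi)))
    y <- pmin(H, pmax(0, fy + r * sin(phi)))
  } else {
    x <- runif(n, 0, W); y <- runif(n, 0, H)
    bad <- .polyline_nearest(x, y, base_poly)$distance < cfg$filament_exclusion
    while (any(bad)) {
      x[bad] <- runif(sum(bad), 0, W); y[bad] <- runif(sum(bad), 0, H)
      bad[bad] <- .polyline_nearest(x[bad], y[bad], base_poly)$distance <
        cfg$filament_exclusion
    }
  }
  theta <- runif(n, 0, 2 * pi)
  z <- rnorm(n, 0, cfg$speed_fluctuation_sd)
  rho <- exp(-dt / cfg$speed_fluctuation_tau)
  zsd <- cfg$speed_fluctuation_sd * sqrt(1 - rho^2)
  p_tumble <- 1 - exp(-cfg$tumble_rate * dt)
  bsd <- sqrt(2 * cfg$brownian_diffusivity * dt)

  # one propagation step; mutates x, y, theta, z in the enclosing frame
  advance <- function(poly_t, cut_active) {
    # run-and-tumble heading update
    tumble <- runif(n) < p_tumble
    if (any(tumble)) theta[tumble] <<- runif(sum(tumble), 0, 2 * pi)
    # within-cell speed fluctuation (log-scale OU, mean-one on natural scale)
    z <<- rho * z + rnorm(n, 0, zsd)
    s <- s_base * exp(z - cfg$speed_fluctuation_sd^2 / 2)

    nf <- .polyline_nearest(x, y, poly_t)
    d <- nf$distance
    A <- if (cut_active) 0 else cfg$attraction_strength
    boost <- if (cut_active) 1 else cfg$speed_boost_factor
    s_eff <- s * ifelse(d <= cfg$boost_radius, boost, 1)

    # direction = heading biased towards the filament; magnitude preserved.
    # The drift amplitude is a fixed velocity, so slower cells are deflected
    # more strongly and sit slightly closer to the filament (speed sorting);
    # see the methods vignette for the consequences for null calibration.
    # The bias-to-speed ratio is capped below 1: chemotaxis steers the
    # heading but cannot push a cell against its own swimming direction,
    # and an uncapped ratio would pin cells to the filament surface.
    a <- A * exp(-d / cfg$attraction_length)
    ratio <- pmin(a / s_eff, cfg$bias_cap)
    # the bias fades out below the standoff distance: flocking cells hold a
    # small clearance from the filament and physical contact is rare and
    # brief, so the flock forms a circulating shell rather than a surface film
    ratio <- ratio * pmin(1, pmax(0, (d - cfg$attraction_standoff) /
                                       cfg$attraction_standoff))
    tox <- ifelse(d > 0, (nf$nx - x) / d, 0)
    toy <- ifelse(d > 0, (nf$ny - y) / d, 0)
    wx <- cos(theta) + ratio * tox
    wy <- sin(theta) + ratio * toy
    wn <- sqrt(wx^2 + wy^2)
    ok <- wn > 0
    ux <- ifelse(ok, wx / wn, cos(theta))
    uy <- ifelse(ok, wy / wn, sin(theta))

    xn <- x + s_eff * dt * ux + rnorm(n, 0, bsd)
    yn <- y + s_eff * dt * uy + rnorm(n, 0, bsd)

    if (cfg$boundary == "reflect") {
      # reflecting arena boundaries (steps are small; one reflection suffices)
      refl_x <- xn < 0 | xn > W
      xn <- ifelse(xn < 0, -xn, ifelse(xn > W, 2 * W - xn, xn))
      refl_y <- yn < 0 | yn > H
      yn <- ifelse(yn < 0, -yn, ifelse(yn > H, 2 * H - yn, yn))
      theta[refl_x] <<- pi - theta[refl_x]
      theta[refl_y] <<- -theta[refl_y]
    }

    # cells may approach but not cross the filament: steps ending inside the
    # exclusion radius are mirrored at it, and the heading is reflected so
    # that a cell pointing at the filament does not get re-mirrored every
    # step and pile up at the surface
    nf2 <- .polyline_nearest(xn, yn, poly_t)
    inside <- nf2$distance < cfg$filament_exclusion & nf2$distance > 1e-9
    if (any(inside)) {
      dd <- nf2$distance[inside]
      awayx <- (xn[inside] - nf2$nx[inside]) / dd
      awayy <- (yn[inside] - nf2$ny[inside]) / dd
      push <- 2 * cfg$filament_exclusion - dd
      xn[inside] <- nf2$nx[inside] + awayx * push
      yn[inside] <- nf2$ny[inside] + awayy * push
      hx <- cos(theta[inside]); hy <- sin(theta[inside])
      dot <- hx * awayx + hy * awayy
      ref <- dot < 0
      if (any(ref)) {
        hx[ref] <- hx[ref] - 2 * dot[ref] * awayx[ref]
        hy[ref] <- hy[ref] - 2 * dot[ref] * awayy[ref]
        th <- theta[inside]
        th[ref] <- atan2(hy[ref], hx[ref])
        theta[inside] <<- th
      }
    }
    x <<- xn; y <<- yn
    invisible(NULL)
  }

  alive <- rep(TRUE, n)
  open_bd <- cfg$boundary == "open"
  check_escape <- function() {
    if (open_bd)
      alive <<- alive & x >= 0 & x <= W & y >= 0 & y <= H
  }

  # equilibration before the first recorded frame (pre-cut dynamics)
  burn_steps <- round(cfg$burn_in / dt)
  for (b in seq_len(burn_steps)) { advance(base_poly, FALSE); check_escape() }

  X <- matrix(NA_real_, T, n); Y <- matrix(NA_real_, T, n)
  X[1, ] <- ifelse(alive, x, NA_real_); Y[1, ] <- ifelse(alive, y, NA_real_)
  poly_t <- base_poly
  for (t in seq_len(T - 1)) {
    if (!static_filament) poly_t <- interpolate_filament(trace, t - 1L)
    cut_active <- !is.na(cfg$cut_time) && ((t - 1) * dt >= cfg$cut_time)
    advance(poly_t, cut_active)
    check_escape()
    X[t + 1, ] <- ifelse(alive, x, NA_real_)
    Y[t + 1, ] <- ifelse(alive, y, NA_real_)
  }

  tracks <- data.frame(
    track_id = rep(seq_len(n), each = T),
    frame = rep(0:(T - 1), times = n),
    x = as.vector(X), y = as.vector(Y),
    major_um = rep(major, each = T),
    minor_um = rep(minor, each = T)
  )
  tracks <- tracks[!is.na(tracks$x), , drop = FALSE]
  # a track needs at least two points
  cnt <- table(tracks$track_id)
  tracks <- tracks[tracks$track_id %in% names(cnt)[cnt >= 2], , drop = FALSE]
  tracks <- new_track_set(tracks, pixel_size = 0.25,
                          frame_interval = dt)
  attr(tracks, "ground_truth") <- list(
    base_speed = s_base, config = cfg
  )
  list(tracks = tracks, trace = trace)
}

#' Simulate a bacterial flock around a filament
#'
#' Runs the run-and-tumble simulation described in [sim_config()] and returns
#' ground-truth tracks (one per cell, sampled every frame) together with the
#' filament trace. Identical configurations (including `seed`) give
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `tracks` (a `track_set`) and `trace`
#'   (a `filament_trace`).
#' @examples
#' run <- simulate_flock(sim_config(n_cells = 10, n_frames = 50))
#' head(run$tracks)
#' @export
simulate_flock <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  .sim_run(config)[c("tracks", "trace")]
}

#' Simulate a laser-cut experiment
#'
#' Identical to [simulate_flock()] until `config$cut_time`; from the cut
#' onwards the attraction and the speed boost are switched off (the mediator
#' is gone) and cells revert to unbiased run-and-tumble motility.
#'
#' @param config A [sim_config()] with `cut_time` set; see [cut_config()].
#' @return A list with elements `tracks`, `trace` and `cut_time` (s).
#' @export
simulate_cut <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.na(config$cut_time))
    stop("'config$cut_time' must be set for simulate_cut()", call. = FALSE)
  validate_sim_config(config)
  out <- .sim_run(config)
  list(tracks = out$tracks, trace = out$trace, cut_time = config$cut_time)
}

#' Rendering parameters for synthetic image stacks
#'
#' Controls how simulated tracks are rasterized into phase-contrast-like
#' frames: a uniform background, a dark filament line, one anisotropic
#' Gaussian spot per cell (elongated along its direction of motion) and
#' additive Gaussian noise.
#'
#' @param pixel_size Pixel size in um/px.
#' @param cell_intensity Peak intensity (a.u.) added per cell.
#' @param cell_axes Fallback (major, minor) axes in um used when tracks carry
#'   no per-cell size columns.
#' @param background_level Constant background intensity (a.u.).
#' @param noise_sd Gaussian noise SD (a.u.) per pixel and frame.
#' @param filament_dark_level Intensity (a.u.) subtracted along the filament
#'   line (its "shadow").
#' @param motion_blur Exposure smear (um) added to the rendered spot along
#'   the direction of motion (roughly swimming speed times exposure time);
#'   keeps rendered swimming cells clearly elongated, as they appear in
#'   phase-contrast videos.
#' @param filament_sigma Gaussian cross-section SD (um) of the filament line.
#' @return An object of class `render_params`.
#' @export
render_params <- function(pixel_size = 1/6,
                          cell_intensity = 80,
                          cell_axes = c(1.6, 0.64),
                          background_level = 100,
                          noise_sd = 3,
                          filament_dark_level = 40,
                          filament_sigma = 0.5,
                          motion_blur = 0.9) {
  .assert_positive(pixel_size, "pixel_size")
  if (length(cell_axes) != 2 || any(cell_axes <= 0) ||
      cell_axes[2] > cell_axes[1])
    stop("'cell_axes' must be (major, minor) with minor <= major",
         call. = FALSE)
  p <- list(pixel_size = pixel_size, cell_intensity = cell_intensity,
            cell_axes = cell_axes, background_level = background_level,
            noise_sd = noise_sd, filament_dark_level = filament_dark_level,
            filament_sigma = filament_sigma, motion_blur = motion_blur)
  class(p) <- "render_params"
  p
}

# Rasterize one polyline as a dark Gaussian-profile line into `img` (H x W,
# rows = y). Returns the modified matrix.
.render_filament <- function(img, poly, params) {
  ps <- params$pixel_size
  H <- nrow(img); W <- ncol(img)
  sig_px <- params$filament_sigma / ps
  reach <- ceiling(3 * sig_px)
  # sample points along the polyline every half pixel
  seglen <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                          poly[-nrow(poly), , drop = FALSE])^2))
  pts <- list()
  for (s in seq_len(nrow(poly) - 1)) {
    k <- max(2, ceiling(seglen[s] / (ps / 2)))
    t <- seq(0, 1, length.out = k)
    pts[[s]] <- cbind(poly[s, 1] + t * (poly[s + 1, 1] - poly[s, 1]),
                      poly[s, 2] + t * (poly[s + 1, 2] - poly[s, 2]))
  }
  pts <- do.call(rbind, pts)
  # accumulate max dip per pixel over a thin band around the line
  dip <- matrix(0, H, W)
  cx <- pts[, 1] / ps + 0.5
  cy <- pts[, 2] / ps + 0.5
  for (i in seq_len(nrow(pts))) {
    x_lo <- max(1, floor(cx[i] - reach)); x_hi <- min(W, ceiling(cx[i] + reach))
    y_lo <- max(1, floor(cy[i] - reach)); y_hi <- min(H, ceiling(cy[i] + reach))
    if (x_lo > x_hi || y_lo > y_hi) next
    jx <- x_lo:x_hi
    jy <- y_lo:y_hi
    gx <- exp(-0.5 * ((jx - cx[i]) / sig_px)^2)
    gy <- exp(-0.5 * ((jy - cy[i]) / sig_px)^2)
    patch <- outer(gy, gx)
    cur <- dip[jy, jx, drop = FALSE]
    dip[jy, jx] <- pmax(cur, patch)
  }
  img - params$filament_dark_level * dip
}

#' Render simulated tracks into a synthetic image stack
#'
#' Produces a multi-frame grayscale stack: constant background, a dark
#' filament polyline, one anisotropic Gaussian ellipse per cell per frame
#' (oriented along the cell's direction of motion) and per-pixel Gaussian
#' noise. Deterministic given `seed`.
#'
#' @param tracks A `track_set` (e.g. from [simulate_flock()]).
#' @param trace A `filament_trace` sharing the time base with `tracks`.
#' @param params [render_params()].
#' @param arena Optional `c(width, height)` in um; defaults to the extent
#'   implied by the simulation config attached to `tracks`, or to the data
#'   range.
#' @param seed Integer seed for the rendering noise.
#' @return An `image_stack` (H x W x T array with `pixel_size` and
#'   `frame_interval` attributes).
#' @export
render_stack <- function(tracks, trace, params = render_params(),
                         arena = NULL, seed = 1L) {
  stopifnot(inherits(params, "render_params"))
  ps <- params$pixel_size
  fi <- attr(tracks, "frame_interval")
  gt <- attr(tracks, "ground_truth")
  if (is.null(arena)) {
    arena <- if (!is.null(gt)) c(gt$config$arena_width, gt$config$arena_height)
             else c(max(tracks$x) * 1.05, max(tracks$y) * 1.05)
  }
  W <- ceiling(arena[1] / ps); H <- ceiling(arena[2] / ps)
  frames <- sort(unique(tracks$frame))
  T <- length(frames)
  minor_px <- (if ("minor_um" %in% names(tracks)) min(tracks$minor_um)
               else params$cell_axes[2]) / ps
  if (minor_px < 2)
    warning("cell minor axis spans < 2 px at this pixel size; ",
            "detection is likely to fail")

  set.seed(seed)
  # per-point orientation from displacement to the adjacent point
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  ids <- tracks$track_id
  dx <- ave(tracks$x, ids, FUN = function(v)
    if (length(v) > 1) c(diff(v), v[length(v)] - v[length(v) - 1]) else 0)
  dy <- ave(tracks$y, ids, FUN = function(v)
    if (length(v) > 1) c(diff(v), v[length(v)] - v[length(v) - 1]) else 0)
  ang <- atan2(dy, dx)

  has_size <- all(c("major_um", "minor_um") %in% names(tracks))
  stack <- array(0, dim = c(H, W, T))
  static <- length(trace$keyframes) == 1 ||
    all(vapply(trace$keyframes, identical, logical(1), trace$keyframes[[1]]))
  base_img <- matrix(params$background_level, H, W)
  if (static)
    base_img <- .render_filament(base_img, trace$keyframes[[1]], params)

  for (ti in seq_len(T)) {
    f <- frames[ti]
    img <- if (static) base_img else
      .render_filament(matrix(params$background_level, H, W),
                       interpolate_filament(trace, f), params)
    sel <- which(tracks$frame == f)
    for (i in sel) {
      maj <- if (has_size) tracks$major_um[i] else params$cell_axes[1]
      mnr <- if (has_size) tracks$minor_um[i] else params$cell_axes[2]
      # the finite exposure smears a swimming cell along its direction of
      # motion, so the rendered spot is more elongated than the cell body
      sig_u <- (maj / 3 + params$motion_blur / 2) / ps   # along motion
      sig_v <- mnr / 3 / ps
      cx <- tracks$x[i] / ps + 0.5
      cy <- tracks$y[i] / ps + 0.5
      reach <- ceiling(3 * sig_u)
      x_lo <- max(1, floor(cx - reach)); x_hi <- min(W, ceiling(cx + reach))
      y_lo <- max(1, floor(cy - reach)); y_hi <- min(H, ceiling(cy + reach))
      if (x_lo > x_hi || y_lo > y_hi) next
      jx <- x_lo:x_hi
      jy <- y_lo:y_hi
      rx <- outer(rep(1, length(jy)), jx - cx)
      ry <- outer(jy - cy, rep(1, length(jx)))
      ca <- cos(ang[i]); sa <- sin(ang[i])
      u <- rx * ca + ry * sa
      v <- -rx * sa + ry * ca
      img[jy, jx] <- img[jy, jx] +
        params$cell_intensity * exp(-0.5 * ((u / sig_u)^2 + (v / sig_v)^2))
    }
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, params$noise_sd), H, W)
    stack[, , ti] <- img
  }
  image_stack(stack, pixel_size = ps, frame_interval = fi %||% 0.088)
}

#' Synthesize a paired near/far Raman spectrum
#'
#' Generates two single-cell Raman spectra on a fixed 600-3100 cm^-1 grid:
#' a gently sloping linear baseline, a cytochrome band at 750 cm^-1 whose
#' amplitude is proportional to the reduced-cytochrome fraction, a C-H
#' stretching envelope at 2800-3000 cm^-1 shared between the two spectra of a
#' pair (so pair QC passes by construction), and additive Gaussian noise.
#'
#' @param redox_near,redox_far Reduced-cytochrome fraction in `[0, 1]`
#'   (1 = fully reduced) for the near- and far-filament measurement.
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param seed Optional integer seed.
#' @param cell_id Cell identifier shared by the pair.
#' @param perturb_ch If `TRUE`, the far spectrum gets an independent C-H
#'   envelope, which makes the pair fail QC (for testing the QC rule).
#' @return A `spectrum_pair` (list with `near`, `far`, `cell_id`).
#' @export
synth_raman_pair <- function(redox_near, redox_far, noise_sd = 5,
                             seed = NULL, cell_id = "cell_1",
                             perturb_ch = FALSE) {
  for (r in c(redox_near, redox_far))
    if (!is.numeric(r) || is.na(r) || r < 0 || r > 1)
      stop("redox fractions must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  wn <- seq(600, 3100, by = 1)
  baseline <- 80 - 0.01 * (wn - 600)
  band <- function(center, amp, width) amp * exp(-0.5 * ((wn - center) / width)^2)
  cyt <- function(redox)
    band(750, 100 * redox, 6) + band(1128, 60 * redox, 8) +
      band(1585, 80 * redox, 10)
  ch_envelope <- function(shift = 0) {
    a <- runif(3, 0.8, 1.2)
    band(2850 + shift, 55 * a[1], 14) + band(2885 + shift, 40 * a[2], 12) +
      band(2935 + shift, 70 * a[3], 16)
  }
  ch <- ch_envelope()
  # a perturbed far spectrum has its C-H bands shifted, the "major shift"
  # the QC rule is designed to reject
  ch_far <- if (perturb_ch) ch_envelope(shift = sample(c(-1, 1), 1) * 25)
            else ch
  make <- function(redox, label, ch_part) {
    inten <- baseline + cyt(redox) + ch_part
    if (noise_sd > 0) inten <- inten + rnorm(length(wn), 0, noise_sd)
    raman_spectrum(wn, inten, label = label, cell_id = cell_id)
  }
  spectrum_pair(make(redox_near, "near", ch),
                make(redox_far, "far", ch_far))
}
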