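#' Phantom configuration
#'
#' Builds the configuration for the synthetic cortical-bone generator. The
#' phantom is an annular cortical cross-section (axis z) with a centred
#' cylindrical medullary cavity, near-axial vascular canals, ellipsoidal
#' lacunae with a right-skewed (truncated lognormal) volume distribution, a
#' perilacunar hypermineralized shell, an optional hypomineralized annulus
#' farther out restricted to largest-quartile lacunae, and additive white
#' Gaussian noise.
#'
#' @param shape_voxels Grid size `c(nz, ny, nx)`.
#' @param spacing_um Isotropic voxel spacing, um.
#' @param cortex List: `outer_radius_um`, `inner_radius_um` (medullary
#'   cavity radius).
#' @param canals List: `count`, `radius_um`, `orientation_jitter_deg`
#'   (maximum tilt of the canal axis away from z).
#' @param lacunae List: `target_count`; `volume_median_um3` and `sigma_log`
#'   of the lognormal volume law; `truncation` bounds in um^3;
#'   `axis_ratio_range` with ranges for the middle/shortest semi-axis
#'   relative to the longest; `volume_scale` (multiplies every lacunar
#'   volume; applied as the cube root on the linear semi-axes);
#'   `endosteal_volume_scale` (extra factor applied only to lacunae whose
#'   truth-side nearest surface is the endosteum).
#' @param mineral List: `baseline` and `background` attenuation levels;
#'   `hyper_shell` (`inner_um`, `outer_um`, `amplitude_frac`) applied around
#'   every lacuna; `hypo_annulus` (`inner_um`, `outer_um`, `amplitude_frac`,
#'   `enabled`) applied only around lacunae in the top volume quartile of
#'   the generated sample.
#' @param noise_sigma_frac Noise standard deviation as a fraction of the
#'   bone-background contrast.
#' @param seed Integer seed; a fixed seed reproduces the phantom
#'   bit-for-bit.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape_voxels = c(128L, 192L, 192L),
                           spacing_um = 1.3,
                           cortex = list(outer_radius_um = 115,
                                         inner_radius_um = 60),
                           canals = list(count = 8L, radius_um = 4,
                                         orientation_jitter_deg = 5),
                           lacunae = list(target_count = 300L,
                                          volume_median_um3 = 160,
                                          sigma_log = 0.45,
                                          truncation = c(65, 700),
                                          axis_ratio_range = list(
                                            mid = c(0.4, 0.7),
                                            short = c(0.3, 0.5)),
                                          volume_scale = 1,
                                          endosteal_volume_scale = 1),
                           mineral = list(baseline = 1.0, background = 0.1,
                                          hyper_shell = list(
                                            inner_um = 2.6, outer_um = 10.4,
                                            amplitude_frac = 0.10),
                                          hypo_annulus = list(
                                            inner_um = 14.0, outer_um = 20.0,
                                            amplitude_frac = -0.05,
                                            enabled = FALSE)),
                           noise_sigma_frac = 0.05,
                           seed = 1L) {
  cfg <- list(shape_voxels = as.integer(shape_voxels), spacing_um = spacing_um,
              cortex = cortex, canals = canals, lacunae = lacunae,
              mineral = mineral, noise_sigma_frac = noise_sigma_frac,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$shape_voxels) == 3L, all(cfg$shape_voxels > 0),
            cfg$spacing_um > 0)
  cx <- cfg$cortex
  if (!(cx$inner_radius_um < cx$outer_radius_um))
    stop("phantom_config: inner_radius_um must be < outer_radius_um")
  tr <- cfg$lacunae$truncation
  if (!(length(tr) == 2L && all(tr > 0) && tr[1] < tr[2]))
    stop("phantom_config: lacunar volume truncation bounds must be positive and ordered")
  hs <- cfg$mineral$hyper_shell
  ha <- cfg$mineral$hypo_annulus
  if (!(hs$inner_um < hs$outer_um))
    stop("phantom_config: hyper_shell.inner_um must be < outer_um")
  if (!(ha$inner_um >= hs$outer_um))
    stop("phantom_config: hypo_annulus.inner_um must be >= hyper_shell.outer_um")
  if (!(abs(hs$amplitude_frac) < 1 && abs(ha$amplitude_frac) < 1))
    stop("phantom_config: mineral amplitudes must lie in (-1, 1)")
  if (tr[1] / cfg$spacing_um^3 < 8)
    warning("phantom_config: smallest admissible lacuna spans < 8 voxels at this spacing")
  invisible(cfg)
}

#' Cohort presets for the phantom generator
#'
#' Returns a configuration for one of the four study-design cohorts:
#' virgin/lactating crossed with control/osteocyte-targeted MMP13 knockout.
#' Lactating presets enable the hypomineralized annulus and thin the cortex
#' from the endosteal side (endosteal resorption). The lacunar volume effect
#' sizes are deliberately **required arguments** for the lactating-control
#' preset, not hard-coded defaults: they are study-level inputs that the
#' caller sets from reported group effects (the knockout presets fix the
#' lacunar scale at 1 because lactation does not change lacunar volume in
#' that genotype).
#'
#' @param name One of `"virgin_control"`, `"lactating_control"`,
#'   `"virgin_mmp13ko"`, `"lactating_mmp13ko"`.
#' @param lacuna_volume_scale Multiplicative lactation effect on lacunar
#'   volume (e.g. `1.25` for a 25\% increase). Required for
#'   `lactating_control`; fixed at 1 for the knockout presets.
#' @param endosteal_volume_scale Extra multiplicative volume effect applied
#'   only to lacunae whose truth-side nearest surface is the endosteum.
#' @param hypo_inner_um Inner edge (um) of the lactation hypomineralized
#'   annulus; the default places it at 14 um from the lacunar edge.
#' @param thinning_frac Fractional reduction of cortical thickness applied
#'   by lactating presets (endosteal side).
#' @param fit_headroom Optional linear factor used only by lacuna
#'   placement: a candidate position is accepted only if the lacuna would
#'   also fit scaled by this factor. Passing the lactation scale's cube
#'   root to both cohorts of a paired design gives them a common placement
#'   support, so seed-matched phantoms place lacunae identically.
#' @param base Base [phantom_config()] the cohort deltas are applied to.
#' @param seed Seed stored in the returned config.
#' @return A `phantom_config`.
#' @export
cohort_preset <- function(name,
                          lacuna_volume_scale = NULL,
                          endosteal_volume_scale = 1,
                          hypo_inner_um = 14.0,
                          thinning_frac = 0.24,
                          fit_headroom = NULL,
                          base = phantom_config(),
                          seed = base$seed) {
  valid <- c("virgin_control", "lactating_control",
             "virgin_mmp13ko", "lactating_mmp13ko")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop(sprintf("cohort_preset: unknown cohort '%s'; valid presets: %s",
                 as.character(name)[1], paste(valid, collapse = ", ")))
  cfg <- base
  cfg$seed <- as.integer(seed)
  if (!is.null(fit_headroom)) cfg$lacunae$fit_headroom <- fit_headroom
  lactating <- grepl("^lactating", name)
  knockout <- grepl("mmp13ko$", name)
  if (!lactating) {
    cfg$lacunae$volume_scale <- 1
    cfg$lacunae$endosteal_volume_scale <- 1
    cfg$mineral$hypo_annulus$enabled <- FALSE
  } else {
    if (knockout) {
      # no lacunar-volume lactation effect in the knockout
      cfg$lacunae$volume_scale <- 1
      cfg$lacunae$endosteal_volume_scale <- endosteal_volume_scale
    } else {
      if (is.null(lacuna_volume_scale))
        stop(paste("cohort_preset: lactating_control requires `lacuna_volume_scale`,",
                   "the control-group lactation effect on lacunar volume"))
      cfg$lacunae$volume_scale <- lacuna_volume_scale
      cfg$lacunae$endosteal_volume_scale <- endosteal_volume_scale
    }
    # endosteal whole-bone resorption: thinner cortex at fixed outer radius;
    # lacuna count scales with the remaining annulus so lacunar density
    # (Lc.Dn) stays constant, as observed across lactation
    th <- cfg$cortex$outer_radius_um - cfg$cortex$inner_radius_um
    r_out <- cfg$cortex$outer_radius_um
    old_area <- r_out^2 - cfg$cortex$inner_radius_um^2
    cfg$cortex$inner_radius_um <- r_out - (1 - thinning_frac) * th
    new_area <- r_out^2 - cfg$cortex$inner_radius_um^2
    cfg$lacunae$target_count <-
      as.integer(round(cfg$lacunae$target_count * new_area / old_area))
    cfg$mineral$hypo_annulus$enabled <- TRUE
    cfg$mineral$hypo_annulus$inner_um <- hypo_inner_um
  }
  cfg$cohort <- name
  validate_phantom_config(cfg)
  cfg
}

# quaternion -> rotation matrix (columns = ellipsoid principal axes)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# 2-D 8-neighbourhood dilation of a logical matrix (borders: background)
dilate8_2d <- function(m) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    src_r <- max(1, 1 - di):min(nr, nr - di)
    src_c <- max(1, 1 - dj):min(nc, nc - dj)
    out[src_r + di, src_c + dj] <- out[src_r + di, src_c + dj] | m[src_r, src_c]
  }
  out
}

#' Generate a synthetic cortical-bone phantom with ground truth
#'
#' Renders the attenuation volume described by a [phantom_config()] and
#' returns it together with the full ground truth: label maps for lacunae
#' and canals, the solid cortical mask, endosteal/periosteal surface masks,
#' and a per-lacuna parameter table. Lacunar boundaries are rendered with
#' 3x3x3 sub-voxel sampling, so boundary voxels carry partial-volume
#' attenuation; the mineral model multiplies the bone baseline by a pure
#' function of the (voxelized) distance to the nearest lacunar edge.
#'
#' @param config A [phantom_config()].
#' @return `list(attenuation = volume3d, truth = list(...))` where `truth`
#'   holds `lacuna_labels`, `canal_labels`, `bone_mask`, `endosteum_mask`,
#'   `periosteum_mask` (all [volume3d()]), `lacuna_params` (data frame),
#'   `canal_params`, `q4_ids` (truth top-quartile lacuna ids) and a config
#'   echo.
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  sp <- config$spacing_um
  dims <- config$shape_voxels            # (nz, ny, nx)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  cx <- (nx - 1) / 2 * sp; cy <- (ny - 1) / 2 * sp
  x_um <- (seq_len(nx) - 1) * sp
  y_um <- (seq_len(ny) - 1) * sp
  z_um <- (seq_len(nz) - 1) * sp
  inner <- config$cortex$inner_radius_um
  outer <- config$cortex$outer_radius_um

  r2d <- sqrt(outer(((y_um - cy))^2, ((x_um - cx))^2, "+"))  # ny x nx
  bone2d <- r2d <= outer & r2d > inner
  med2d <- r2d <= inner
  ext2d <- r2d > outer
  if (!any(bone2d))
    stop("generate_phantom: geometry leaves no cortical annulus")

  rep_z <- function(m) aperm(array(m, c(ny, nx, nz)), c(3, 1, 2))
  bone_arr <- rep_z(bone2d)
  nvox <- nz * ny * nx

  # ---- canals -------------------------------------------------------------
  canal_labels <- array(0L, dims)
  frac_canal <- array(0, dims)
  occupancy <- array(FALSE, dims)   # voids placed so far (canals + lacunae)
  canal_params <- data.frame()
  ncan <- config$canals$count
  if (ncan > 0) {
    cr <- config$canals$radius_um
    jit <- config$canals$orientation_jitter_deg * pi / 180
    half_len <- (nz - 1) / 2 * sp
    drift <- tan(jit) * half_len
    margin <- cr + drift + 2 * sp
    if (inner + margin >= outer - margin)
      stop("generate_phantom: cortex too thin for canal radius/orientation jitter (canal placement failure)")
    base_pts <- matrix(NA_real_, ncan, 2)
    dirs <- matrix(NA_real_, ncan, 3)
    for (c_i in seq_len(ncan)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        rc <- sqrt(stats::runif(1, (inner + margin)^2, (outer - margin)^2))
        th <- stats::runif(1, 0, 2 * pi)
        p0 <- c(cx + rc * cos(th), cy + rc * sin(th))
        if (c_i > 1) {
          dmin <- min(sqrt(rowSums((base_pts[seq_len(c_i - 1), , drop = FALSE] -
                                      matrix(p0, c_i - 1, 2, byrow = TRUE))^2)))
          if (dmin < 2 * (cr + 2 * sp) + 2 * drift) next
        }
        al <- stats::runif(1, 0, jit); ph <- stats::runif(1, 0, 2 * pi)
        dirs[c_i, ] <- c(sin(al) * cos(ph), sin(al) * sin(ph), cos(al))
        base_pts[c_i, ] <- p0
        placed <- TRUE
        break
      }
      if (!placed)
        stop("generate_phantom: canal placement failed after bounded retries; reduce canals$count or radius (crowding)")
    }
    z_mid <- (nz - 1) / 2 * sp
    for (c_i in seq_len(ncan)) {
      p0 <- c(base_pts[c_i, ], z_mid); dv <- dirs[c_i, ]
      hw <- cr + drift + sp
      ix <- which(x_um >= p0[1] - hw & x_um <= p0[1] + hw)
      iy <- which(y_um >= p0[2] - hw & y_um <= p0[2] + hw)
      g <- expand.grid(z = seq_len(nz), y = iy, x = ix)
      px <- x_um[g$x] - p0[1]; py <- y_um[g$y] - p0[2]; pz <- z_um[g$z] - p0[3]
      tproj <- px * dv[1] + py * dv[2] + pz * dv[3]
      perp <- sqrt((px - tproj * dv[1])^2 + (py - tproj * dv[2])^2 +
                     (pz - tproj * dv[3])^2)
      # linear sub-voxel ramp across the canal wall (partial volume)
      fr <- pmin(pmax(0.5 + (cr - perp) / sp, 0), 1)
      touched <- fr > 0
      lin_all <- g$z[touched] + nz * (g$y[touched] - 1) + nz * ny * (g$x[touched] - 1)
      in_b <- bone_arr[lin_all]
      lin_all <- lin_all[in_b]
      fr <- fr[touched][in_b]
      frac_canal[lin_all] <- pmax(frac_canal[lin_all], fr)
      lin <- lin_all[fr >= 0.5]
      canal_labels[lin] <- c_i
      occupancy[lin] <- TRUE
    }
    canal_params <- data.frame(id = seq_len(ncan),
                               x0_um = base_pts[, 1], y0_um = base_pts[, 2],
                               dir_x = dirs[, 1], dir_y = dirs[, 2],
                               dir_z = dirs[, 3], radius_um = cr)
  }

  # ---- lacunae ------------------------------------------------------------
  lac <- config$lacunae
  nlac <- lac$target_count
  lacuna_labels <- array(0L, dims)
  frac_void <- array(0, dims)
  lacuna_params <- NULL
  if (nlac > 0) {
    # truncated lognormal volumes
    meanlog <- log(lac$volume_median_um3)
    draw_vol <- function() {
      for (i in seq_len(1000L)) {
        v <- stats::rlnorm(1, meanlog, lac$sigma_log)
        if (v >= lac$truncation[1] && v <= lac$truncation[2]) return(v)
      }
      stop("generate_phantom: lacunar volume rejection sampling failed; check truncation bounds")
    }
    sub_off <- as.matrix(expand.grid(dx = c(-1, 0, 1) / 3 * sp,
                                     dy = c(-1, 0, 1) / 3 * sp,
                                     dz = c(-1, 0, 1) / 3 * sp))
    s_glob <- lac$volume_scale^(1 / 3)
    s_endo <- lac$endosteal_volume_scale^(1 / 3)
    # two-voxel clearance between void sets: partial-volume halo voxels of
    # neighbouring voids must not bridge under a permissive threshold
    nb_off <- as.vector(outer(outer(-2:2, nz * (-2:2), "+"), nz * ny * (-2:2), "+"))
    # truth-side nearest-surface maps, computed with the same convention the
    # analysis uses (exact EDT to each surface, minimum over lacuna voxels)
    endo2d_t <- bone2d & dilate8_2d(med2d)
    peri2d_t <- bone2d & dilate8_2d(ext2d)
    d_endo_map <- if (any(endo2d_t)) sqrt(cpp_edt3(rep_z(endo2d_t), dims)$dist2) else NULL
    d_peri_map <- if (any(peri2d_t)) sqrt(cpp_edt3(rep_z(peri2d_t), dims)$dist2) else NULL
    d_can_map <- if (ncan > 0 && any(canal_labels > 0L))
      sqrt(cpp_edt3(canal_labels > 0L, dims)$dist2) else NULL
    surf_min <- function(mp, v) if (is.null(mp)) Inf else min(mp[v])
    # sizes, shapes and orientations are drawn up front so the sampled size
    # sequence depends only on the seed and target count, never on how many
    # placement retries the geometry later needs
    draws <- lapply(seq_len(nlac), function(i) {
      v0 <- draw_vol()
      r_mid <- stats::runif(1, lac$axis_ratio_range$mid[1], lac$axis_ratio_range$mid[2])
      r_short <- stats::runif(1, lac$axis_ratio_range$short[1], lac$axis_ratio_range$short[2])
      a0 <- (3 * v0 / (4 * pi * r_mid * r_short))^(1 / 3)
      list(v0 = v0, semi0 = c(a0, a0 * r_mid, a0 * r_short),
           rot = random_rotation())
    })
    # candidate positions are pre-drawn per lacuna as well, so the RNG
    # stream consumed by placement is a fixed function of (seed, count):
    # a retry for one lacuna never shifts another lacuna's candidates
    max_tries <- 300L
    try_mat <- array(stats::runif(nlac * max_tries * 3L),
                     c(max_tries, 3L, nlac))
    rows <- vector("list", nlac)
    for (i in seq_len(nlac)) {
      v0 <- draws[[i]]$v0
      semi0 <- draws[[i]]$semi0
      rot <- draws[[i]]$rot
      placed <- FALSE
      a_fit <- max(semi0) * max(s_glob * max(1, s_endo),
                                lac$fit_headroom %||% 0)
      if (inner + 2 * (a_fit + 2 * sp) >= outer)
        stop("generate_phantom: cortex too thin for lacunar size (crowding via target_count/semi-axes)")
      if ((nz - 1) * sp <= 2 * (a_fit + 2 * sp))
        stop("generate_phantom: volume too short along z for lacunar size")
      for (try in seq_len(max_tries)) {
        # candidate centres are sampled uniformly over the cortical band
        # (cohort-independent mapping; candidates that do not fit are
        # rejected after rasterization, not excluded by shrunken margins)
        u3 <- try_mat[try, , i]
        rmin <- inner + 2 * sp; rmax <- outer - 2 * sp
        rc <- sqrt(rmin^2 + u3[1] * (rmax^2 - rmin^2))
        th <- u3[2] * 2 * pi
        ctr <- c(cx + rc * cos(th), cy + rc * sin(th),
                 u3[3] * (nz - 1) * sp)
        rasterize <- function(semi) {
          amax <- max(semi)
          ix <- which(x_um >= ctr[1] - amax - sp & x_um <= ctr[1] + amax + sp)
          iy <- which(y_um >= ctr[2] - amax - sp & y_um <= ctr[2] + amax + sp)
          iz <- which(z_um >= ctr[3] - amax - sp & z_um <= ctr[3] + amax + sp)
          g <- expand.grid(z = iz, y = iy, x = ix)
          pc <- cbind(x_um[g$x] - ctr[1], y_um[g$y] - ctr[2], z_um[g$z] - ctr[3])
          fr <- numeric(nrow(pc))
          for (s in seq_len(nrow(sub_off))) {
            u <- (pc + matrix(sub_off[s, ], nrow(pc), 3, byrow = TRUE)) %*% rot
            fr <- fr + as.numeric((u[, 1] / semi[1])^2 + (u[, 2] / semi[2])^2 +
                                    (u[, 3] / semi[3])^2 <= 1)
          }
          fr <- fr / nrow(sub_off)
          list(lin = g$z + nz * (g$y - 1) + nz * ny * (g$x - 1), fr = fr)
        }
        # quick reject when the bounding sphere cannot fit at this centre
        if (rc - a_fit - 2 * sp < inner || rc + a_fit + 2 * sp > outer) next
        if (ctr[3] < a_fit + 2 * sp || ctr[3] > (nz - 1) * sp - a_fit - 2 * sp) next
        # rasterize at the cohort's global scale, then read the truth-side
        # nearest surface off the lacuna's own voxels (pipeline convention)
        ras <- rasterize(semi0 * s_glob)
        probe_vox <- ras$lin[ras$fr >= 0.5]
        if (!length(probe_vox)) next   # too small to voxelize at this position
        dists <- c(endosteum = surf_min(d_endo_map, probe_vox),
                   canals = surf_min(d_can_map, probe_vox),
                   periosteum = surf_min(d_peri_map, probe_vox))
        nearest <- names(dists)[which.min(dists)]   # ties -> endosteum (order)
        s_i <- s_glob * if (nearest == "endosteum") s_endo else 1
        semi <- semi0 * s_i
        if (s_i != s_glob) ras <- rasterize(semi)
        fr <- ras$fr
        keep <- fr > 0
        if (!any(fr >= 0.5)) next   # too small to voxelize at this position
        lin_all <- ras$lin
        void_lin <- lin_all[fr >= 0.5]
        # clearance from every existing void (keeps components disjoint)
        dil <- unique(as.vector(outer(void_lin, nb_off, "+")))
        if (any(occupancy[dil])) next
        if (!all(bone_arr[void_lin])) next
        occupancy[void_lin] <- TRUE
        lacuna_labels[void_lin] <- i
        sel <- lin_all[keep]
        frac_void[sel] <- pmax(frac_void[sel], fr[keep])
        rows[[i]] <- data.frame(
          id = i,
          center_z_um = ctr[3], center_y_um = ctr[2], center_x_um = ctr[1],
          semi_a_um = semi[1], semi_b_um = semi[2], semi_c_um = semi[3],
          analytic_volume_um3 = 4 / 3 * pi * prod(semi),
          base_volume_um3 = v0,
          linear_scale_applied = s_i,
          cohort_effect_applied = s_i != 1,
          truth_surface = nearest,
          voxel_count = length(void_lin))
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(paste("generate_phantom: lacuna placement failed after bounded",
                           "retries at lacuna %d; the cortex is too crowded for",
                           "lacunae$target_count = %d"), i, nlac))
    }
    lacuna_params <- do.call(rbind, rows)
  } else {
    lacuna_params <- data.frame(id = integer(), center_z_um = numeric(),
                                center_y_um = numeric(), center_x_um = numeric(),
                                semi_a_um = numeric(), semi_b_um = numeric(),
                                semi_c_um = numeric(),
                                analytic_volume_um3 = numeric(),
                                base_volume_um3 = numeric(),
                                linear_scale_applied = numeric(),
                                cohort_effect_applied = logical(),
                                truth_surface = character(),
                                voxel_count = integer())
  }

  # truth top-quartile lacunae (per generated sample, by analytic volume)
  q4_ids <- integer()
  if (nrow(lacuna_params) >= 4) {
    q75 <- stats::quantile(lacuna_params$analytic_volume_um3, 0.75, type = 7)
    q4_ids <- lacuna_params$id[lacuna_params$analytic_volume_um3 >= q75]
  }

  # ---- mineral field ------------------------------------------------------
  mn <- config$mineral
  bone_val <- array(mn$baseline, dims)
  if (nrow(lacuna_params) > 0) {
    e <- cpp_edt3(lacuna_labels > 0, dims)
    d_um <- sqrt(e$dist2) * sp
    modifier <- array(0, dims)
    hs <- mn$hyper_shell
    in_shell <- d_um >= hs$inner_um & d_um < hs$outer_um
    modifier[in_shell] <- hs$amplitude_frac
    ha <- mn$hypo_annulus
    if (isTRUE(ha$enabled) && length(q4_ids)) {
      near_id <- array(lacuna_labels[e$site], dims)
      in_ann <- d_um >= ha$inner_um & d_um < ha$outer_um &
        array(near_id %in% q4_ids, dims)
      modifier[in_ann] <- modifier[in_ann] + ha$amplitude_frac
    }
    bone_val <- mn$baseline * (1 + modifier)
  }

  att <- array(mn$background, dims)
  in_bone <- bone_arr & !occupancy
  att[in_bone] <- bone_val[in_bone]
  # partial-volume blend at lacunar and canal boundaries
  frac_void <- pmax(frac_void, frac_canal)
  pv <- frac_void > 0
  att[pv] <- (1 - frac_void[pv]) * bone_val[pv] + frac_void[pv] * mn$background

  if (config$noise_sigma_frac > 0) {
    att <- att + stats::rnorm(nvox, 0,
                              config$noise_sigma_frac * (mn$baseline - mn$background))
  }

  endo2d <- bone2d & dilate8_2d(med2d)
  peri2d <- bone2d & dilate8_2d(ext2d)

  truth <- list(
    lacuna_labels = volume3d(lacuna_labels, sp, "labels"),
    canal_labels = volume3d(canal_labels, sp, "labels"),
    bone_mask = volume3d(bone_arr + 0L, sp, "binary"),
    endosteum_mask = volume3d(rep_z(endo2d) + 0L, sp, "binary"),
    periosteum_mask = volume3d(rep_z(peri2d) + 0L, sp, "binary"),
    lacuna_params = lacuna_params,
    canal_params = canal_params,
    q4_ids = q4_ids,
    config = config)
  list(attenuation = volume3d(att, sp, "attenuation"), truth = truth)
}
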