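#' Specification for a synthetic lesioned-slice image
#'
#' Parameters of the synthetic generators that emulate a focal contusion in
#' a cultured cortical slice: a radially decaying cell-death (PI-like)
#' signal centred on the lesion, filamentous neurite networks whose density
#' drops toward the lesion core, and cell populations shifting from ramified
#' (periphery) to amoeboid (core) morphology. Noise is Poisson shot noise
#' plus additive Gaussian read noise, the photon-limited confocal model.
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_size um/pixel (> 0).
#' @param n_z number of z-slices (>= 1).
#' @param lesion_center 0-based `(row, col)`; must lie inside the image.
#' @param pi_amplitude,pi_sigma,pi_baseline radial Gaussian profile of the
#'   cell-death signal: amplitude and baseline in intensity units, sigma in
#'   um (> 0).
#' @param filament_rate expected filaments seeded per 100 x 100 um tile at
#'   density factor 1.
#' @param density_factors named numeric `(lesion, perilesion, periphery)`,
#'   each in \[0, 1\]: regional modulation `d(region)` of the filament
#'   seeding rate. Regions follow the half-open 0.5 mm convention shared
#'   with the analysis ([assign_region()]).
#' @param branching_prob per-step branch probability in \[0, 1\].
#' @param filament_steps `(min, max)` random-walk step count per filament.
#' @param cell_count number of cells to place (uniformly over the image).
#' @param amoeboid_fraction_core,amoeboid_fraction_periphery probability a
#'   cell is amoeboid at the lesion centre (r = 0) and at the farthest image
#'   corner; interpolated linearly in between. Both in \[0, 1\].
#' @param cell_area_range `(min, max)` designed amoeboid cell area in um^2.
#' @param background,foreground 16-bit gray levels of background and
#'   rendered structures (defaults 900 and 4000, so a 1200 background floor
#'   is meaningful on synthetic data).
#' @param noise_gain photons per intensity unit (> 0; `Inf` disables shot
#'   noise).
#' @param read_noise_sd Gaussian read noise SD in intensity units (>= 0).
#' @param z_step z spacing in um (metadata only).
#' @param seed integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return an object of class `slice_spec`.
#' @export
slice_spec <- function(image_shape = c(400L, 400L),
                       pixel_size = 10,
                       n_z = 1L,
                       lesion_center = (image_shape - 1) / 2,
                       pi_amplitude = 1000,
                       pi_sigma = 500,
                       pi_baseline = 100,
                       filament_rate = 2,
                       density_factors = c(lesion = 0.2, perilesion = 0.6,
                                           periphery = 1.0),
                       branching_prob = 0.04,
                       filament_steps = c(15L, 25L),
                       cell_count = 150L,
                       amoeboid_fraction_core = 0.8,
                       amoeboid_fraction_periphery = 0.2,
                       cell_area_range = c(80, 300),
                       background = 900,
                       foreground = 4000,
                       noise_gain = 0.5,
                       read_noise_sd = 20,
                       z_step = 1,
                       seed = 1L) {
  spec <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
               n_z = as.integer(n_z), lesion_center = as.numeric(lesion_center),
               pi_amplitude = pi_amplitude, pi_sigma = pi_sigma,
               pi_baseline = pi_baseline, filament_rate = filament_rate,
               density_factors = density_factors,
               branching_prob = branching_prob,
               filament_steps = as.integer(filament_steps),
               cell_count = as.integer(cell_count),
               amoeboid_fraction_core = amoeboid_fraction_core,
               amoeboid_fraction_periphery = amoeboid_fraction_periphery,
               cell_area_range = cell_area_range,
               background = background, foreground = foreground,
               noise_gain = noise_gain, read_noise_sd = read_noise_sd,
               z_step = z_step, seed = as.integer(seed))
  validate_slice_spec(spec)
  structure(spec, class = "slice_spec")
}

validate_slice_spec <- function(s) {
  stopifnot(length(s$image_shape) == 2, all(s$image_shape >= 8))
  if (s$pixel_size <= 0) stop("pixel_size must be > 0")
  if (s$pi_sigma <= 0) stop("pi_sigma must be > 0")
  if (s$pi_amplitude < 0 || s$pi_baseline < 0)
    stop("amplitudes must be >= 0")
  if (s$noise_gain <= 0) stop("noise_gain must be > 0")
  if (s$read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  fr <- c(s$density_factors, s$branching_prob, s$amoeboid_fraction_core,
          s$amoeboid_fraction_periphery)
  if (any(fr < 0 | fr > 1))
    stop("fractions and probabilities must lie in [0, 1]")
  if (length(s$density_factors) != 3)
    stop("density_factors must give (lesion, perilesion, periphery)")
  ctr <- s$lesion_center
  if (any(ctr < 0) || ctr[1] > s$image_shape[1] - 1 ||
      ctr[2] > s$image_shape[2] - 1)
    stop("lesion_center must lie inside the image")
  if (s$n_z < 1) stop("n_z must be >= 1")
  invisible(s)
}

# Poisson shot noise + Gaussian read noise on a noiseless signal array.
apply_noise <- function(signal, noise_gain, read_noise_sd) {
  n <- length(signal)
  shot <- if (is.infinite(noise_gain)) as.numeric(signal)
          else rpois(n, lambda = as.numeric(signal) * noise_gain) / noise_gain
  out <- shot + if (read_noise_sd > 0) rnorm(n, 0, read_noise_sd) else 0
  array(pmin(pmax(out, 0), 65535), dim = dim(signal))
}

#' Simulate the cell-death (PI) channel
#'
#' Noiseless signal at pixel `p` is
#' `baseline + amplitude * exp(-r(p)^2 / (2 * sigma^2))` with `r(p)` the
#' Euclidean distance to the lesion centre in um; Poisson/Gaussian noise is
#' applied independently per z-slice. Ground truth records the true
#' (pre-noise) mean intensity per 500 um concentric ring.
#'
#' @param spec a [slice_spec()].
#' @return list with `image` (rows x cols x n_z array), `noiseless`
#'   (2D matrix), `ground_truth` (data.frame `ring`, `inner_um`,
#'   `outer_um`, `true_mean`), `spec`.
#' @export
simulate_pi_channel <- function(spec) {
  validate_slice_spec(spec)
  withr::with_seed(spec$seed, {
    d <- distance_map_um(spec$image_shape, spec$lesion_center,
                         spec$pixel_size)
    signal <- spec$pi_baseline +
      spec$pi_amplitude * exp(-d^2 / (2 * spec$pi_sigma^2))
    img <- array(0, dim = c(spec$image_shape, spec$n_z))
    for (z in seq_len(spec$n_z))
      img[, , z] <- apply_noise(signal, spec$noise_gain, spec$read_noise_sd)
    geom <- lesion_geometry(spec$lesion_center, spec$pixel_size,
                            n_rings = max(1L, floor(max(d) / 500)))
    rings <- build_concentric_rings(geom, spec$image_shape)
    gt <- rings$info[, c("ring", "inner_um", "outer_um")]
    gt$true_mean <- vapply(rings$masks, function(m)
      if (sum(m)) mean(signal[m]) else NA_real_, numeric(1))
    list(image = img, noiseless = signal, ground_truth = gt, spec = spec)
  })
}

#' Simulate the neurite (MAP-2-like) channel
#'
#' Filaments are grown as biased random walks (step 1 px, direction
#' perturbed by a bounded angle each step, branching with `branching_prob`
#' per step). Seed points arise from a Poisson process whose intensity is
#' `filament_rate * d(region)` per 100 x 100 um tile, with the region of the
#' seed determined by its distance from the lesion centre (same half-open
#' 0.5 mm convention as the analysis). Filaments are rendered 3 px wide at
#' the foreground intensity onto one randomly assigned z-slice each. Ground
#' truth records one row per filament: seed position, region, realized step
#' count and path length (steps x pixel_size, branches included).
#'
#' @param spec a [slice_spec()].
#' @param seeds optional matrix of 0-based `(row, col)` seed positions that
#'   bypasses Poisson seeding (used for constructed fixtures).
#' @param max_turn maximum per-step direction change in radians.
#' @return list with `image`, `binary_truth` (noiseless rendered mask),
#'   `ground_truth` (per-filament data.frame), `spec`.
#' @export
simulate_neurite_channel <- function(spec, seeds = NULL, max_turn = 0.4) {
  validate_slice_spec(spec)
  withr::with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    if (is.null(seeds)) {
      tiles <- nr * nc * spec$pixel_size^2 / 1e4
      n_cand <- rpois(1, spec$filament_rate * tiles)
      if (n_cand > 0) {
        cand <- cbind(runif(n_cand, 0, nr - 1), runif(n_cand, 0, nc - 1))
        dist_um <- spec$pixel_size *
          sqrt((cand[, 1] - spec$lesion_center[1])^2 +
               (cand[, 2] - spec$lesion_center[2])^2)
        reg <- assign_region(dist_um)
        keep <- runif(n_cand) < spec$density_factors[as.integer(reg)]
        seeds <- cand[keep, , drop = FALSE]
      } else seeds <- matrix(numeric(), ncol = 2)
    }
    mask <- matrix(FALSE, nr, nc)
    zmask <- array(FALSE, dim = c(nr, nc, spec$n_z))
    n_fil <- nrow(seeds)
    gt_z <- gt_steps <- integer(n_fil)
    for (f in seq_len(n_fil)) {
      n_steps <- spec$filament_steps[1] +
        sample.int(spec$filament_steps[2] - spec$filament_steps[1] + 1L, 1) - 1L
      z <- sample.int(spec$n_z, 1)
      # depth-first stack of walkers: each walker's whole path is drawn
      # vectorized (cumulative turns); walks stop at the image border
      walkers <- list(list(pos = c(seeds[f, 1], seeds[f, 2]),
                           ang = runif(1, 0, 2 * pi), left = n_steps))
      total_steps <- 0L
      while (length(walkers) > 0) {
        w <- walkers[[length(walkers)]]
        walkers[[length(walkers)]] <- NULL
        n <- w$left
        if (n <= 0) next
        angs <- w$ang + cumsum(runif(n, -max_turn, max_turn))
        rows <- w$pos[1] + cumsum(sin(angs))
        cols <- w$pos[2] + cumsum(cos(angs))
        out <- which(rows < 0 | cols < 0 | rows > nr - 1 | cols > nc - 1)
        n_eff <- if (length(out)) out[1] - 1L else n
        if (n_eff == 0L) next
        total_steps <- total_steps + n_eff
        # branch spawns along the realized path, inheriting the remaining
        # step budget
        br <- which(runif(n) < spec$branching_prob)
        for (b in br[br < n_eff])
          walkers[[length(walkers) + 1L]] <- list(
            pos = c(rows[b], cols[b]),
            ang = angs[b] + sample(c(-1, 1), 1) * runif(1, pi / 6, pi / 3),
            left = n - b)
        # render 3 px wide
        pr <- round(rows[seq_len(n_eff)]) + 1L
        pc <- round(cols[seq_len(n_eff)]) + 1L
        for (dr in -1:1) for (dc in -1:1) {
          ri <- pmin(pmax(pr + dr, 1L), nr)
          ci <- pmin(pmax(pc + dc, 1L), nc)
          idx <- cbind(ri, ci)
          mask[idx] <- TRUE
          zmask[cbind(ri, ci, z)] <- TRUE
        }
      }
      gt_z[f] <- z
      gt_steps[f] <- total_steps
    }
    if (n_fil > 0) {
      dist_um <- spec$pixel_size *
        sqrt((seeds[, 1] - spec$lesion_center[1])^2 +
             (seeds[, 2] - spec$lesion_center[2])^2)
      gt <- data.frame(
        filament = seq_len(n_fil), seed_row = seeds[, 1],
        seed_col = seeds[, 2],
        region = as.character(assign_region(dist_um)), z = gt_z,
        n_steps = gt_steps, length_um = gt_steps * spec$pixel_size)
    } else {
      gt <- data.frame(filament = integer(), seed_row = numeric(),
                       seed_col = numeric(), region = character(),
                       z = integer(), n_steps = integer(),
                       length_um = numeric())
    }
    img <- array(0, dim = c(nr, nc, spec$n_z))
    for (z in seq_len(spec$n_z)) {
      signal <- matrix(spec$background, nr, nc)
      signal[zmask[, , z]] <- spec$foreground
      img[, , z] <- apply_noise(signal, spec$noise_gain, spec$read_noise_sd)
    }
    list(image = img, binary_truth = mask, ground_truth = gt, spec = spec)
  })
}

#' Aggregate filament ground truth over a rectangular ROI
#'
#' Counts filaments seeded inside the ROI and sums their designed path
#' lengths (a filament is attributed to the ROI of its seed point).
#'
#' @param ground_truth per-filament data.frame from
#'   [simulate_neurite_channel()].
#' @param roi numeric `(row0, col0, size)`: 0-based top-left corner and edge
#'   length in pixels.
#' @return list with `n_filaments` and `length_um`.
#' @export
filament_truth_in_roi <- function(ground_truth, roi) {
  inroi <- ground_truth$seed_row >= roi[1] &
    ground_truth$seed_row < roi[1] + roi[3] &
    ground_truth$seed_col >= roi[2] &
    ground_truth$seed_col < roi[2] + roi[3]
  list(n_filaments = sum(inroi),
       length_um = sum(ground_truth$length_um[inroi]))
}

#' Simulate the cell (microglia-like) channel
#'
#' Places `cell_count` non-overlapping cells uniformly over the image.
#' The probability that a cell is amoeboid interpolates linearly from
#' `amoeboid_fraction_core` at the lesion centre to
#' `amoeboid_fraction_periphery` at the farthest image corner. Amoeboid
#' cells are filled ellipses with designed area drawn from
#' `cell_area_range`; ramified cells are a small soma with 3-6 narrow
#' radiating processes. Cells are rendered on every z-slice (focal planes
#' of one field) with independent noise. Ground truth stores one row per
#' cell: class, centre, designed area (analytic ellipse area for amoeboid,
#' rendered pixel area for ramified) and distance from the lesion centre.
#'
#' @param spec a [slice_spec()].
#' @param max_attempts_per_cell rejection-sampling budget per cell before
#'   the generator fails; default 200.
#' @return list with `image`, `binary_truth`, `ground_truth`
#'   (data.frame: `cell`, `class`, `row`, `col`, `designed_area_um2`,
#'   `dist_um`, `p_amoeboid`), `spec`.
#' @export
simulate_cell_channel <- function(spec, max_attempts_per_cell = 200) {
  validate_slice_spec(spec)
  withr::with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    ps <- spec$pixel_size
    corners <- rbind(c(0, 0), c(0, nc - 1), c(nr - 1, 0), c(nr - 1, nc - 1))
    r_corner <- max(sqrt((corners[, 1] - spec$lesion_center[1])^2 +
                         (corners[, 2] - spec$lesion_center[2])^2)) * ps
    mask <- matrix(FALSE, nr, nc)
    placed <- matrix(numeric(), ncol = 3)  # row, col, clearance radius (px)
    gt <- list()
    attempts_left <- max_attempts_per_cell * max(1L, spec$cell_count)
    for (cell in seq_len(spec$cell_count)) {
      ok <- FALSE
      while (attempts_left > 0) {
        attempts_left <- attempts_left - 1
        pos <- c(runif(1, 0, nr - 1), runif(1, 0, nc - 1))
        r_um <- ps * sqrt(sum((pos - spec$lesion_center)^2))
        p_amo <- spec$amoeboid_fraction_core +
          (spec$amoeboid_fraction_periphery - spec$amoeboid_fraction_core) *
          min(r_um / r_corner, 1)
        is_amo <- runif(1) < p_amo
        if (is_amo) {
          area <- runif(1, spec$cell_area_range[1], spec$cell_area_range[2])
          aspect <- runif(1, 1, 1.8)
          a_um <- sqrt(area * aspect / pi); b_um <- area / (pi * a_um)
          rad_px <- a_um / ps
          shape <- list(kind = "amoeboid", a = a_um / ps, b = b_um / ps,
                        theta = runif(1, 0, pi), designed_area = area)
        } else {
          soma_px <- runif(1, 2.5, 3.5) / ps  # soma radius in um -> px
          nproc <- sample(3:6, 1)
          plen <- runif(nproc, 8, 18) / ps
          pang <- 2 * pi * (seq_len(nproc) - 1) / nproc +
            runif(nproc, -0.3, 0.3)
          rad_px <- soma_px + max(plen)
          shape <- list(kind = "ramified", soma = soma_px, plen = plen,
                        pang = pang)
        }
        margin <- rad_px + 1
        if (pos[1] < margin || pos[2] < margin ||
            pos[1] > nr - 1 - margin || pos[2] > nc - 1 - margin) next
        if (nrow(placed) > 0) {
          dd <- sqrt((placed[, 1] - pos[1])^2 + (placed[, 2] - pos[2])^2)
          if (any(dd < placed[, 3] + rad_px + 2)) next
        }
        # render
        npix_before <- sum(mask)
        mask <- render_cell(mask, pos, shape)
        placed <- rbind(placed, c(pos, rad_px))
        designed <- if (shape$kind == "amoeboid") shape$designed_area else
          (sum(mask) - npix_before) * ps^2
        gt[[cell]] <- data.frame(
          cell = cell, class = shape$kind, row = pos[1], col = pos[2],
          designed_area_um2 = designed, dist_um = r_um, p_amoeboid = p_amo)
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(
          "could not place %d non-overlapping cells (attempt budget exhausted at cell %d)",
          spec$cell_count, cell))
    }
    gt <- if (length(gt)) do.call(rbind, gt) else
      data.frame(cell = integer(), class = character(), row = numeric(),
                 col = numeric(), designed_area_um2 = numeric(),
                 dist_um = numeric(), p_amoeboid = numeric())
    img <- array(0, dim = c(nr, nc, spec$n_z))
    for (z in seq_len(spec$n_z)) {
      signal <- matrix(spec$background, nr, nc)
      signal[mask] <- spec$foreground
      img[, , z] <- apply_noise(signal, spec$noise_gain, spec$read_noise_sd)
    }
    list(image = img, binary_truth = mask, ground_truth = gt, spec = spec)
  })
}

# Render one cell onto a logical mask (1-based matrix indexing internally).
render_cell <- function(mask, pos, shape) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (shape$kind == "amoeboid") {
    a <- shape$a; b <- shape$b; th <- shape$theta
    half <- ceiling(a) + 1
    ri <- max(1, floor(pos[1]) - half):min(nr, ceiling(pos[1]) + half)
    ci <- max(1, floor(pos[2]) - half):min(nc, ceiling(pos[2]) + half)
    dr <- (ri - 1) - pos[1]; dc <- (ci - 1) - pos[2]
    u <- outer(dr * cos(th), dc * sin(th), `+`)
    v <- outer(-dr * sin(th), dc * cos(th), `+`)
    mask[ri, ci] <- mask[ri, ci] | (u / a)^2 + (v / b)^2 <= 1
  } else {
    # soma
    half <- ceiling(shape$soma) + 1
    ri <- max(1, floor(pos[1]) - half):min(nr, ceiling(pos[1]) + half)
    ci <- max(1, floor(pos[2]) - half):min(nc, ceiling(pos[2]) + half)
    dr <- (ri - 1) - pos[1]; dc <- (ci - 1) - pos[2]
    mask[ri, ci] <- mask[ri, ci] |
      outer(dr^2, dc^2, `+`) <= shape$soma^2
    # processes: 1-px-wide rays from the soma edge
    for (k in seq_along(shape$plen)) {
      tt <- seq(0, 1, length.out = max(2, ceiling(shape$plen[k]) * 2))
      rr <- round(pos[1] + (shape$soma * 0.8 + tt * shape$plen[k]) *
                    sin(shape$pang[k])) + 1
      cc <- round(pos[2] + (shape$soma * 0.8 + tt * shape$plen[k]) *
                    cos(shape$pang[k])) + 1
      keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      mask[cbind(rr[keep], cc[keep])] <- TRUE
    }
  }
  mask
}

#' Simulate a qPCR Ct table
#'
#' `Ct(gene, sample) = base_ct(gene) - true_log2fc(gene) * treated +
#' N(0, ct_noise_sd)`; the reference gene's Ct is independent of group
#' (its planted log2 fold change is 0 by construction). An optional second
#' treated group supports three-arm designs.
#'
#' @param genes character vector of target gene names.
#' @param n_ctrl,n_tbi samples per group (>= 2).
#' @param true_log2fc named numeric: planted log2 fold change per gene in
#'   the treated group (unnamed scalar recycles to all genes).
#' @param ct_noise_sd per-measurement Ct noise SD in cycles (>= 0).
#' @param seed integer seed.
#' @param base_ct named numeric baseline Ct per gene (default 25; reference
#'   18).
#' @param reference_gene reference gene name; default `"RPL27"`.
#' @param group_labels `(control, treated)` labels.
#' @param treated2 optional `list(label =, n =, log2fc =)` for a second
#'   treated group.
#' @return data.frame: `sample_id`, `group`, `gene`, `ct`, `is_reference`.
#' @export
simulate_ct_table <- function(genes, n_ctrl, n_tbi, true_log2fc = 0,
                              ct_noise_sd = 0.3, seed = 1L, base_ct = NULL,
                              reference_gene = "RPL27",
                              group_labels = c("CTRL", "TBI"),
                              treated2 = NULL) {
  if (n_ctrl < 2 || n_tbi < 2) stop("need >= 2 samples per group")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  if (is.null(names(true_log2fc)))
    true_log2fc <- stats::setNames(rep(true_log2fc, length(genes)), genes)
  if (reference_gene %in% names(true_log2fc) &&
      true_log2fc[[reference_gene]] != 0)
    stop("the reference gene must have true_log2fc = 0")
  all_genes <- union(genes, reference_gene)
  lfc <- stats::setNames(rep(0, length(all_genes)), all_genes)
  lfc[names(true_log2fc)] <- true_log2fc
  lfc[reference_gene] <- 0
  if (is.null(base_ct))
    base_ct <- stats::setNames(
      ifelse(all_genes == reference_gene, 18, 25), all_genes)
  groups <- c(rep(group_labels[1], n_ctrl), rep(group_labels[2], n_tbi))
  effects <- list(stats::setNames(rep(0, length(all_genes)), all_genes),
                  lfc)
  names(effects) <- group_labels
  if (!is.null(treated2)) {
    groups <- c(groups, rep(treated2$label, treated2$n))
    lfc2 <- stats::setNames(rep(0, length(all_genes)), all_genes)
    l2 <- treated2$log2fc
    if (is.null(names(l2))) l2 <- stats::setNames(rep(l2, length(genes)), genes)
    lfc2[names(l2)] <- l2
    lfc2[reference_gene] <- 0
    effects[[treated2$label]] <- lfc2
  }
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (i in seq_along(groups)) {
      sid <- sprintf("S%02d", i)
      eff <- effects[[groups[i]]]
      ct <- base_ct[all_genes] - eff[all_genes] +
        rnorm(length(all_genes), 0, ct_noise_sd)
      rows[[i]] <- data.frame(sample_id = sid, group = groups[i],
                              gene = all_genes, ct = as.numeric(ct),
                              is_reference = all_genes == reference_gene)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a per-sample biomarker concentration table
#'
#' Log-normal concentrations with a planted fold change in the treated
#' group, emulating injury biomarkers released into culture medium.
#'
#' @param analytes character vector of analyte names.
#' @param n_per_group samples per group.
#' @param fold_change named (or scalar) treated/control fold change per
#'   analyte.
#' @param cv coefficient of variation on the log-normal scale.
#' @param seed integer seed.
#' @param base_conc control-group median concentration (pg/ml).
#' @param group_labels `(control, treated)` labels.
#' @return data.frame: `sample_id`, `group`, `analyte`,
#'   `concentration_pg_ml`.
#' @export
simulate_biomarker_table <- function(analytes, n_per_group = 6,
                                     fold_change = 2, cv = 0.25, seed = 1L,
                                     base_conc = 100,
                                     group_labels = c("CTRL", "TBI")) {
  if (is.null(names(fold_change)))
    fold_change <- stats::setNames(rep(fold_change, length(analytes)),
                                   analytes)
  withr::with_seed(as.integer(seed), {
    rows <- list()
    i <- 0
    for (g in group_labels) for (s in seq_len(n_per_group)) {
      i <- i + 1
      fc <- if (g == group_labels[1]) 1 else fold_change[analytes]
      conc <- base_conc * fc *
        exp(rnorm(length(analytes), 0, sqrt(log(1 + cv^2))))
      rows[[i]] <- data.frame(sample_id = sprintf("S%02d", i), group = g,
                              analyte = analytes,
                              concentration_pg_ml = as.numeric(conc))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
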