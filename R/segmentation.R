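# Statistics-based tagged segmentation of the left-atrial wall from a
# contrast-enhanced voxel image: sample-statistics thresholds, median
# prefilter, dilation-based wall construction with a physical thickness cap,
# MV/PV orifice tagging by analytic cutting geometries, and constrained
# level-set smoothing with isotropic resampling.

#' Tag registry shared by all segmentation outputs
#'
#' Integer codes for the named segmentation classes: background (0),
#' blood_pool (1), aw (2, atrial wall), mv (3, mitral-valve ring),
#' pv (4, pulmonary-vein ends).  The wall proper (`mc`) is the union of
#' aw, mv and pv.
#' @return named integer vector
#' @export
segmentation_tags <- function() {
  c(background = 0L, blood_pool = 1L, aw = 2L, mv = 3L, pv = 4L)
}

#' Tagged segmentation container
#'
#' @param labels 3-D integer array of codes from [segmentation_tags()]
#' @param spacing,origin as in [voxel_image()]
#' @return object of class `tagged_segmentation`
#' @export
tagged_segmentation <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stopf("tagged_segmentation: labels must be 3-D")
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), tags = segmentation_tags()),
            class = "tagged_segmentation")
}

#' Class mask of a tagged segmentation
#' @param seg a [tagged_segmentation()]
#' @param classes character vector of class names; `"mc"` expands to
#'   `c("aw","mv","pv")` (the myocardial wall)
#' @return logical array
#' @export
seg_mask <- function(seg, classes) {
  if ("mc" %in% classes) classes <- unique(c(setdiff(classes, "mc"), "aw", "mv", "pv"))
  codes <- segmentation_tags()[classes]
  if (anyNA(codes)) stopf("seg_mask: unknown class name")
  array(seg$labels %in% codes, dim(seg$labels))
}

#' @export
print.tagged_segmentation <- function(x, ...) {
  tb <- table(factor(x$labels, levels = segmentation_tags(),
                     labels = names(segmentation_tags())))
  cat(sprintf("tagged_segmentation %s @ (%g, %g, %g) mm\n",
              paste(dim(x$labels), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  print(tb)
  invisible(x)
}

#' Intensity thresholds from sample-region statistics
#'
#' Pools the myocardial and blood sample voxels (union over the sample
#' regions, not per-region averages) and derives the lower, mid and upper
#' thresholds: LT = mean_myo - 3 sd_myo, UT = mean_blood + 3 sd_blood, and the
#' common mid threshold MT = (mean_myo + mean_blood)/2 separating the two
#' populations.
#'
#' @param image a [voxel_image()]
#' @param myo_samples,blood_samples logical voxel masks of the sample regions
#' @return list with `stats` (mean_myo, sd_myo, mean_blood, sd_blood, n_myo,
#'   n_blood) and `thresholds` (LT, MT, UT)
#' @export
compute_thresholds <- function(image, myo_samples, blood_samples) {
  if (!any(myo_samples) || !any(blood_samples))
    stopf("compute_thresholds: empty sample mask")
  if (any(myo_samples & blood_samples))
    stopf("compute_thresholds: sample masks overlap")
  xm <- image$data[myo_samples]; xb <- image$data[blood_samples]
  # population SD over the pooled sample voxels
  sdp <- function(x) sqrt(mean((x - mean(x))^2))
  st <- list(mean_myo = mean(xm), sd_myo = sdp(xm),
             mean_blood = mean(xb), sd_blood = sdp(xb),
             n_myo = length(xm), n_blood = length(xb))
  thr <- list(LT = st$mean_myo - 3 * st$sd_myo,
              MT = (st$mean_myo + st$mean_blood) / 2,
              UT = st$mean_blood + 3 * st$sd_blood)
  if (thr$LT >= thr$MT)
    stopf(paste("compute_thresholds: degenerate statistics, LT %.3g >= MT %.3g",
                "(myocardium N(%.3g, %.3g) overlaps blood N(%.3g, %.3g))"),
          thr$LT, thr$MT, st$mean_myo, st$sd_myo, st$mean_blood, st$sd_blood)
  if (thr$MT >= thr$UT)
    stopf("compute_thresholds: degenerate statistics, MT %.3g >= UT %.3g", thr$MT, thr$UT)
  list(stats = st, thresholds = thr)
}

#' Median prefilter
#'
#' Radius-parameterized median filter; the default kernel is the voxel plus
#' its 6 face neighbors (edge voxels replicate the border).  Idempotent on
#' constant images and removes isolated impulses.
#'
#' @param image a [voxel_image()]
#' @param kernel `"face6"` (center + 6 face neighbors) or `"center_only"`
#' @return filtered [voxel_image()]
#' @export
median_prefilter <- function(image, kernel = c("face6", "center_only")) {
  kernel <- match.arg(kernel)
  if (kernel == "center_only") return(image)
  a <- image$data
  d <- dim(a)
  # replicate-padded shifts
  shift_rep <- function(a, ax, s) {
    out <- array_shift(a, ax, s, 0)
    idx <- lapply(d, seq_len)
    if (s > 0) idx[[ax]] <- 1L else idx[[ax]] <- d[ax]
    src <- idx; # border replication
    out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  cols <- list(as.vector(a))
  for (ax in 1:3) for (s in c(-1L, 1L))
    cols[[length(cols) + 1L]] <- as.vector(shift_rep(a, ax, s))
  M <- do.call(cbind, cols)
  k <- ncol(M)
  # vectorized bubble sorting network; median = middle column of sorted rows
  for (i in seq_len(k - 1L)) for (j in seq_len(k - i)) {
    x <- M[, j]; y <- M[, j + 1L]
    M[, j] <- pmin(x, y); M[, j + 1L] <- pmax(x, y)
  }
  med <- M[, (k + 1L) %/% 2L]
  voxel_image(array(med, d), image$spacing, image$origin)
}

#' Build the blood pool and thickness-restricted wall
#'
#' Thresholds the blood pool (intensities in \[MT, UT\] connected to the seed)
#' and the viable myocardium (\[LT, MT)), then constructs the wall as the
#' union of (a) K iterative 6-connected dilations of the blood pool
#' intersected with the viable myocardium, where K realizes the physical
#' thickness cap, and (b) a 1-voxel dilation ring guaranteeing minimum wall
#' thickness everywhere adjacent to blood.
#'
#' @param image a [voxel_image()]
#' @param thresholds list with LT, MT, UT (from [compute_thresholds()])
#' @param seed physical coordinate (mm) of a point inside the blood pool
#' @param max_thickness physical wall-thickness cap (mm); default 3
#' @param cap_mode `"dilations"` (K = floor(cap / min spacing) dilation steps,
#'   default) or `"euclidean"` (additionally crop wall voxels farther than the
#'   cap from the blood pool)
#' @return a [tagged_segmentation()] with blood_pool and aw classes
#' @export
build_wall <- function(image, thresholds, seed, max_thickness = 3,
                       cap_mode = c("dilations", "euclidean")) {
  cap_mode <- match.arg(cap_mode)
  stopifnot(max_thickness > 0)
  thr <- thresholds
  a <- image$data
  blood_band <- a >= thr$MT & a <= thr$UT
  if (!any(blood_band)) stopf("build_wall: empty blood pool after thresholding")
  seed_idx <- physical_to_voxel(image, matrix(seed, 1))[1, ]
  blood <- connected_component6(blood_band, seed_idx)
  viable <- a >= thr$LT & a < thr$MT

  K <- max(1L, as.integer(floor(max_thickness / min(image$spacing))))
  ring1 <- dilate6(blood) & !blood
  wall <- ring1
  cur <- dilate6(blood)
  for (k in seq_len(K)) {
    wall <- wall | (cur & viable)
    if (k < K) cur <- dilate6(cur)
  }
  wall <- wall & !blood
  if (cap_mode == "euclidean") {
    widx <- mask_indices(wall)
    bidx <- mask_indices(blood)
    wp <- sweep(widx - 1, 2, image$spacing, `*`)
    bp <- sweep(bidx - 1, 2, image$spacing, `*`)
    keep <- .nn_min_dist(wp, bp) <= max_thickness
    wall[widx[!keep, , drop = FALSE]] <- FALSE
    wall <- wall | ring1
  }
  lab <- array(0L, dim(a))
  tg <- segmentation_tags()
  lab[blood] <- tg[["blood_pool"]]
  lab[wall] <- tg[["aw"]]
  seg <- tagged_segmentation(lab, image$spacing, image$origin)
  attr(seg, "seed_index") <- seed_idx
  seg
}

# Circumcircle of 3 non-collinear points in 3-D: center, radius, unit normal.
circumcircle3 <- function(p) {
  p <- matrix(as.numeric(p), ncol = 3)
  a <- p[1, ]; b <- p[2, ]; c <- p[3, ]
  n <- cross3(b - a, c - a)
  n2 <- sum(n^2)
  if (sqrt(n2) <= 1e-9 * max(vec_norm(b - a), vec_norm(c - a), 1e-12))
    stopf("circumcircle3: points are collinear")
  ab <- b - a; ac <- c - a
  # classic circumcenter formula
  center <- a + (sum(ac^2) * cross3(cross3(ab, ac), ab) +
                 sum(ab^2) * cross3(ac, cross3(ab, ac))) / (2 * n2)
  list(center = center, radius = vec_norm(center - a), normal = n / sqrt(n2))
}

#' Tag the mitral-valve and pulmonary-vein orifices
#'
#' The MV is excluded by a thin spherical shell through 3 user points on the
#' annulus (sphere = circumsphere of the circle through the points); each PV
#' by a finite cylinder whose axis is normal to the plane of its 3 points
#' through the circumcircle center.  Voxels distal to the LA (disconnected
#' from the blood-pool seed after cutting) are removed, the orifice tags
#' mv/pv are set on wall voxels inside the cutting geometries, and the
#' atrial-wall class is recomputed as wall minus orifices.
#'
#' @param seg a [tagged_segmentation()] from [build_wall()]
#' @param mv_points 3 x 3 matrix of physical points on the MV annulus
#' @param pv_points list of 3 x 3 matrices, one per vein
#' @param shell_thickness thickness of the MV spherical shell (mm)
#' @param cyl_margin PV cylinder radius as a multiple of the circumcircle
#'   radius
#' @param cyl_height PV cylinder height (mm)
#' @param seed physical blood-pool seed (mm); defaults to the seed recorded by
#'   [build_wall()]
#' @return retagged [tagged_segmentation()]
#' @export
tag_orifices <- function(seg, mv_points = NULL, pv_points = list(),
                         shell_thickness = 2, cyl_margin = 1.2,
                         cyl_height = 3, seed = NULL) {
  tg <- segmentation_tags()
  lab <- seg$labels
  d <- dim(lab)
  blood <- lab == tg[["blood_pool"]]
  wall <- lab == tg[["aw"]] | lab == tg[["mv"]] | lab == tg[["pv"]]
  idx <- mask_indices(array(TRUE, d))
  pts <- sweep(sweep(idx - 1, 2, seg$spacing, `*`), 2, seg$origin, `+`)

  shell <- array(FALSE, d); cyl <- array(FALSE, d)
  if (!is.null(mv_points)) {
    cc <- circumcircle3(mv_points)
    r <- sqrt(rowSums(sweep(pts, 2, cc$center, `-`)^2))
    shell <- array(abs(r - cc$radius) <= shell_thickness / 2, d)
  }
  for (pv in pv_points) {
    cc <- circumcircle3(pv)
    rel <- sweep(pts, 2, cc$center, `-`)
    ax <- rel %*% cc$normal
    rad2 <- rowSums(rel^2) - as.numeric(ax)^2
    cyl <- cyl | array(abs(ax) <= cyl_height / 2 &
                       rad2 <= (cyl_margin * cc$radius)^2, d)
  }
  cut <- shell | cyl

  if (is.null(seed)) {
    si <- attr(seg, "seed_index")
    if (is.null(si)) stopf("tag_orifices: no seed recorded; pass `seed`")
  } else si <- physical_to_voxel(list(spacing = seg$spacing, origin = seg$origin), matrix(seed, 1))[1, ]
  # keep the LA-side connected component of (blood + wall) minus the cuts
  domain <- (blood | wall) & !cut
  comp <- connected_component6(domain, si)

  mv_tag <- wall & shell
  pv_tag <- wall & cyl
  # orifice tags are kept only where they touch the retained component
  touch <- dilate6(comp)
  mv_tag <- mv_tag & connected_touch(mv_tag, touch)
  pv_tag <- pv_tag & connected_touch(pv_tag, touch)
  wall_keep <- (wall & comp) | mv_tag | pv_tag
  blood_keep <- blood & comp

  lab2 <- array(0L, d)
  lab2[blood_keep] <- tg[["blood_pool"]]
  lab2[wall_keep] <- tg[["aw"]]
  lab2[mv_tag] <- tg[["mv"]]
  lab2[pv_tag] <- tg[["pv"]]
  out <- tagged_segmentation(lab2, seg$spacing, seg$origin)
  attr(out, "seed_index") <- si
  out
}

# Connected sub-parts of `mask` that intersect `touch` (6-connectivity),
# realized by frontier growth from mask & touch within mask.
connected_touch <- function(mask, touch) {
  cur <- mask & touch
  if (!any(cur)) return(array(FALSE, dim(mask)))
  repeat {
    grown <- dilate6(cur) & mask
    if (sum(grown) == sum(cur)) break
    cur <- grown
  }
  cur
}

#' Constrained smoothing and isotropic resampling of a segmentation
#'
#' The binary wall (aw + mv + pv) is embedded as an approximate signed
#' Euclidean distance field; iterative neighborhood averaging (a Laplacian /
#' Taubin-style relaxation) smooths the zero level set while a hard per-voxel
#' clamp of `max_displacement_fraction` times the original voxel size bounds
#' the displacement of the surface.  The smoothed implicit volume is then
#' resampled to isotropic `target_spacing` and class tags are transferred from
#' the nearest original voxel.
#'
#' @param seg a [tagged_segmentation()]
#' @param target_spacing isotropic output voxel size (mm); must not exceed the
#'   original minimum spacing (upsampling-only contract); `NULL` skips
#'   resampling
#' @param max_displacement_fraction hard surface-displacement cap as a
#'   fraction of the original voxel size (default 0.5)
#' @param iterations smoothing iterations (default 50)
#' @param relax relaxation factor per iteration (default 0.5)
#' @return list with `seg` (resampled [tagged_segmentation()] or the original
#'   grid if `target_spacing = NULL`), `surface_points` (n x 3, smoothed
#'   zero-crossing points), `displacement` (per-point displacement, mm),
#'   `max_displacement_fraction` (max displacement / original voxel size)
#' @export
smooth_and_resample <- function(seg, target_spacing = 0.1,
                                max_displacement_fraction = 0.5,
                                iterations = 50, relax = 0.5) {
  h0 <- min(seg$spacing)
  if (!is.null(target_spacing)) {
    if (target_spacing <= 0) stopf("smooth_and_resample: target_spacing must be positive")
    if (target_spacing > h0 + 1e-12)
      stopf("smooth_and_resample: target spacing %g mm exceeds original %g mm (upsampling only)",
            target_spacing, h0)
  }
  wall <- seg_mask(seg, "mc")
  if (!any(wall)) stopf("smooth_and_resample: empty wall")
  d0 <- signed_distance(wall, seg$spacing)
  cap <- max_displacement_fraction * h0
  neighbor_mean <- function(dm) {
    acc <- array(0, dim(dm)); cnt <- array(0L, dim(dm))
    for (sp in list(c(1, 1), c(1, -1), c(2, 1), c(2, -1), c(3, 1), c(3, -1))) {
      nb <- array_shift(dm, sp[1], sp[2], NA)
      ok <- !is.na(nb)
      acc <- acc + ifelse(ok, nb, 0); cnt <- cnt + ok
    }
    acc / pmax(cnt, 1)
  }
  # Taubin-style lambda|mu relaxation: the negative pass compensates the
  # shrinkage of pure Laplacian (curvature-flow) smoothing, so smooth shapes
  # keep their volume while staircase frequencies are damped; the clamp
  # enforces the hard displacement cap regardless.
  mu <- -relax / (1 - 0.15 * relax) # pass-band ~0.15 (Taubin k_PB)
  dmat <- d0
  for (it in seq_len(iterations)) {
    dmat <- dmat + relax * (neighbor_mean(dmat) - dmat)
    dmat <- dmat + mu * (neighbor_mean(dmat) - dmat)
    dmat <- pmin(pmax(dmat, d0 - cap), d0 + cap)
  }

  sp <- surface_crossings(dmat, seg$spacing, seg$origin)
  disp <- abs(interp3(d0, seg$spacing, seg$origin, sp))

  if (!is.null(target_spacing)) {
    extent <- (dim(wall) - 1) * seg$spacing
    nd <- pmax(as.integer(floor(extent / target_spacing)) + 1L, 2L)
    gx <- seg$origin[1] + (seq_len(nd[1]) - 1) * target_spacing
    gy <- seg$origin[2] + (seq_len(nd[2]) - 1) * target_spacing
    gz <- seg$origin[3] + (seq_len(nd[3]) - 1) * target_spacing
    pts <- cbind(rep(gx, times = nd[2] * nd[3]),
                 rep(rep(gy, each = nd[1]), times = nd[3]),
                 rep(gz, each = nd[1] * nd[2]))
    dv <- interp3(dmat, seg$spacing, seg$origin, pts)
    inside <- dv < 0
    lab_new <- array(0L, nd)
    if (any(inside)) {
      # nearest original voxel supplies the class tag
      nidx <- physical_to_voxel(list(spacing = seg$spacing, origin = seg$origin),
                                pts[inside, , drop = FALSE])
      for (ax in 1:3) nidx[, ax] <- pmin(pmax(nidx[, ax], 1L), dim(wall)[ax])
      src <- seg$labels[nidx]
      tgv <- segmentation_tags()
      src[!(src %in% c(tgv[["aw"]], tgv[["mv"]], tgv[["pv"]]))] <- tgv[["aw"]]
      lab_new[inside] <- src
    }
    out_seg <- tagged_segmentation(lab_new, rep(target_spacing, 3), seg$origin)
  } else {
    out_seg <- seg
  }
  list(seg = out_seg, surface_points = sp, displacement = disp,
       max_displacement_fraction = if (length(disp)) max(disp) / h0 else 0)
}

# Zero-crossing points of a level-set array along grid edges (all 3 axes).
surface_crossings <- function(dmat, spacing, origin) {
  d <- dim(dmat)
  pts <- list()
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    idx_a <- lapply(d, seq_len); idx_b <- idx_a
    idx_a[[ax]] <- 1:(n - 1); idx_b[[ax]] <- 2:n
    va <- dmat[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE]
    vb <- dmat[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE]
    cross <- which((va < 0 & vb >= 0) | (va >= 0 & vb < 0))
    if (!length(cross)) next
    dd <- dim(va)
    ai <- arrayInd(cross, dd)
    t <- va[cross] / (va[cross] - vb[cross])
    p <- sweep(sweep(ai - 1, 2, spacing, `*`), 2, origin, `+`)
    p[, ax] <- p[, ax] + t * spacing[ax]
    pts[[length(pts) + 1L]] <- p
  }
  if (!length(pts)) matrix(numeric(), 0, 3) else do.call(rbind, pts)
}

#' Dice overlap of two binary masks
#' @param a,b logical arrays of equal dimension
#' @return Dice coefficient in \[0, 1\]
#' @export
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
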