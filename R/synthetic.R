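# Synthetic silique-like capsules, scenes and phenotype populations with
# analytically known ground truth. These stand in for scanned images and a
# multiparent mapping population so that every downstream stage (QC, trait
# recovery, evaluation, statistics) can be validated without any external
# data.

#' Parametric capsule specification
#'
#' A capsule is the set of points within distance `r(t)` of a smooth
#' centerline — a tube with rounded ends, the idealised geometry of a
#' silique. The spec carries analytic ground truth: centerline arclength
#' (the true "length" trait), maximum radius, foreground area
#' (`integral 2 r ds` plus the two half-disk caps) and the disk-stack
#' volume `integral pi r(s)^2 ds` along the centerline.
#'
#' @param centerline n x 2 matrix of (x, y) control points in continuous
#'   0-based pixel coordinates; two points give a straight capsule, more
#'   are interpolated with a natural spline.
#' @param radius scalar radius in px, or a function of normalised arclength
#'   `t` in `[0, 1]` returning the local radius; must be >= 1 everywhere.
#' @param dense_step arclength step (px) of the dense discretisation used
#'   for rasterisation and ground-truth quadrature.
#' @return object of class `capsule_spec` with the dense centerline and
#'   `truth` (length_px, digital_length_px — the expected 8-connected
#'   chain-code length of the digitised centerline —, max_radius_px,
#'   area_px2, volume_px3).
#' @export
capsule_spec <- function(centerline, radius = 5, dense_step = 0.25) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 2L || nrow(centerline) < 2L)
    stop("centerline must be an n x 2 matrix with n >= 2")
  # chord-length parameterisation, then spline (or linear) resampling
  seg <- sqrt(diff(centerline[, 1L])^2 + diff(centerline[, 2L])^2)
  u <- c(0, cumsum(seg))
  n_out <- max(32L, ceiling(u[length(u)] / dense_step) * 4L)
  uu <- seq(0, u[length(u)], length.out = n_out)
  if (nrow(centerline) == 2L) {
    x <- approx(u, centerline[, 1L], uu)$y
    y <- approx(u, centerline[, 2L], uu)$y
  } else {
    x <- spline(u, centerline[, 1L], xout = uu, method = "natural")$y
    y <- spline(u, centerline[, 2L], xout = uu, method = "natural")$y
  }
  # resample uniformly in true arclength
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate centerline of zero length")
  ss <- seq(0, L, by = dense_step)
  if (ss[length(ss)] < L) ss <- c(ss, L)
  xd <- approx(s, x, ss)$y
  yd <- approx(s, y, ss)$y
  tt <- ss / L
  r_fun <- if (is.function(radius)) radius else function(t) rep(radius, length(t))
  rd <- r_fun(tt)
  if (any(!is.finite(rd)) || any(rd < 1))
    stop("radius profile must be finite and >= 1 px everywhere")
  # chain-code (8-connected step-sum) length of the digitised centerline:
  # a straight run in direction (dx, dy) costs max + (sqrt(2)-1) * min,
  # the known orientation-dependent digital-length factor (up to +8.2%)
  dx <- abs(diff(xd)); dy <- abs(diff(yd))
  digital <- sum(pmax(dx, dy) + (sqrt(2) - 1) * pmin(dx, dy))
  truth <- list(
    length_px = L,
    digital_length_px = digital,
    max_radius_px = max(rd),
    area_px2 = trapz(ss, 2 * rd) + pi / 2 * (rd[1L]^2 + rd[length(rd)]^2),
    volume_px3 = trapz(ss, pi * rd^2))
  structure(list(centerline = centerline, radius = radius,
                 dense = data.frame(x = xd, y = yd, s = ss, t = tt, r = rd),
                 dense_step = dense_step, truth = truth),
            class = "capsule_spec")
}

#' Rasterise a capsule specification
#'
#' A pixel is foreground iff its centre lies within the local radius of the
#' centerline, which keeps the analytic area/volume truths well defined.
#' Rasterisation is deterministic given the spec.
#'
#' @param spec [capsule_spec()].
#' @param instance_id,image_id,score passed to [instance_mask()].
#' @param canvas optional `c(h, w)` canvas; by default a tight canvas with a
#'   3-px background margin. The centerline is translated accordingly.
#' @param offset optional `c(x0, y0)` translation applied to the centerline
#'   before rasterising into `canvas`.
#' @return list with `instance` ([instance_mask()]) and `truth` (px-unit
#'   ground-truth traits from the spec).
#' @export
generate_capsule <- function(spec, instance_id = "capsule", image_id = "synthetic",
                             score = 1.0, canvas = NULL, offset = NULL) {
  stopifnot(inherits(spec, "capsule_spec"))
  d <- spec$dense
  margin <- ceiling(spec$truth$max_radius_px) + 3
  # integer translation only: sub-pixel placement of the spec is preserved
  if (is.null(offset))
    offset <- c(margin - floor(min(d$x)), margin - floor(min(d$y)))
  xs <- d$x + offset[1L]
  ys <- d$y + offset[2L]
  if (is.null(canvas)) {
    canvas <- c(ceiling(max(ys) + margin) + 1L, ceiling(max(xs) + margin) + 1L)
  }
  h <- canvas[1L]; w <- canvas[2L]
  if (any(xs - d$r < 0) || any(ys - d$r < 0) ||
      any(xs + d$r > w - 1L) || any(ys + d$r > h - 1L))
    stop("capsule does not fit in the canvas")
  fg <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(d))) {
    ri <- d$r[i]
    cols <- max(0L, floor(xs[i] - ri)):min(w - 1L, ceiling(xs[i] + ri))
    rows <- max(0L, floor(ys[i] - ri)):min(h - 1L, ceiling(ys[i] + ri))
    blk <- outer((rows - ys[i])^2, (cols - xs[i])^2, "+") <= ri^2
    fg[rows + 1L, cols + 1L] <- fg[rows + 1L, cols + 1L] | blk
  }
  mask <- matrix(as.integer(fg), h, w)
  if (component_count(mask) != 1L)
    stop("rasterised capsule is not a single connected component")
  list(instance = instance_mask(mask, instance_id = instance_id,
                                image_id = image_id, score = score),
       truth = spec$truth)
}

#' Draw a random capsule specification
#'
#' Samples a capsule with random length, radius, orientation, gentle
#' curvature and sub-pixel placement from the current RNG stream (seed the
#' RNG, or wrap in a seeded context, for reproducibility). Random sub-pixel
#' offsets make rasterised pixel counts unbiased for the analytic area.
#'
#' @param length_range centerline arclength range, px.
#' @param radius_range base radius range, px.
#' @param curvature_max maximum perpendicular sag as a fraction of length.
#' @param profile `"constant"` radius, or `"bulged"` (radius peaking
#'   mid-organ at the base value, tapering to 70% at the tips).
#' @return [capsule_spec()].
#' @export
random_capsule_spec <- function(length_range = c(60, 180),
                                radius_range = c(4, 9),
                                curvature_max = 0.06,
                                profile = c("constant", "bulged")) {
  profile <- match.arg(profile)
  L <- runif(1L, length_range[1L], length_range[2L])
  r0 <- runif(1L, radius_range[1L], radius_range[2L])
  theta <- runif(1L, 0, pi)
  sag <- runif(1L, 0, curvature_max) * L
  tt <- seq(0, 1, length.out = 7L)
  bx <- tt * L
  by <- sag * 4 * tt * (1 - tt)
  rot <- cbind(bx * cos(theta) - by * sin(theta),
               bx * sin(theta) + by * cos(theta))
  rot <- sweep(rot, 2L, runif(2L), "+") # sub-pixel jitter
  radius <- if (profile == "constant") r0 else {
    force(r0); function(t) r0 * (1 - 0.3 * (2 * t - 1)^2)
  }
  capsule_spec(rot, radius = radius)
}

#' Generate a scene of capsules with optional overlaps
#'
#' Places `n_siliques` random capsules on one canvas. A requested fraction
#' of instances are placed in overlapping pairs (amodal ground truth: the
#' shared pixels belong to both instances); all other placements are
#' pairwise disjoint. Placement retries are bounded; an over-full canvas
#' raises an error.
#'
#' @param n_siliques number of instances.
#' @param overlap_fraction fraction of instances belonging to an
#'   overlapping pair (`round(overlap_fraction * n / 2)` pairs).
#' @param image_size canvas `c(h, w)` in px.
#' @param seed optional integer seed (local to this call).
#' @param image_id image identifier stamped on all instances.
#' @param length_range,radius_range passed to [random_capsule_spec()].
#' @param max_tries placement retries per instance before giving up.
#' @return list with `instances` (ground truth, scores 1), `truths`
#'   (per-instance px ground truth) and `image_size`.
#' @export
generate_scene <- function(n_siliques, overlap_fraction = 0,
                           image_size = c(320, 420), seed = NULL,
                           image_id = "scene",
                           length_range = c(50, 110),
                           radius_range = c(3.5, 7),
                           max_tries = 400L) {
  stopifnot(n_siliques >= 1L, overlap_fraction >= 0, overlap_fraction <= 1)
  with_seed(seed, {
    h <- image_size[1L]; w <- image_size[2L]
    n_pairs <- round(overlap_fraction * n_siliques / 2)
    pair_partner <- rep(NA_integer_, n_siliques)
    if (n_pairs > 0L) {
      for (p in seq_len(n_pairs)) {
        pair_partner[2L * p] <- 2L * p - 1L
      }
    }
    occupied <- matrix(0L, h, w) # union of non-partner masks
    instances <- vector("list", n_siliques)
    truths <- vector("list", n_siliques)
    masks <- vector("list", n_siliques)
    for (i in seq_len(n_siliques)) {
      partner <- pair_partner[i]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        spec <- random_capsule_spec(length_range = length_range,
                                    radius_range = radius_range)
        d <- spec$dense
        margin <- ceiling(spec$truth$max_radius_px) + 2
        span_x <- diff(range(d$x)); span_y <- diff(range(d$y))
        if (span_x + 2 * margin >= w || span_y + 2 * margin >= h) next
        x0 <- runif(1L, margin - min(d$x), (w - 1 - margin) - max(d$x))
        y0 <- runif(1L, margin - min(d$y), (h - 1 - margin) - max(d$y))
        cap <- tryCatch(
          generate_capsule(spec, instance_id = sprintf("gt_%03d", i),
                           image_id = image_id, canvas = c(h, w),
                           offset = c(x0, y0)),
          error = function(e) NULL)
        if (is.null(cap)) next
        m <- cap$instance$mask
        clash <- occupied * m
        if (!is.na(partner)) {
          pm <- masks[[partner]]
          inter <- sum(pm * m)
          others <- sum(clash) - inter
          if (inter < 1L || others > 0L) next
        } else {
          if (sum(clash) > 0L) next
        }
        instances[[i]] <- cap$instance
        truths[[i]] <- cap$truth
        masks[[i]] <- m
        # partners-to-be may overlap this instance; others may not
        occupied <- pmax(occupied, m)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place instance ", i, " in a ", h, "x", w,
             " canvas after ", max_tries, " tries")
    }
    list(instances = instances, truths = truths, image_size = image_size)
  })
}

#' Perturb ground-truth instances into synthetic "predictions"
#'
#' Each perturbation has a computable effect on the IoU with its source
#' instance, making expected evaluation outcomes constructible: `identity`
#' gives IoU 1, `erode`/`dilate` scale the area, `shift` translates the
#' mask.
#'
#' @param instances list of [instance_mask()].
#' @param op perturbation applied to every mask.
#' @param px structuring-element radius for erode/dilate.
#' @param dx,dy translation in px (x right, y down) for `shift`.
#' @param scores confidence scores, recycled (default 1).
#' @return list of perturbed [instance_mask()] with scores attached.
#' @export
perturb_instances <- function(instances,
                              op = c("identity", "erode", "dilate", "shift"),
                              px = 1L, dx = 0L, dy = 0L, scores = 1.0) {
  op <- match.arg(op)
  scores <- rep_len(scores, length(instances))
  kern <- if (op %in% c("erode", "dilate"))
    EBImage::makeBrush(2L * px + 1L, shape = "disc") else NULL
  out <- vector("list", length(instances))
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    m <- inst$mask
    m2 <- switch(op,
                 identity = m,
                 erode = as_binary_matrix(EBImage::erode(m, kern)),
                 dilate = as_binary_matrix(EBImage::dilate(m, kern)),
                 shift = shift_mat(m, dy, dx))
    if (!any(m2 == 1L))
      stop("perturbation erased instance ", inst$instance_id)
    out[[i]] <- instance_mask(m2, instance_id = paste0(inst$instance_id, "_pred"),
                              image_id = inst$image_id, score = scores[i],
                              category = inst$category)
  }
  out
}

#' Generate a mask guaranteed (or constructed) to fail quality control
#'
#' * `multi_component`: two disjoint capsules stored in one mask — exactly
#'   two 8-connected components.
#' * `spurred`: a straight tube with a one-pixel-wide stub attached at
#'   mid-organ, calibrated so the skeletal side branch has `spur_px` pixels
#'   (the stub protrudes `spur_px - radius` px past the tube wall and the
#'   branch runs on to the centerline).
#' * `fused_pair`: two capsules crossing — a single component whose
#'   skeleton retains branch points, emulating one mask covering two
#'   touching siliques.
#'
#' @param kind aberration type.
#' @param spur_px target skeletal spur length in px (`spurred` only); must
#'   exceed `radius`.
#' @param radius tube radius in px.
#' @param length tube length in px.
#' @return [instance_mask()].
#' @export
generate_aberrant <- function(kind = c("multi_component", "spurred", "fused_pair"),
                              spur_px = 8L, radius = 3L, length = 80L) {
  kind <- match.arg(kind)
  if (kind == "multi_component") {
    margin <- radius + 3L
    h <- 2L * (2L * radius + 2L * margin)
    w <- length + 2L * margin
    mask <- matrix(0L, h, w)
    for (yc in c(margin + radius, h - margin - radius - 1L)) {
      sp <- capsule_spec(rbind(c(margin, yc), c(margin + length - 1L, yc)),
                         radius = radius)
      cap <- generate_capsule(sp, canvas = c(h, w), offset = c(0, 0))
      mask <- pmax(mask, cap$instance$mask)
    }
    if (max(label_components(mask)) != 2L)
      stop("multi_component construction failed")
    return(instance_mask(mask, instance_id = "aberrant_multi",
                         image_id = "synthetic"))
  }
  if (kind == "spurred") {
    if (spur_px < radius)
      stop("spur_px must be at least radius: the skeletal branch runs from ",
           "the stub tip to the tube's spinal line")
    margin <- radius + spur_px + 4L
    h <- 2L * radius + 2L * margin
    w <- length + 2L * margin
    yc <- margin + radius          # integer centerline row (0-based y)
    sp <- capsule_spec(rbind(c(margin, yc), c(margin + length - 1L, yc)),
                       radius = radius)
    cap <- generate_capsule(sp, canvas = c(h, w), offset = c(0, 0))
    mask <- cap$instance$mask
    x0 <- margin + length %/% 2L   # stub column, mid-organ
    # one-pixel-wide stub; the extra pixel compensates for the junction
    # pixel that the degree rule counts as the branch point
    stub_rows <- (yc - spur_px - 1L):(yc) + 1L  # 1-based rows, tip to spine
    mask[stub_rows, x0 + 1L] <- 1L
    return(instance_mask(mask, instance_id = "aberrant_spur",
                         image_id = "synthetic"))
  }
  # fused_pair: X-crossing of two tubes
  margin <- radius + 4L
  half <- length / 2
  ang <- 25 * pi / 180
  cx <- half + margin; cy <- half * sin(ang) + margin + radius
  mk <- function(theta) {
    pts <- rbind(c(cx - half * cos(theta), cy - half * sin(theta)),
                 c(cx + half * cos(theta), cy + half * sin(theta)))
    pts
  }
  h <- ceiling(2 * (half * sin(ang) + margin + radius)) + 2L
  w <- ceiling(2 * (half + margin)) + 2L
  mask <- matrix(0L, h, w)
  for (th in c(ang, -ang)) {
    sp <- capsule_spec(mk(th), radius = radius)
    cap <- generate_capsule(sp, canvas = c(h, w), offset = c(0, 0))
    mask <- pmax(mask, cap$instance$mask)
  }
  instance_mask(mask, instance_id = "aberrant_fused", image_id = "synthetic")
}

#' Simulate a line-by-treatment phenotype population
#'
#' Draws trait values from the additive model
#' `value = mu + line_effect + treatment_effect * [group] + residual`,
#' with `line_effect ~ N(0, line_sd^2)` and `residual ~ N(0, resid_sd^2)`.
#' The defaults emulate the structure of the source experiment: 485
#' recombinant inbred lines, two social-environment treatments (plants
#' grown in isolation vs. groups), three replicates per line and
#' treatment, and a trait scale resembling silique length in mm (mean 12).
#' Expected broad-sense heritability within a treatment is
#' `line_sd^2 / (line_sd^2 + resid_sd^2)` (0.39 at the defaults).
#'
#' @param n_lines number of genotype lines (>= 2).
#' @param reps_per_line replicates per line within each treatment.
#' @param treatment_effect additive mean shift of the `group` treatment.
#' @param line_sd between-line standard deviation.
#' @param resid_sd within-line residual standard deviation.
#' @param mu grand mean of the `isolation` treatment.
#' @param seed optional integer seed (local to this call).
#' @return data.frame with columns `line`, `treatment`, `replicate`,
#'   `value`.
#' @export
generate_phenotype_population <- function(n_lines = 485L, reps_per_line = 3L,
                                          treatment_effect = 0.6,
                                          line_sd = 0.8, resid_sd = 1.0,
                                          mu = 12, seed = NULL) {
  stopifnot(n_lines >= 2L, reps_per_line >= 1L, line_sd >= 0, resid_sd >= 0)
  with_seed(seed, {
    lines <- sprintf("L%04d", seq_len(n_lines))
    line_eff <- rnorm(n_lines, 0, line_sd)
    df <- expand.grid(replicate = seq_len(reps_per_line),
                      treatment = c("isolation", "group"),
                      line = lines, stringsAsFactors = FALSE)
    df <- df[, c("line", "treatment", "replicate")]
    df$value <- mu + line_eff[match(df$line, lines)] +
      treatment_effect * (df$treatment == "group") +
      rnorm(nrow(df), 0, resid_sd)
    rownames(df) <- NULL
    df
  })
}

#' Deterministic synthetic manifest mirroring the study's sample arithmetic
#'
#' Builds a 2,801-sample manifest over 485 genotypes (376 genotypes with 6
#' replicate samples, 109 with 5), two treatments and three batches, with a
#' flag list of 123 genotypes (87 six-replicate and 36 five-replicate)
#' whose removal drops exactly 702 samples and leaves 2,099 across 362
#' genotypes. This is a synthetic reconstruction of the bookkeeping, not
#' real sample metadata.
#'
#' @return list with `manifest` (data.frame) and `flagged_genotypes`
#'   (character vector).
#' @export
synthetic_study_manifest <- function() {
  reps <- c(rep(6L, 376L), rep(5L, 109L))
  genotypes <- sprintf("G%03d", seq_len(485L))
  n <- sum(reps)
  g <- rep(genotypes, reps)
  within_idx <- sequence(reps)
  manifest <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    genotype = g,
    treatment = ifelse(within_idx %% 2L == 1L, "isolation", "group"),
    batch = ((within_idx - 1L) %% 3L) + 1L,
    dpi = 300,
    stringsAsFactors = FALSE)
  manifest$images <- manifest$sample_id
  manifest$excluded <- FALSE
  manifest$exclusion_reason <- ""
  flagged <- c(genotypes[seq_len(87L)], genotypes[376L + seq_len(36L)])
  list(manifest = manifest, flagged_genotypes = flagged)
}
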