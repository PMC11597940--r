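# Synthetic fundus-ROI generator.
#
# Generates seeded datasets of fundus-like ROI images with nested optic
# disc / optic cup ellipse masks. The two classes differ in cup-to-disc
# morphology (glaucoma: enlarged cup, per-axis CDR drawn from a higher
# range) and in imaging style (per-channel color gain, contrast and
# texture shifts). Curvilinear vessel clutter is drawn as random
# quadratic Bezier strokes. The generator stands in for clinical
# datasets so that the whole training and evaluation pipeline can be
# exercised deterministically at desk scale.

#' Style parameters of a synthetic sample
#'
#' @param rgb_gain Per-channel multiplicative gain (length 3, > 0).
#' @param background_base Mean background color (length 3, in `[0,1]`).
#' @param vessel_count Number of vessel strokes.
#' @param vessel_contrast Opacity of vessel strokes in `[0,1]`.
#' @param texture_sigma Gaussian pixel-noise standard deviation
#'   (intensity units on the `[0,1]` scale, `>= 0`).
#' @param blur_sigma Gaussian blur of region boundaries (pixels).
#' @param global_contrast Global contrast multiplier (> 0).
#' @return An object of class `style_params`.
#' @export
style_params <- function(rgb_gain = c(1, 1, 1),
                         background_base = c(0.55, 0.30, 0.15),
                         vessel_count = 6L, vessel_contrast = 0.45,
                         texture_sigma = 0.02, blur_sigma = 1.2,
                         global_contrast = 1.0) {
  if (any(rgb_gain <= 0) || global_contrast <= 0 || vessel_contrast < 0)
    stop("gains and contrasts must be strictly positive")
  if (texture_sigma < 0) stop("texture_sigma must be >= 0")
  structure(list(rgb_gain = rgb_gain, background_base = background_base,
                 vessel_count = as.integer(vessel_count),
                 vessel_contrast = vessel_contrast,
                 texture_sigma = texture_sigma, blur_sigma = blur_sigma,
                 global_contrast = global_contrast),
            class = "style_params")
}

# Shipped glaucoma style shift: warmer red cast, dimmer green/blue and
# lower global contrast than the normal class. The gains are set so the
# per-channel shift dominates the within-class spread (the enlarged cup
# itself brightens all channels, which partially offsets a gain cut).
glaucoma_style <- function(base = style_params()) {
  base$rgb_gain <- base$rgb_gain * c(1.18, 0.75, 0.50)
  base$global_contrast <- base$global_contrast * 0.85
  base$texture_sigma <- base$texture_sigma + 0.01
  base
}

#' Synthetic dataset configuration
#'
#' @param image_size Side length of square ROI images (pixels).
#' @param n_normal,n_glaucoma,n_validation Sample counts for the
#'   source (normal), target (glaucoma) and validation (glaucoma)
#'   splits.
#' @param cdr_range_normal,cdr_range_glaucoma Per-axis cup-to-disc
#'   ratio ranges `(lo, hi)`, `0 < lo < hi < 1`. The shipped defaults
#'   are disjoint so a CDR threshold separates the classes.
#' @param cup_jitter Cup-center displacement bound as a fraction of the
#'   disc radius.
#' @param style_normal,style_glaucoma Per-class [style_params()].
#' @param seed Master seed; one named RNG stream is derived per split.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(image_size = 256L, n_normal = 10L,
                         n_glaucoma = 6L, n_validation = 0L,
                         cdr_range_normal = c(0.3, 0.5),
                         cdr_range_glaucoma = c(0.6, 0.85),
                         cup_jitter = 0.15,
                         style_normal = style_params(),
                         style_glaucoma = glaucoma_style(),
                         seed = 1L) {
  for (rg in list(cdr_range_normal, cdr_range_glaucoma))
    if (!(rg[1] > 0 && rg[1] < rg[2] && rg[2] < 1))
      stop("CDR ranges must satisfy 0 < lo < hi < 1")
  structure(list(image_size = as.integer(image_size),
                 n_normal = as.integer(n_normal),
                 n_glaucoma = as.integer(n_glaucoma),
                 n_validation = as.integer(n_validation),
                 cdr_range_normal = cdr_range_normal,
                 cdr_range_glaucoma = cdr_range_glaucoma,
                 cup_jitter = cup_jitter,
                 style_normal = style_normal,
                 style_glaucoma = style_glaucoma,
                 seed = as.integer(seed)),
            class = "synth_config")
}

derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 10007 + h * 2654435) %% 2147483647)
}

ellipse_mask <- function(size, center, radii, rotation) {
  r <- matrix(rep(0:(size - 1L), each = size), size, size, byrow = TRUE)
  c_ <- matrix(rep(0:(size - 1L), times = size), size, size, byrow = TRUE)
  th <- rotation * pi / 180
  dy <- r - center[1]; dx <- c_ - center[2]
  xr <- cos(th) * dx + sin(th) * dy
  yr <- -sin(th) * dx + cos(th) * dy
  ((xr / radii[2])^2 + (yr / radii[1])^2 <= 1) * 1L
}

#' Sample a disc/cup geometry
#'
#' Cup radii are the disc radii scaled by per-axis ratios drawn from the
#' class's CDR range; the cup center is jittered within
#' `cup_jitter * disc radius` and redrawn until the rendered cup mask is
#' contained in the disc mask.
#'
#' @param class_label `"normal"` or `"glaucoma"`.
#' @param config A [synth_config()].
#' @param seed Optional integer; if given, seeds the RNG locally.
#' @return A list of class `disc_cup_geometry`.
#' @export
sample_geometry <- function(class_label, config, seed = NULL) {
  if (!class_label %in% c("normal", "glaucoma"))
    stop("class_label must be 'normal' or 'glaucoma'")
  if (!is.null(seed)) set.seed(seed)
  sz <- config$image_size
  rg <- if (class_label == "glaucoma") config$cdr_range_glaucoma
        else config$cdr_range_normal
  for (try in 1:50) {
    disc_rv <- stats::runif(1, 0.50, 0.62) * sz / 2
    disc_rh <- disc_rv * stats::runif(1, 0.88, 1.05)
    center <- sz / 2 + stats::runif(2, -0.04, 0.04) * sz
    rot <- stats::runif(1, -15, 15)
    margin <- 1
    fits <- center[1] - disc_rv >= margin && center[1] + disc_rv <= sz - margin &&
            center[2] - disc_rh >= margin && center[2] + disc_rh <= sz - margin
    if (!fits) next
    ratio_v <- stats::runif(1, rg[1], rg[2])
    ratio_h <- stats::runif(1, rg[1], rg[2])
    cup_rv <- disc_rv * ratio_v
    cup_rh <- disc_rh * ratio_h
    for (jt in 1:30) {
      jit <- stats::runif(2, -1, 1) * config$cup_jitter * c(disc_rv, disc_rh)
      cup_center <- center + jit
      geom <- structure(list(disc_center = center,
                             disc_radii = c(disc_rv, disc_rh),
                             cup_center = cup_center,
                             cup_radii = c(cup_rv, cup_rh),
                             rotation = rot),
                        class = "disc_cup_geometry")
      od <- ellipse_mask(sz, geom$disc_center, geom$disc_radii, rot)
      oc <- ellipse_mask(sz, geom$cup_center, geom$cup_radii, rot)
      if (all(od[oc == 1L] == 1L) && sum(oc) > 0) return(geom)
    }
  }
  stop("could not sample a geometry fitting the canvas")
}

bezier_stroke <- function(size) {
  side <- sample.int(4L, 1L)
  edge_pt <- function(s) switch(s,
    c(0, stats::runif(1, 0, size - 1)),
    c(size - 1, stats::runif(1, 0, size - 1)),
    c(stats::runif(1, 0, size - 1), 0),
    c(stats::runif(1, 0, size - 1), size - 1))
  p0 <- edge_pt(side)
  p2 <- stats::runif(2, 0.1, 0.9) * (size - 1)
  p1 <- stats::runif(2, 0, 1) * (size - 1)
  t <- seq(0, 1, length.out = 6L * size)
  pts <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  mask <- matrix(0, size, size)
  rr <- round(pts[, 1]) + 1L; cc <- round(pts[, 2]) + 1L
  for (d in list(c(0L, 0L), c(0L, 1L), c(1L, 0L))) {
    r2 <- pmin(pmax(rr + d[1], 1L), size)
    c2 <- pmin(pmax(cc + d[2], 1L), size)
    mask[cbind(r2, c2)] <- 1
  }
  mask
}

#' Render one synthetic sample
#'
#' @param geometry A [sample_geometry()] result.
#' @param style A [style_params()].
#' @param class_label `"normal"` or `"glaucoma"`.
#' @param config A [synth_config()].
#' @param sample_id Identifier string stored in the sample.
#' @param seed Optional integer; if given, seeds the RNG locally.
#' @return A list of class `synthetic_sample` with `image`
#'   (`H x W x 3` integer array, 0-255), binary `od_mask` and `oc_mask`
#'   matrices, `domain_label` (0 = normal, 1 = glaucoma),
#'   `has_pixel_annotation` and `sample_id`.
#' @export
render_sample <- function(geometry, style, class_label, config,
                          sample_id = "s", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sz <- config$image_size
  od <- ellipse_mask(sz, geometry$disc_center, geometry$disc_radii,
                     geometry$rotation)
  oc <- ellipse_mask(sz, geometry$cup_center, geometry$cup_radii,
                     geometry$rotation)
  if (any(oc == 1L & od == 0L)) stop("geometry violates cup-in-disc containment")
  disc_col <- c(0.88, 0.62, 0.35)
  cup_col <- c(0.97, 0.85, 0.55)
  img <- array(0, dim = c(sz, sz, 3L))
  rim <- od == 1L & oc == 0L
  for (ch in 1:3) {
    plane <- matrix(style$background_base[ch], sz, sz)
    plane[rim] <- disc_col[ch]
    plane[oc == 1L] <- cup_col[ch]
    img[, , ch] <- plane
  }
  if (style$vessel_count > 0) {
    vcol <- c(0.35, 0.12, 0.10)
    for (v in seq_len(style$vessel_count)) {
      m <- bezier_stroke(sz)
      a <- style$vessel_contrast * m
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - a) + a * vcol[ch]
    }
  }
  if (style$blur_sigma > 0) {
    for (ch in 1:3)
      img[, , ch] <- as.matrix(EBImage::gblur(img[, , ch],
                                              sigma = style$blur_sigma))
  }
  for (ch in 1:3) img[, , ch] <- img[, , ch] * style$rgb_gain[ch]
  img <- 0.5 + (img - 0.5) * style$global_contrast
  if (style$texture_sigma > 0)
    img <- img + array(stats::rnorm(length(img), 0, style$texture_sigma),
                       dim = dim(img))
  img <- round(pmin(pmax(img, 0), 1) * 255)
  storage.mode(img) <- "integer"
  structure(list(image = img, od_mask = od, oc_mask = oc,
                 domain_label = if (class_label == "glaucoma") 1L else 0L,
                 has_pixel_annotation = FALSE, sample_id = sample_id),
            class = "synthetic_sample")
}

#' Generate a synthetic dataset
#'
#' Generates the source (normal), target (glaucoma) and validation
#' (glaucoma) splits with one derived RNG stream per split, flags
#' pixel-annotation availability according to the clinical scenario
#' (1: normals annotated; 2: a glaucoma subset annotated; 3: both), and
#' optionally writes PNG images/masks plus a CSV manifest.
#'
#' @param config A [synth_config()].
#' @param scenario Annotation scenario, 1, 2 or 3.
#' @param out_dir Optional output directory for PNGs and
#'   `manifest.csv`.
#' @param overwrite Overwrite a non-empty `out_dir`.
#' @param n_glaucoma_annotated Number of target glaucoma samples flagged
#'   annotated in scenarios 2 and 3 (default: half, rounded up).
#' @return A list of class `odcseg_dataset` with `samples` (list of
#'   [render_sample()] outputs) and `manifest` (data frame with columns
#'   sample_id, image_path, mask_path, domain, split, annotated).
#' @export
generate_dataset <- function(config, scenario = 1L, out_dir = NULL,
                             overwrite = FALSE,
                             n_glaucoma_annotated = ceiling(config$n_glaucoma / 2)) {
  stopifnot(scenario %in% 1:3)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
      stop("output directory exists and is not empty; use overwrite = TRUE")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  splits <- list(source = list(n = config$n_normal, class = "normal"),
                 target = list(n = config$n_glaucoma, class = "glaucoma"),
                 validation = list(n = config$n_validation, class = "glaucoma"))
  samples <- list()
  rows <- list()
  for (split in names(splits)) {
    info <- splits[[split]]
    if (info$n < 1L) next
    set.seed(derive_seed(config$seed, split))
    style <- if (info$class == "glaucoma") config$style_glaucoma
             else config$style_normal
    for (i in seq_len(info$n)) {
      id <- sprintf("%s_%03d", split, i)
      geom <- sample_geometry(info$class, config)
      smp <- render_sample(geom, style, info$class, config, sample_id = id)
      ann <- switch(split,
        source = scenario %in% c(1L, 3L),
        target = scenario %in% c(2L, 3L) && i <= n_glaucoma_annotated,
        validation = FALSE)
      smp$has_pixel_annotation <- ann
      smp$split <- split
      ipath <- mpath <- NA_character_
      if (!is.null(out_dir)) {
        ipath <- file.path(out_dir, paste0(id, ".png"))
        mpath <- file.path(out_dir, paste0(id, "_mask.png"))
        png::writePNG(smp$image / 255, ipath)
        png::writePNG((smp$od_mask + smp$oc_mask) / 255, mpath)
      }
      samples[[id]] <- smp
      rows[[id]] <- data.frame(sample_id = id, image_path = ipath,
                               mask_path = mpath,
                               domain = info$class, split = split,
                               annotated = ann)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  structure(list(samples = samples, manifest = manifest, config = config,
                 scenario = as.integer(scenario)),
            class = "odcseg_dataset")
}

#' Read a dataset written by [generate_dataset()] back from disk
#'
#' @param dir Directory containing `manifest.csv` and the PNGs.
#' @return An `odcseg_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  samples <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- png::readPNG(row$image_path)
    img <- round(img * 255); storage.mode(img) <- "integer"
    m <- round(png::readPNG(row$mask_path) * 255)
    samples[[row$sample_id]] <- structure(
      list(image = img, od_mask = (m >= 1) * 1L, oc_mask = (m >= 2) * 1L,
           domain_label = if (row$domain == "glaucoma") 1L else 0L,
           has_pixel_annotation = as.logical(row$annotated),
           sample_id = row$sample_id, split = row$split),
      class = "synthetic_sample")
  }
  structure(list(samples = samples, manifest = manifest),
            class = "odcseg_dataset")
}
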