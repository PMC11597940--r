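# YAML run configuration: nested sections with shipped defaults,
# strict validation (unknown keys rejected), deterministic
# serialization and hashing for reproducibility manifests.

default_config <- function() {
  list(
    synth = list(image_size = 256L, n_normal = 10L, n_glaucoma = 6L,
                 n_validation = 0L,
                 cdr_range_normal = c(0.3, 0.5),
                 cdr_range_glaucoma = c(0.6, 0.85),
                 cup_jitter = 0.15, seed = 1L),
    preprocess = list(margin = 200L, clip_limit = 2.0,
                      tile_grid = c(8L, 8L), size = 256L, equalize = TRUE),
    model = list(base_width = 64L, upsample_encoding = FALSE),
    loss = list(w_e = 0.2, w_o = 0.8, w_style_phase1 = 0.05),
    train = list(scenario = 1L, epochs = 30L, batch_size = 2L,
                 lr_seg = 1e-4, lr_disc = 1e-2, betas = c(0.9, 0.99),
                 lr_gamma = 0.95, phase1_fraction = 0.8,
                 keep_seg_in_phase2 = TRUE, style_detach_target = FALSE,
                 seed = 1L),
    gscore = list(region = "mean", direction = "vertical")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key: %s", full))
    if (is.list(defaults[[key]]) && !is.list(user[[key]]))
      stop(sprintf("configuration key %s must be a section", full))
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      val <- user[[key]]
      tmpl <- defaults[[key]]
      if (is.numeric(tmpl) && !is.numeric(val))
        stop(sprintf("configuration key %s must be numeric", full))
      if (is.logical(tmpl) && !is.logical(val))
        stop(sprintf("configuration key %s must be logical", full))
      if (is.numeric(tmpl) && is.integer(tmpl)) val <- as.integer(round(val))
      defaults[[key]] <- val
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (abs(cfg$loss$w_e + cfg$loss$w_o - 1) > 1e-8)
    stop("loss.w_e and loss.w_o must sum to 1")
  if (cfg$preprocess$margin < 0) stop("preprocess.margin must be >= 0")
  if (!cfg$train$scenario %in% 1:3) stop("train.scenario must be 1, 2 or 3")
  if (cfg$train$phase1_fraction <= 0 || cfg$train$phase1_fraction > 1)
    stop("train.phase1_fraction must be in (0, 1]")
  for (nm in c("cdr_range_normal", "cdr_range_glaucoma")) {
    rg <- cfg$synth[[nm]]
    if (!(rg[1] > 0 && rg[1] < rg[2] && rg[2] < 1))
      stop(sprintf("synth.%s must satisfy 0 < lo < hi < 1", nm))
  }
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML file, fills in the shipped defaults for missing keys,
#' rejects unknown keys and validates constraints. An empty (or
#' missing) file yields all defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A nested list of class `run_config` with sections `synth`,
#'   `preprocess`, `model`, `loss`, `train` and `gscore`, plus a
#'   `hash` attribute from [config_hash()].
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- validate_config(merge_config(default_config(), user))
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# Canonical (alphabetically sorted) YAML serialization of a config.
serialize_config <- function(cfg) {
  sort_rec <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[order(names(x))]
    lapply(x, sort_rec)
  }
  yaml::as.yaml(sort_rec(unclass(cfg)), precision = 15)
}

#' Deterministic hash of a configuration
#'
#' @param cfg A `run_config`.
#' @return MD5 hex string of the canonical serialization.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(serialize_config(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Build a [train_config()] from a run configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @param scenario,seed Optional overrides.
#' @return A [train_config()].
#' @export
as_train_config <- function(cfg, scenario = NULL, seed = NULL) {
  tr <- cfg$train
  train_config(
    scenario = if (!is.null(scenario)) scenario else tr$scenario,
    epochs = tr$epochs, image_size = cfg$preprocess$size,
    base_width = cfg$model$base_width, batch_size = tr$batch_size,
    lr_seg = tr$lr_seg, lr_disc = tr$lr_disc, betas = tr$betas,
    lr_gamma = tr$lr_gamma, phase1_fraction = tr$phase1_fraction,
    w_e = cfg$loss$w_e, w_o = cfg$loss$w_o,
    w_style_phase1 = cfg$loss$w_style_phase1,
    keep_seg_in_phase2 = tr$keep_seg_in_phase2,
    style_detach_target = tr$style_detach_target,
    equalize = cfg$preprocess$equalize,
    upsample_encoding = cfg$model$upsample_encoding,
    seed = if (!is.null(seed)) seed else tr$seed)
}

#' Build a [synth_config()] from a run configuration
#'
#' @param cfg A `run_config`.
#' @param seed Optional seed override.
#' @return A [synth_config()].
#' @export
as_synth_config <- function(cfg, seed = NULL) {
  s <- cfg$synth
  synth_config(image_size = s$image_size, n_normal = s$n_normal,
               n_glaucoma = s$n_glaucoma, n_validation = s$n_validation,
               cdr_range_normal = s$cdr_range_normal,
               cdr_range_glaucoma = s$cdr_range_glaucoma,
               cup_jitter = s$cup_jitter,
               seed = if (!is.null(seed)) seed else s$seed)
}

#' Write predicted masks and overlays for a set of images
#'
#' Inference uses only the segmenter; discriminators are not involved.
#' Writes one 3-valued label PNG (0 = background, 1 = rim, 2 = cup) and
#' one contour-overlay PNG per input image, plus a small reproducibility
#' manifest.
#'
#' @param fit An `odcseg_fit`.
#' @param images Character vector of image paths, or a list of
#'   `synthetic_sample` objects.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the data frame of written files.
#' @export
predict_masks <- function(fit, images, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(images)) {
    paths <- images
    images <- lapply(paths, function(p) {
      img <- png::readPNG(p)
      if (length(dim(img)) == 3L && dim(img)[3] > 3L)
        img <- img[, , 1:3, drop = FALSE]
      list(image = img, sample_id = sub("\\.png$", "", basename(p)))
    })
  }
  preds <- stats::predict(fit, images)
  rows <- lapply(seq_along(images), function(i) {
    id <- images[[i]]$sample_id
    if (is.null(id)) id <- sprintf("image_%03d", i)
    m <- preds[[i]]$od_mask + preds[[i]]$oc_mask  # 0 / 1 / 2
    mpath <- file.path(out_dir, paste0(id, "_pred.png"))
    png::writePNG(m / 255, mpath)
    img <- images[[i]]$image
    if (max(img) > 1) img <- img / 255
    sz <- nrow(preds[[i]]$od_mask)
    if (nrow(img) != sz) img <- resize_sample(img, size = sz)$image
    ov <- img
    edge <- function(mask) {
      d <- EBImage::dilate(EBImage::Image(mask),
                           EBImage::makeBrush(3, "box"))
      (as.matrix(d) > 0) & (mask == 0)
    }
    eo <- edge(preds[[i]]$od_mask); ec <- edge(preds[[i]]$oc_mask)
    for (ch in 1:3) {
      pl <- ov[, , ch]
      pl[eo] <- c(0, 1, 0)[ch]
      pl[ec] <- c(0, 0, 1)[ch]
      ov[, , ch] <- pl
    }
    opath <- file.path(out_dir, paste0(id, "_overlay.png"))
    png::writePNG(ov, opath)
    data.frame(sample_id = id, mask_path = mpath, overlay_path = opath)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(out)
}
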