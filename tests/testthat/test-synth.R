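cfg64 <- synth_config(image_size = 64L, n_normal = 10L, n_glaucoma = 6L,
                      seed = 3L)

test_that("geometry sampling is deterministic and class-conditional", {
  g1 <- sample_geometry("glaucoma", cfg64, seed = 5L)
  g2 <- sample_geometry("glaucoma", cfg64, seed = 5L)
  expect_identical(g1, g2)
  expect_error(sample_geometry("cat", cfg64), "class_label")
  # near-unity CDR range with low eccentricity rasterizes to vCDR ~ 1
  cfg_hi <- synth_config(image_size = 64L,
                         cdr_range_normal = c(0.3, 0.5),
                         cdr_range_glaucoma = c(0.99, 0.999),
                         cup_jitter = 0.0, seed = 1L)
  for (s in 1:10) {
    g <- sample_geometry("glaucoma", cfg_hi, seed = s)
    od <- odcseg:::ellipse_mask(64L, g$disc_center, g$disc_radii, g$rotation)
    oc <- odcseg:::ellipse_mask(64L, g$cup_center, g$cup_radii, g$rotation)
    v <- extract_cdr(od, oc)$vertical
    expect_gte(v, 0.95); expect_lte(v, 1.0)
  }
})

test_that("rendered vertical CDR separates the classes under defaults", {
  set.seed(21)
  vals <- list(normal = numeric(0), glaucoma = numeric(0))
  for (cl in names(vals)) {
    for (i in 1:200) {
      g <- sample_geometry(cl, cfg64)
      od <- odcseg:::ellipse_mask(64L, g$disc_center, g$disc_radii,
                                  g$rotation)
      oc <- odcseg:::ellipse_mask(64L, g$cup_center, g$cup_radii, g$rotation)
      vals[[cl]] <- c(vals[[cl]], extract_cdr(od, oc)$vertical)
    }
  }
  expect_gt(mean(vals$glaucoma), mean(vals$normal))
})

test_that("a vertical-CDR threshold separates classes at native scale", {
  # at the shipped 256-px scale rasterization error is small relative to
  # the disjoint CDR ranges, so separation is perfect
  cfg256 <- synth_config(seed = 23L)
  set.seed(23)
  vals <- list(normal = numeric(0), glaucoma = numeric(0))
  for (cl in names(vals)) {
    for (i in 1:40) {
      g <- sample_geometry(cl, cfg256)
      od <- odcseg:::ellipse_mask(256L, g$disc_center, g$disc_radii,
                                  g$rotation)
      oc <- odcseg:::ellipse_mask(256L, g$cup_center, g$cup_radii,
                                  g$rotation)
      vals[[cl]] <- c(vals[[cl]], extract_cdr(od, oc)$vertical)
    }
  }
  expect_gt(min(vals$glaucoma), max(vals$normal))
})

test_that("rendering respects nesting and degenerates to flat regions", {
  g <- sample_geometry("normal", cfg64, seed = 9L)
  flat <- style_params(vessel_count = 0L, texture_sigma = 0,
                       blur_sigma = 0)
  s <- render_sample(g, flat, "normal", cfg64, seed = 9L)
  # piecewise-constant image: at most 3 distinct values per channel
  for (ch in 1:3) expect_lte(length(unique(as.vector(s$image[, , ch]))), 3L)
  s2 <- render_sample(g, style_params(), "normal", cfg64, seed = 9L)
  expect_true(all(s2$od_mask[s2$oc_mask == 1] == 1))
  expect_gt(sum(s2$oc_mask), 0)
  expect_equal(dim(s2$image)[1:2], dim(s2$od_mask))
})

test_that("class style shift separates per-channel intensity means", {
  cfgs <- synth_config(image_size = 64L, seed = 31L)
  set.seed(31)
  chan_means <- function(cl, style) t(sapply(1:100, function(i) {
    g <- sample_geometry(cl, cfgs)
    s <- render_sample(g, style, cl, cfgs)
    apply(s$image, 3, mean)
  }))
  mn <- chan_means("normal", cfgs$style_normal)
  mg <- chan_means("glaucoma", cfgs$style_glaucoma)
  for (ch in 1:3) {
    gap <- abs(mean(mg[, ch]) - mean(mn[, ch]))
    expect_gt(gap, 2 * max(sd(mn[, ch]), sd(mg[, ch])))
  }
})

test_that("generate_dataset builds scenario-dependent manifests", {
  ds <- generate_dataset(cfg64, scenario = 1)
  expect_equal(nrow(ds$manifest), 16L)
  expect_equal(sum(ds$manifest$annotated), 10L)
  expect_true(all(ds$manifest$domain[ds$manifest$annotated] == "normal"))
  ds2 <- generate_dataset(cfg64, scenario = 2)
  ann2 <- ds2$manifest[ds2$manifest$annotated, ]
  expect_equal(sum(ann2$domain == "normal"), 0L)
  tgt <- ds2$manifest[ds2$manifest$split == "target", ]
  expect_true(any(tgt$annotated) && any(!tgt$annotated))
  ds3 <- generate_dataset(cfg64, scenario = 3)
  expect_true(all(ds3$manifest$annotated[ds3$manifest$split == "source"]))
})

test_that("datasets are fully deterministic per (seed, config)", {
  a <- generate_dataset(cfg64, scenario = 1)
  b <- generate_dataset(cfg64, scenario = 1)
  expect_identical(lapply(a$samples, `[[`, "image"),
                   lapply(b$samples, `[[`, "image"))
  # nestedness holds for every generated sample
  for (s in a$samples) expect_true(all(s$od_mask[s$oc_mask == 1] == 1))
  # byte-identical files on re-generation with the same seed
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  unlink(c(d1, d2), recursive = TRUE)
  small <- synth_config(image_size = 64L, n_normal = 2L, n_glaucoma = 2L,
                        seed = 12L)
  generate_dataset(small, scenario = 1, out_dir = d1)
  generate_dataset(small, scenario = 1, out_dir = d2)
  f1 <- sort(list.files(d1, pattern = "mask.png$", full.names = TRUE))
  f2 <- sort(list.files(d2, pattern = "mask.png$", full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(generate_dataset(small, scenario = 1, out_dir = d1),
               "overwrite")
  # round trip through disk
  rd <- read_dataset(d1)
  expect_identical(rd$samples[[1]]$od_mask,
                   generate_dataset(small, scenario = 1)$samples[[1]]$od_mask)
})
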