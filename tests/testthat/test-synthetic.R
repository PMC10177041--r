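tax <- build_default_taxonomy()

test_that("texture models: one per class, separation floor, difficulty collapse", {
  m0 <- default_texture_models(tax, 0)
  expect_length(m0, 15)
  expect_equal(vapply(m0, `[[`, 0L, "class_id"), 0:14)
  cols <- t(vapply(m0, `[[`, numeric(3), "color_mean"))
  d <- as.matrix(dist(cols))
  diag(d) <- Inf
  expect_gte(min(d), attr(m0, "color_floor"))

  m1 <- default_texture_models(tax, 1)
  c1 <- t(vapply(m1, `[[`, numeric(3), "color_mean"))
  dd <- function(a, b) sqrt(sum((c1[a + 1, ] - c1[b + 1, ])^2))
  epi_bla <- dd(class_of(tax, "Epithelium"), class_of(tax, "Blastema"))
  str_fat <- dd(class_of(tax, "Stroma"), class_of(tax, "Fat"))
  expect_lt(epi_bla, str_fat)
})

test_that("case generation is bit-identical under a fixed seed", {
  cfg <- cohort_config(n_cases = 2, size = 64, regions_per_case = 15,
                       seed = 9)
  models <- default_texture_models(tax, 0)
  a <- generate_case(cfg, models, 2)
  b <- generate_case(cfg, models, 2)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$image$labels, b$image$labels)
  expect_identical(a$annotations, b$annotations)
})

test_that("full-coverage annotations reproduce the dense mask away from edges", {
  cfg <- cohort_config(n_cases = 1, size = 96, regions_per_case = 15,
                       coverage = 1.0, seed = 4)
  models <- default_texture_models(tax, 0)
  cs <- generate_case(cfg, models, 1)
  aset <- annotation_set(
    cs$annotations,
    data.frame(case_id = "case_001", image = NA, spacing = cfg$spacing,
               width = 96, height = 96, stringsAsFactors = FALSE))
  sparse <- rasterize(aset, "case_001", c(96, 96))
  dense <- cs$image$labels
  # interior pixels: 4-neighborhood all in the same region as the pixel
  inner <- dense[2:95, 2:95]
  same <- (dense[1:94, 2:95] == inner) & (dense[3:96, 2:95] == inner) &
    (dense[2:95, 1:94] == inner) & (dense[2:95, 3:96] == inner)
  got <- sparse[2:95, 2:95][same]
  expect_true(all(got == inner[same]))
})

test_that("region class frequencies follow the configured weights", {
  w <- rep(1, 15)
  w[4] <- 40  # heavily favour necrosis (class id 3)
  cfg <- cohort_config(n_cases = 20, size = 64, regions_per_case = 15,
                       class_weights = w, seed = 21)
  models <- default_texture_models(tax, 0)
  cls <- unlist(lapply(1:20, function(i) {
    generate_case(cfg, models, i)$region_classes
  }))
  expect_gt(mean(cls == 3L), 0.5)
})

test_that("dense mask proportions match uniform weights (chi-square)", {
  cfg <- cohort_config(n_cases = 67, size = 32, regions_per_case = 15,
                       seed = 33)
  models <- default_texture_models(tax, 0)
  cls <- unlist(lapply(seq_len(cfg$n_cases), function(i) {
    generate_case(cfg, models, i)$region_classes
  }))
  expect_gte(length(cls), 1000)
  p <- chisq.test(tabulate(cls + 1L, 15), p = rep(1 / 15, 15))$p.value
  expect_gt(p, 0.01)
})

test_that("cohort writes all artifacts and round-trips through disk", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_cases = 5, size = 64, regions_per_case = 15,
                       seed = 2)
  aset <- generate_cohort(cfg, dir, tax)
  expect_length(list.files(dir, pattern = "^case_\\d+\\.png$"), 5)
  expect_length(list.files(dir, pattern = "^case_\\d+\\.xml$"), 5)
  expect_length(list.files(dir, pattern = "_mask\\.png$"), 5)
  expect_true(file.exists(file.path(dir, "manifest.json")))

  back <- read_annotations(dir, tax)
  expect_equal(length(back$annotations), length(aset$annotations))
  expect_equal(back$cases$case_id, aset$cases$case_id)
  for (i in seq_along(aset$annotations)) {
    expect_equal(back$annotations[[i]]$case_id, aset$annotations[[i]]$case_id)
    expect_equal(back$annotations[[i]]$class_id,
                 aset$annotations[[i]]$class_id)
    expect_equal(back$annotations[[i]]$id, aset$annotations[[i]]$id)
    expect_equal(back$annotations[[i]]$vertices,
                 aset$annotations[[i]]$vertices, tolerance = 1e-9)
  }
  # dense masks round-trip exactly
  m <- read_mask_png(aset$cases$mask[1])
  expect_true(all(m %in% 0:14))
})

test_that("every class appears in a default cohort", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_cases = 3, size = 64, regions_per_case = 16,
                       seed = 6)
  aset <- generate_cohort(cfg, dir, tax)
  present <- sort(unique(vapply(aset$annotations, `[[`, 0L, "class_id")))
  masks <- lapply(aset$cases$mask, read_mask_png)
  dense_present <- sort(unique(unlist(lapply(masks, as.vector))))
  expect_setequal(dense_present, 0:14)
})

test_that("nearest-color accuracy decreases with difficulty", {
  acc <- vapply(c(0, 0.5, 1), function(d) {
    cfg <- cohort_config(n_cases = 1, size = 96, regions_per_case = 15,
                         difficulty = d, seed = 12)
    models <- default_texture_models(tax, d)
    cs <- generate_case(cfg, models, 1)
    pred <- nearest_color_classifier(cs$image$pixels, models)
    mean(pred == cs$image$labels)
  }, 0)
  expect_true(all(diff(acc) <= 0))
  expect_gt(acc[1], 0.6)
})
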