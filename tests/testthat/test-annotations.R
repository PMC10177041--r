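tax <- build_default_taxonomy()

test_that("annotation XML writes and reads back field-by-field", {
  set.seed(7)
  anns <- lapply(1:5, function(a) {
    polygon_annotation("case_a", sample(0:14, 1),
                       random_polygon(30, 30, 20), a)
  })
  path <- withr::local_tempfile(fileext = ".xml")
  write_annotation_xml(anns, tax, path)
  got <- renalseg:::read_annotation_xml(path, tax, "case_a")
  expect_equal(got$dropped, 0L)
  expect_length(got$annotations, 5)
  for (i in 1:5) {
    expect_equal(got$annotations[[i]]$class_id, anns[[i]]$class_id)
    expect_equal(got$annotations[[i]]$id, anns[[i]]$id)
    expect_equal(got$annotations[[i]]$vertices, anns[[i]]$vertices,
                 tolerance = 1e-12)
  }
})

test_that("excluded classes are dropped with a count, unknown names error", {
  xml <- paste0(
    '<ASAP_Annotations><Annotations>',
    '<Annotation Name="Annotation 1" Type="Polygon" PartOfGroup="Blastema">',
    '<Coordinates><Coordinate Order="0" X="0" Y="0"/>',
    '<Coordinate Order="1" X="10" Y="0"/>',
    '<Coordinate Order="2" X="0" Y="10"/></Coordinates></Annotation>',
    '<Annotation Name="Annotation 2" Type="Polygon" PartOfGroup="Stroma">',
    '<Coordinates><Coordinate Order="0" X="0" Y="0"/>',
    '<Coordinate Order="1" X="10" Y="0"/>',
    '<Coordinate Order="2" X="0" Y="10"/></Coordinates></Annotation>',
    '<Annotation Name="Annotation 3" Type="Polygon" PartOfGroup="Anaplasia">',
    '<Coordinates><Coordinate Order="0" X="0" Y="0"/>',
    '<Coordinate Order="1" X="10" Y="0"/>',
    '<Coordinate Order="2" X="0" Y="10"/></Coordinates></Annotation>',
    '</Annotations></ASAP_Annotations>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  expect_message(aset <- read_annotations(path, tax), "1 annotation")
  expect_length(aset$annotations, 2)

  bad <- sub("Anaplasia", "Chondrocyte", xml)
  writeLines(bad, path)
  expect_error(read_annotations(path, tax), "Chondrocyte")

  writeLines("<ASAP_Annotations><oops>", path)
  expect_error(read_annotations(path, tax), "malformed")
})

test_that("empty annotation files read back without error", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_annotation_xml(list(), tax, path)
  aset <- read_annotations(path, tax)
  expect_length(aset$annotations, 0)
})

test_that("rasterization covers exact pixel areas and last polygon wins", {
  square <- function(x0, y0, x1, y1) {
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  }
  aset <- annotation_set(
    list(polygon_annotation("c", 2L, square(10, 10, 20, 20), 1L)),
    data.frame(case_id = "c", image = NA, spacing = 0.5, width = 32,
               height = 32, stringsAsFactors = FALSE))
  lab <- rasterize(aset, "c", c(32, 32))
  expect_equal(sum(lab == 2L), 100)
  expect_equal(sum(lab != unlabeled_value()), 100)

  aset2 <- annotation_set(
    list(polygon_annotation("c", 1L, square(4, 4, 12, 12), 1L),
         polygon_annotation("c", 3L, square(8, 8, 16, 16), 2L)),
    data.frame(case_id = "c", image = NA, spacing = 0.5, width = 20,
               height = 20, stringsAsFactors = FALSE))
  lab2 <- rasterize(aset2, "c", c(20, 20))
  # overlap [8,12) x [8,12) belongs to annotation id 2 (class 3)
  expect_true(all(lab2[9:12, 9:12] == 3L))
  expect_equal(sum(lab2 == 3L), 64)
  expect_equal(sum(lab2 == 1L), 64 - 16)

  expect_error(rasterize(aset2, "nope", c(20, 20)), "unknown case")
})

test_that("rasterization agrees with a per-pixel point-in-polygon oracle", {
  set.seed(101)
  for (rep in 1:30) {
    H <- sample(12:24, 1)
    W <- sample(12:24, 1)
    np <- sample(1:4, 1)
    polys <- lapply(seq_len(np), function(p) {
      random_polygon(runif(1, 0, W), runif(1, 0, H), runif(1, 3, 10))
    })
    vals <- sample(0:14, np, replace = TRUE)
    anns <- lapply(seq_len(np), function(p) {
      polygon_annotation("c", vals[p], polys[[p]], p)
    })
    aset <- annotation_set(
      anns, data.frame(case_id = "c", image = NA, spacing = 0.5, width = W,
                       height = H, stringsAsFactors = FALSE))
    got <- rasterize(aset, "c", c(H, W))
    want <- rasterize_oracle(H, W, polys, vals)
    expect_identical(unname(got), unname(want))
  }
})

test_that("rasterization is resolution-consistent up to boundary pixels", {
  set.seed(11)
  poly <- random_polygon(30, 30, 22)
  aset <- annotation_set(
    list(polygon_annotation("c", 5L, poly, 1L)),
    data.frame(case_id = "c", image = NA, spacing = 0.25, width = 64,
               height = 64, stringsAsFactors = FALSE))
  base <- rasterize(aset, "c", c(64, 64))           # at 0.25
  half <- rasterize(aset, "c", c(32, 32), 0.5)      # vertices scaled by 1/2
  # compare the coarse mask to the block-majority downsampling of the fine one
  agree <- 0
  interior <- 0
  for (i in 1:32) {
    for (j in 1:32) {
      block <- base[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
      if (length(unique(as.vector(block))) == 1) {
        interior <- interior + 1
        agree <- agree + (half[i, j] == block[1])
      }
    }
  }
  expect_gte(agree / interior, 0.99)
})

test_that("case split is exclusive, deterministic, and order-invariant", {
  aset <- make_annset(20, c(5, 9, 13))
  sp <- split_by_case(aset, c(0.7, 0.15, 0.15), seed = 1)
  expect_setequal(names(sp$assignment), aset$cases$case_id)
  expect_true(all(table(sp$assignment) >= 1))
  # exclusivity: each case in exactly one partition
  expect_equal(length(sp$assignment), 20)
  expect_true(all(sp$assignment %in% c("train", "validation", "test")))

  sp2 <- split_by_case(aset, c(0.7, 0.15, 0.15), seed = 1)
  expect_identical(sp$assignment, sp2$assignment)

  # permuting annotation order leaves the split unchanged
  aset_perm <- aset
  aset_perm$annotations <- rev(aset_perm$annotations)
  sp3 <- split_by_case(aset_perm, c(0.7, 0.15, 0.15), seed = 1)
  expect_identical(sp$assignment, sp3$assignment)

  expect_false(identical(sp$assignment,
                         split_by_case(aset, seed = 2)$assignment))
})

test_that("3 cases give one case per partition; <3 cases error", {
  aset <- make_annset(3, 4)
  sp <- split_by_case(aset, c(0.7, 0.15, 0.15), seed = 5)
  expect_setequal(unname(sp$assignment), c("train", "validation", "test"))
  expect_error(split_by_case(make_annset(2, 4)), "at least 3")
})

test_that("equal-sized cases realize 70/15/15 within one case-worth", {
  aset <- make_annset(100, 6)
  sp <- split_by_case(aset, c(0.7, 0.15, 0.15), seed = 3)
  counts <- table(sp$assignment) * 6
  total <- sum(counts)
  expect_lte(abs(counts[["train"]] / total - 0.70), 6 / total)
  expect_lte(abs(counts[["validation"]] / total - 0.15), 6 / total)
  expect_lte(abs(counts[["test"]] / total - 0.15), 6 / total)
})

test_that("split JSON round-trips", {
  aset <- make_annset(10, 3)
  sp <- split_by_case(aset, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(sp, path)
  expect_identical(read_split(path), sp$assignment)
})

test_that("image and mask PNG round-trip exactly", {
  set.seed(3)
  px <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3))
  p1 <- withr::local_tempfile(fileext = ".png")
  write_image_png(px, p1)
  expect_equal(read_image_png(p1), px, ignore_attr = TRUE)
  lab <- matrix(sample(c(0:14, 255L), 16 * 16, TRUE), 16, 16)
  p2 <- withr::local_tempfile(fileext = ".png")
  write_mask_png(lab, p2)
  expect_identical(read_mask_png(p2), lab)
})
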