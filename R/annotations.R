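#' Construct a polygon annotation
#'
#' Vertices are in pixel coordinates at the case's base resolution, 0-based,
#' with x = column and y = row. Polygons are closed implicitly (last vertex
#' connects back to the first).
#'
#' @param case_id case identifier.
#' @param class_id integer class id from the taxonomy.
#' @param vertices numeric matrix with columns x, y and at least 3 rows.
#' @param id integer annotation id; within a case, higher ids are drawn later
#'   and win on overlap.
#' @return a list of class `polygon_annotation`.
#' @export
polygon_annotation <- function(case_id, class_id, vertices, id) {
  vertices <- as.matrix(vertices)
  colnames(vertices) <- c("x", "y")
  stopifnot(nrow(vertices) >= 3, ncol(vertices) == 2)
  structure(list(case_id = as.character(case_id),
                 class_id = as.integer(class_id),
                 vertices = vertices,
                 id = as.integer(id)),
            class = "polygon_annotation")
}

#' Construct an annotation set
#'
#' @param annotations list of [polygon_annotation()] objects.
#' @param cases data.frame with columns `case_id`, `image` (path or NA),
#'   `spacing` (base microns per pixel), `width`, `height`, and optionally
#'   `mask` (path to a dense ground-truth mask, synthetic cohorts only).
#' @return a list of class `annotation_set`.
#' @export
annotation_set <- function(annotations, cases) {
  stopifnot(all(vapply(annotations, inherits, TRUE, "polygon_annotation")),
            all(c("case_id", "spacing") %in% names(cases)),
            all(cases$spacing > 0))
  ann_cases <- unique(vapply(annotations, `[[`, "", "case_id"))
  if (!all(ann_cases %in% cases$case_id)) {
    stop("annotations reference unknown case ids: ",
         paste(setdiff(ann_cases, cases$case_id), collapse = ", "))
  }
  structure(list(annotations = annotations, cases = cases),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$annotations), "polygons over",
      nrow(x$cases), "cases\n")
  invisible(x)
}

annotations_for_case <- function(annset, case_id) {
  keep <- vapply(annset$annotations, function(a) a$case_id == case_id, TRUE)
  anns <- annset$annotations[keep]
  anns[order(vapply(anns, `[[`, 0L, "id"))]
}

# ---- XML dialect ------------------------------------------------------------

#' Write one case's annotations as ASAP-style XML
#'
#' Dialect: root `ASAP_Annotations` > `Annotations` > repeated `Annotation`
#' elements with attributes `Name` ("Annotation k"), `Type` ("Polygon") and
#' `PartOfGroup` (class name), each holding `Coordinates` > `Coordinate`
#' elements with `Order`, `X`, `Y` attributes.
#'
#' @param annotations list of [polygon_annotation()] for a single case.
#' @param taxonomy a `class_taxonomy` used to map ids to names.
#' @param path output XML path.
#' @export
write_annotation_xml <- function(annotations, taxonomy, path) {
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  for (a in annotations) {
    node <- xml2::xml_add_child(
      anns, "Annotation",
      Name = paste("Annotation", a$id),
      Type = "Polygon",
      PartOfGroup = class_name(taxonomy, a$class_id)
    )
    coords <- xml2::xml_add_child(node, "Coordinates")
    for (i in seq_len(nrow(a$vertices))) {
      xml2::xml_add_child(coords, "Coordinate",
                          Order = as.character(i - 1L),
                          X = format(a$vertices[i, 1], digits = 15),
                          Y = format(a$vertices[i, 2], digits = 15))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_annotation_xml <- function(path, taxonomy, case_id) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  nodes <- xml2::xml_find_all(doc, "./Annotations/Annotation")
  anns <- list()
  dropped <- 0L
  excluded_lc <- tolower(taxonomy$excluded)
  for (node in nodes) {
    cls <- xml2::xml_attr(node, "PartOfGroup")
    if (tolower(cls) %in% excluded_lc) {
      dropped <- dropped + 1L
      next
    }
    cid <- class_of(taxonomy, cls)
    name <- xml2::xml_attr(node, "Name")
    aid <- suppressWarnings(as.integer(sub("^Annotation\\s+", "", name)))
    if (is.na(aid)) aid <- length(anns) + 1L
    coords <- xml2::xml_find_all(node, "./Coordinates/Coordinate")
    ord <- as.integer(xml2::xml_attr(coords, "Order"))
    v <- cbind(x = as.numeric(xml2::xml_attr(coords, "X")),
               y = as.numeric(xml2::xml_attr(coords, "Y")))[order(ord), ,
                                                            drop = FALSE]
    anns[[length(anns) + 1L]] <- polygon_annotation(case_id, cid, v, aid)
  }
  list(annotations = anns, dropped = dropped)
}

#' Read polygon annotations
#'
#' `path` may be a cohort directory holding a `manifest.json` (as written by
#' [generate_cohort()]) or a single annotation XML file (the case id is then
#' taken from the file name and the base spacing defaults to 0.24 micron per
#' pixel). Annotations whose class is excluded from the taxonomy are dropped
#' with a message reporting the count.
#'
#' @param path cohort directory or XML file.
#' @param taxonomy a `class_taxonomy`.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, taxonomy) {
  if (dir.exists(path)) {
    manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                    simplifyVector = TRUE)
    cases <- manifest$cases
    cases$image <- file.path(path, cases$image)
    cases$xml <- file.path(path, cases$xml)
    if (!is.null(cases$mask)) cases$mask <- file.path(path, cases$mask)
    anns <- list()
    dropped <- 0L
    for (i in seq_len(nrow(cases))) {
      got <- read_annotation_xml(cases$xml[i], taxonomy, cases$case_id[i])
      anns <- c(anns, got$annotations)
      dropped <- dropped + got$dropped
    }
  } else {
    case_id <- sub("\\.xml$", "", basename(path))
    got <- read_annotation_xml(path, taxonomy, case_id)
    anns <- got$annotations
    dropped <- got$dropped
    cases <- data.frame(case_id = case_id, image = NA_character_,
                        spacing = 0.24, width = NA_integer_,
                        height = NA_integer_, stringsAsFactors = FALSE)
  }
  if (dropped > 0) {
    message(dropped, " annotation(s) with excluded classes dropped")
  }
  annotation_set(anns, cases)
}

# ---- rasterization ----------------------------------------------------------

#' Rasterize a case's polygon annotations to a sparse label mask
#'
#' A pixel (row i, col j) takes a polygon's class when its center
#' (j + 0.5, i + 0.5) lies inside the polygon (even-odd rule); pixels covered
#' by no polygon get [unlabeled_value()]. Overlaps are resolved by the
#' highest annotation id (last drawn wins). Vertices, stored at the case's
#' base spacing, are scaled by `base spacing / spacing`.
#'
#' @param annset an [annotation_set()].
#' @param case_id which case to rasterize.
#' @param shape integer c(height, width) of the target mask.
#' @param spacing target microns per pixel (defaults to the base spacing).
#' @return integer matrix `shape[1]` x `shape[2]` of class ids / 255.
#' @export
rasterize <- function(annset, case_id, shape, spacing = NULL) {
  row <- match(case_id, annset$cases$case_id)
  if (is.na(row)) stop("unknown case id: ", case_id)
  base <- annset$cases$spacing[row]
  if (is.null(spacing)) spacing <- base
  scale <- base / spacing
  anns <- annotations_for_case(annset, case_id)
  polys <- lapply(anns, function(a) a$vertices * scale)
  vals <- vapply(anns, `[[`, 0L, "class_id")
  cpp_rasterize(as.integer(shape[1]), as.integer(shape[2]),
                polys, as.integer(vals), unlabeled_value())
}

#' Bundle pixels and labels into a labeled image
#'
#' @param pixels H x W x 3 array, integer 0-255 or double in the same range.
#' @param labels H x W integer matrix of class ids / [unlabeled_value()].
#' @param spacing microns per pixel.
#' @param case_id case identifier.
#' @return a list of class `labeled_image`.
#' @export
labeled_image <- function(pixels, labels, spacing, case_id) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            all(dim(pixels)[1:2] == dim(labels)), spacing > 0)
  structure(list(pixels = pixels, labels = labels,
                 spacing = spacing, case_id = as.character(case_id)),
            class = "labeled_image")
}

#' Load a case image and rasterized labels as a labeled image
#' @param annset an [annotation_set()] with image paths (cohort directory).
#' @param case_id which case.
#' @return a [labeled_image()] at the case's base spacing.
#' @export
load_labeled_image <- function(annset, case_id) {
  row <- match(case_id, annset$cases$case_id)
  if (is.na(row)) stop("unknown case id: ", case_id)
  pixels <- read_image_png(annset$cases$image[row])
  labels <- rasterize(annset, case_id, dim(pixels)[1:2])
  labeled_image(pixels, labels, annset$cases$spacing[row], case_id)
}

# ---- raster I/O -------------------------------------------------------------

#' Write an RGB image (0-255) as PNG
#' @param pixels H x W x 3 array with values in 0..255.
#' @param path output path.
#' @export
write_image_png <- function(pixels, path) {
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' Read an RGB PNG as an H x W x 3 array with values in 0..255
#' @param path PNG path.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an integer label mask (values 0..255) as single-channel PNG
#' @param labels H x W integer matrix.
#' @param path output path.
#' @export
write_mask_png <- function(labels, path) {
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read a label mask written by [write_mask_png()]
#' @param path PNG path.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

# ---- train/validation/test split -------------------------------------------

#' Case-exclusive train/validation/test split
#'
#' Cases (never individual annotations) are assigned to partitions so that no
#' case contributes annotations to two partitions. Cases are shuffled with
#' the seed, then assigned greedily: each case goes to the partition with the
#' largest remaining annotation deficit relative to its target fraction, so
#' realized annotation fractions match the targets as closely as case
#' granularity allows. Each partition is guaranteed at least one case.
#'
#' @param annset an [annotation_set()] with at least 3 cases.
#' @param fractions numeric length 3 (train, validation, test), summing to 1.
#' @param seed integer seed; the assignment depends only on case ids,
#'   per-case annotation counts and this seed.
#' @return a list of class `split_spec` with `fractions`, `seed`,
#'   `assignment` (named character vector case id -> partition) and
#'   `realized` (named numeric, realized annotation fractions).
#' @export
split_by_case <- function(annset, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  parts <- c("train", "validation", "test")
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  ids <- sort(annset$cases$case_id)
  if (length(ids) < 3) stop("need at least 3 cases to split, got ",
                            length(ids))
  ann_cases <- vapply(annset$annotations, `[[`, "", "case_id")
  counts <- vapply(ids, function(cid) sum(ann_cases == cid), 0)
  counts[counts == 0] <- 1  # annotation-free cases still occupy a slot
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample(length(ids))
  assigned <- numeric(3)
  names(assigned) <- parts
  assignment <- setNames(character(length(ids)), ids)
  remaining <- length(ids)
  for (i in ord) {
    empty <- parts[assigned == 0]
    if (length(empty) >= remaining) {
      p <- empty[1]
    } else {
      deficit <- fractions * sum(assigned, counts[i]) - assigned
      p <- parts[which.max(deficit)]
    }
    assignment[ids[i]] <- p
    assigned[p] <- assigned[p] + counts[i]
    remaining <- remaining - 1
  }
  structure(list(fractions = setNames(fractions, parts), seed = seed,
                 assignment = assignment,
                 realized = assigned / sum(assigned)),
            class = "split_spec")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Save a split as JSON (case id -> partition)
#' @param split a `split_spec`.
#' @param path output path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(as.list(split$assignment), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a split saved by [write_split()]
#' @param path JSON path.
#' @return named character vector case id -> partition.
#' @export
read_split <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Case ids belonging to one partition
#' @param split a `split_spec`.
#' @param partition one of "train", "validation", "test".
#' @export
split_cases <- function(split, partition) {
  names(split$assignment)[split$assignment == partition]
}
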