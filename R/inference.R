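#' Plan a tiling of an image for sliding-window inference
#'
#' Tiles of `tile_size` pixels overlap by `overlap` on each side; the tile
#' interiors (tiles minus margins, clipped to the image) exactly partition
#' the image, so every pixel is predicted by exactly one tile and stitching
#' is independent of traversal order. Images smaller than one tile get a
#' single mirror-padded tile.
#'
#' @param shape integer c(height, width).
#' @param tile_size tile side length; must be at least `2 * overlap + 1`.
#' @param overlap margin on each tile side, >= 0.
#' @return list of class `tiling_plan` with `tile_size`, `overlap`, and a
#'   data.frame `tiles` (interior bounds `y0, y1, x0, x1` and tile origin
#'   `ty0, tx0`, all 1-based inclusive).
#' @export
plan_tiles <- function(shape, tile_size, overlap = 0) {
  tile_size <- as.integer(tile_size)
  overlap <- as.integer(overlap)
  stopifnot(tile_size >= 2 * overlap + 1, overlap >= 0)
  H <- as.integer(shape[1])
  W <- as.integer(shape[2])
  step <- tile_size - 2L * overlap
  ys <- seq.int(1L, H, by = step)
  xs <- seq.int(1L, W, by = step)
  tiles <- expand.grid(y0 = ys, x0 = xs)
  tiles$y1 <- pmin(tiles$y0 + step - 1L, H)
  tiles$x1 <- pmin(tiles$x0 + step - 1L, W)
  tiles$ty0 <- tiles$y0 - overlap
  tiles$tx0 <- tiles$x0 - overlap
  structure(list(tile_size = tile_size, overlap = overlap,
                 shape = c(H, W), tiles = tiles),
            class = "tiling_plan")
}

#' Construct a probability map
#' @param values H x W x K array on the per-pixel simplex.
#' @param spacing microns per pixel.
#' @param case_id case identifier.
#' @param source one of "unet", "densenet", "ensemble", or any tag.
#' @export
probability_map <- function(values, spacing, case_id, source) {
  stopifnot(length(dim(values)) == 3)
  structure(list(values = values, spacing = spacing,
                 case_id = as.character(case_id), source = source),
            class = "probability_map")
}

#' Whole-image probability map by tiled prediction
#'
#' Each tile (mirror-padded at image borders) is pushed through the model's
#' `predict` method; each pixel's probability vector is taken from the tile
#' whose interior contains it. The model's output is checked against the
#' simplex contract (per-pixel sums within 1e-5 of 1).
#'
#' @param model an object with a `predict(model, pixels)` method returning
#'   an H x W x K probability array (e.g. a `segnet`).
#' @param pixels H x W x 3 image array.
#' @param plan a [plan_tiles()] plan for `dim(pixels)[1:2]`.
#' @param spacing microns per pixel of `pixels`.
#' @param case_id case identifier.
#' @param source tag for the resulting map.
#' @return a [probability_map()].
#' @export
predict_map <- function(model, pixels, plan, spacing = 0.5,
                        case_id = "case", source = "model") {
  H <- plan$shape[1]
  W <- plan$shape[2]
  stopifnot(all(dim(pixels)[1:2] == c(H, W)))
  ts <- plan$tile_size
  ov <- plan$overlap
  out <- NULL
  for (i in seq_len(nrow(plan$tiles))) {
    tl <- plan$tiles[i, ]
    tile_px <- crop_mirror(pixels, tl$ty0, tl$tx0, ts, ts)
    probs <- predict(model, tile_px)
    sums <- apply(probs, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-5)) {
      stop("model output violates the probability-simplex contract ",
           "(max |sum - 1| = ", max(abs(sums - 1)), ")")
    }
    if (is.null(out)) out <- array(0, c(H, W, dim(probs)[3]))
    iy <- tl$y0:tl$y1
    ix <- tl$x0:tl$x1
    out[iy, ix, ] <- probs[ov + seq_along(iy), ov + seq_along(ix), ,
                           drop = FALSE]
  }
  probability_map(out, spacing, case_id, source)
}

#' Per-pixel average of probability maps (softmax ensembling)
#'
#' The ensemble output is the arithmetic mean of the member maps at every
#' pixel and class; means of simplex vectors stay on the simplex.
#'
#' @param maps list of [probability_map()] with identical shapes and spacing.
#' @return a [probability_map()] tagged "ensemble".
#' @export
ensemble_average <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, TRUE, "probability_map")))
  d <- dim(maps[[1]]$values)
  for (m in maps) {
    if (!all(dim(m$values) == d)) stop("probability map shape mismatch")
    if (abs(m$spacing - maps[[1]]$spacing) > 1e-9) {
      stop("probability map spacing mismatch")
    }
  }
  acc <- maps[[1]]$values
  for (m in maps[-1]) acc <- acc + m$values
  probability_map(acc / length(maps), maps[[1]]$spacing,
                  maps[[1]]$case_id, "ensemble")
}

#' Decode a probability map to a label map
#'
#' Per-pixel arg-max; exact ties resolve to the lowest class id.
#'
#' @param map a [probability_map()] (or a bare H x W x K array).
#' @return H x W integer matrix of class ids.
#' @export
decode <- function(map) {
  values <- if (inherits(map, "probability_map")) map$values else map
  d <- dim(values)
  P <- matrix(values, d[1] * d[2], d[3])
  matrix(max.col(P, ties.method = "first") - 1L, d[1], d[2])
}
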