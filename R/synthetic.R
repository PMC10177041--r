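#' Cohort generator configuration
#'
#' Defaults describe the synthetic study conditions used throughout the test
#' suite: 20 cases of 256 x 256 pixels at a base spacing of 0.24 micron per
#' pixel, 18 polygonal regions per case with uniform class frequencies,
#' fully separated class appearances (difficulty 0) and 70% annotation
#' coverage (annotations are sparse, as in real slide annotation practice).
#'
#' @param n_cases number of cases.
#' @param size image side length in pixels (square images).
#' @param spacing base microns per pixel.
#' @param regions_per_case number of Voronoi regions per image.
#' @param class_weights length-15 frequency weights for region classes.
#' @param difficulty in `[0, 1]`; 0 keeps class color signatures well
#'   separated, 1 collapses the designated confusable pairs
#'   (epithelium/blastema, stroma/mesenchyme, stroma/regression).
#' @param coverage fraction of regions exported as polygon annotations.
#' @param seed integer master seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 20, size = 256, spacing = 0.24,
                          regions_per_case = 18,
                          class_weights = rep(1, 15),
                          difficulty = 0, coverage = 0.7, seed = 1L) {
  stopifnot(n_cases >= 1, size >= 32, spacing > 0,
            regions_per_case >= 15, length(class_weights) == 15,
            all(class_weights >= 0), sum(class_weights) > 0,
            difficulty >= 0, difficulty <= 1,
            coverage > 0, coverage <= 1)
  structure(list(n_cases = as.integer(n_cases), size = as.integer(size),
                 spacing = spacing,
                 regions_per_case = as.integer(regions_per_case),
                 class_weights = class_weights / sum(class_weights),
                 difficulty = difficulty, coverage = coverage,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# H&E-plausible base palette, one row per class id 0..14; chosen so the
# minimum pairwise distance exceeds the separation floor at difficulty 0.
.base_palette <- function() {
  matrix(c(120, 70, 160,   # Blastema: basophilic, dense
           230, 160, 200,  # Stroma: pale pink
           180, 100, 140,  # Epithelium
           240, 200, 170,  # Necrosis: amorphous eosinophilic
           200, 55, 55,    # Bleeding: erythrocyte red
           235, 210, 225,  # Regression: paucicellular pale
           150, 90, 200,   # Glomeruli
           210, 120, 95,   # Tubules
           248, 244, 240,  # Fat: near-white
           205, 185, 150,  # Mesenchyme / connective tissue
           170, 60, 100,   # Vessels
           230, 195, 120,  # Nerves
           90, 60, 130,    # Lymph nodes: dense basophilic
           160, 130, 185,  # Urothelium
           140, 110, 85),  # Nephrogenic rest
         ncol = 3, byrow = TRUE)
}

#' Per-class texture models
#'
#' Each class gets a visual signature: a base cytoplasm/matrix color with
#' additive Gaussian noise, plus nuclei rendered as filled ellipses with a
#' Poisson count per region (density in expected nuclei per pixel of region
#' area). `difficulty` shrinks all color means toward the grand mean and
#' additionally collapses the confusable pairs (epithelium toward blastema,
#' mesenchyme and regression toward stroma), so class separability decreases
#' monotonically.
#'
#' @param taxonomy a `class_taxonomy`.
#' @param difficulty in `[0, 1]`.
#' @return list of 15 `texture_model` lists (fields `class_id`, `color_mean`,
#'   `color_cov`, `nuc_density`, `nuc_size_mean`, `nuc_size_sd`, `nuc_color`,
#'   `anisotropy`, `noise_sd`), with attribute `color_floor` giving the
#'   guaranteed minimum pairwise color-mean distance at difficulty 0.
#' @export
default_texture_models <- function(taxonomy, difficulty = 0) {
  stopifnot(difficulty >= 0, difficulty <= 1)
  pal <- .base_palette()
  grand <- colMeans(pal)
  m <- sweep(sweep(pal, 2, grand), 1, 1 - 0.5 * difficulty, `*`)
  m <- sweep(m, 2, grand, `+`)
  # confusable pairs collapse at difficulty 1
  pull <- function(a, b, f) m[a + 1, ] + f * difficulty * (m[b + 1, ] - m[a + 1, ])
  m[3, ] <- pull(2L, 0L, 0.9)    # epithelium -> blastema
  m[10, ] <- pull(9L, 1L, 0.85)  # mesenchyme -> stroma
  m[6, ] <- pull(5L, 1L, 0.85)   # regression -> stroma
  density <- c(0.030, 0.006, 0.016, 0, 0, 0.002, 0.025, 0.012, 0.001,
               0.005, 0.008, 0.006, 0.035, 0.018, 0.020)
  size_mean <- c(2.0, 3.0, 2.6, 2.5, 2.5, 2.8, 2.0, 2.8, 2.5,
                 3.2, 2.6, 3.0, 2.0, 2.4, 2.2)
  aniso <- c(1.2, 2.5, 1.2, 1.2, 1.2, 1.5, 1.2, 1.4, 1.2,
             3.0, 1.6, 3.0, 1.2, 1.2, 1.2)
  hematoxylin <- c(60, 40, 110)
  models <- lapply(0:14, function(cid) {
    structure(list(
      class_id = cid,
      color_mean = m[cid + 1, ],
      color_cov = diag(rep(49, 3)),
      nuc_density = density[cid + 1],
      nuc_size_mean = size_mean[cid + 1],
      nuc_size_sd = 0.5,
      nuc_color = 0.75 * hematoxylin + 0.25 * m[cid + 1, ],
      anisotropy = aniso[cid + 1],
      noise_sd = 7
    ), class = "texture_model")
  })
  attr(models, "color_floor") <- 30
  models
}

# ---- Voronoi geometry -------------------------------------------------------

# Sutherland-Hodgman clip of polygon (n x 2) against half-plane a.p <= b
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  d <- poly %*% a - b
  out <- matrix(0, 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pin <- d[i] <= 0
    qin <- d[j] <= 0
    if (pin) out <- rbind(out, poly[i, ])
    if (pin != qin) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of site i clipped to [0,W] x [0,H]; sites: n x 2 (x, y)
voronoi_cell <- function(sites, i, width, height) {
  poly <- matrix(c(0, 0, width, 0, width, height, 0, height),
                 ncol = 2, byrow = TRUE)
  si <- sites[i, ]
  for (j in seq_len(nrow(sites))) {
    if (j == i) next
    sj <- sites[j, ]
    a <- sj - si
    b <- (sum(sj^2) - sum(si^2)) / 2
    poly <- clip_halfplane(poly, a, b)
    if (nrow(poly) < 3) break
  }
  # drop near-duplicate consecutive vertices
  if (nrow(poly) >= 2) {
    keep <- c(TRUE, rowSums((poly[-1, , drop = FALSE] -
                               poly[-nrow(poly), , drop = FALSE])^2) > 1e-12)
    poly <- poly[keep, , drop = FALSE]
  }
  poly
}

# ---- case generation --------------------------------------------------------

case_seed <- function(seed, case_index) {
  as.integer((as.numeric(seed) * 10007 + case_index * 7919) %% 2147483647)
}

#' Generate one synthetic annotated case
#'
#' The image is partitioned into polygonal regions by a seeded Voronoi
#' tessellation; each region is assigned a class from the configured
#' frequency weights (the first case carries a quota: its first 15 regions
#' are a permutation of all classes, so every cohort exhibits every class)
#' and rendered from its texture model. A seeded subset of regions
#' (`coverage`) is exported as polygon annotations; the dense class mask is
#' kept as evaluation ground truth. Deterministic given `(seed, case_index)`.
#'
#' @param config a [cohort_config()].
#' @param models texture models from [default_texture_models()].
#' @param case_index 1-based case number.
#' @return list with `image` (a [labeled_image()] whose labels are the dense
#'   ground-truth mask), `annotations` (list of [polygon_annotation()]), and
#'   `region_classes` (integer vector of region class ids).
#' @export
generate_case <- function(config, models, case_index) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(case_seed(config$seed, case_index))
  H <- config$size
  W <- config$size
  n <- config$regions_per_case
  case_id <- sprintf("case_%03d", case_index)

  sites <- cbind(runif(n, 0, W), runif(n, 0, H))
  cls <- sample(0:14, n, replace = TRUE, prob = config$class_weights)
  if (case_index == 1) cls[1:15] <- sample(0:14)

  polys <- lapply(seq_len(n), function(i) voronoi_cell(sites, i, W, H))
  region_mask <- cpp_rasterize(H, W, polys, seq_len(n), 0L)
  # fill the (measure-zero) pixels whose center fell exactly on a cell
  # boundary by nearest site
  holes <- which(region_mask == 0L)
  if (length(holes) > 0) {
    hy <- (holes - 1) %% H
    hx <- (holes - 1) %/% H
    for (k in seq_along(holes)) {
      d2 <- (sites[, 1] - (hx[k] + 0.5))^2 + (sites[, 2] - (hy[k] + 0.5))^2
      region_mask[holes[k]] <- which.min(d2)
    }
  }
  labels <- matrix(cls[region_mask], H, W)

  # base tissue color + per-pixel Gaussian noise
  colmat <- t(vapply(models, `[[`, numeric(3), "color_mean"))
  sds <- vapply(models, `[[`, 0, "noise_sd")
  pixels <- array(0, c(H, W, 3))
  noise_sd <- matrix(sds[labels + 1], H, W)
  for (ch in 1:3) {
    pixels[, , ch] <- matrix(colmat[labels + 1, ch], H, W) +
      rnorm(H * W, 0, noise_sd)
  }

  # nuclei: Poisson count per region, filled ellipses clipped to the region
  for (r in seq_len(n)) {
    mod <- models[[cls[r] + 1]]
    if (mod$nuc_density <= 0) next
    rpix <- which(region_mask == r)
    if (length(rpix) == 0) next
    count <- rpois(1, mod$nuc_density * length(rpix))
    if (count == 0) next
    centers <- sample(rpix, count, replace = TRUE)
    cy <- (centers - 1) %% H + runif(count, -0.5, 0.5)
    cx <- (centers - 1) %/% H + runif(count, -0.5, 0.5)
    for (q in seq_len(count)) {
      a <- max(1, rnorm(1, mod$nuc_size_mean, mod$nuc_size_sd))
      b <- max(0.8, a / mod$anisotropy)
      th <- runif(1, 0, pi)
      r_out <- ceiling(a) + 1
      ys <- max(0, floor(cy[q] - r_out)):min(H - 1, ceiling(cy[q] + r_out))
      xs <- max(0, floor(cx[q] - r_out)):min(W - 1, ceiling(cx[q] + r_out))
      dy <- rep(ys - cy[q], times = length(xs))
      dx <- rep(xs - cx[q], each = length(ys))
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      inside <- u^2 + v^2 <= 1
      if (!any(inside)) next
      idx <- (rep(xs, each = length(ys)) * H + rep(ys, times = length(xs)) +
                1)[inside]
      idx <- idx[region_mask[idx] == r]
      if (length(idx) == 0) next
      jit <- rnorm(3, 0, 4)
      for (ch in 1:3) {
        plane <- (ch - 1) * H * W
        pixels[plane + idx] <- mod$nuc_color[ch] + jit[ch]
      }
    }
  }
  pixels <- round(pmin(pmax(pixels, 0), 255))

  exported <- sort(sample(n, max(1, round(config$coverage * n))))
  annotations <- lapply(exported, function(r) {
    polygon_annotation(case_id, cls[r], polys[[r]], r)
  })
  list(image = labeled_image(pixels, labels, config$spacing, case_id),
       annotations = annotations,
       region_classes = cls)
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per case, the RGB image (PNG), the ASAP-style annotation XML, the
#' dense ground-truth mask (single-channel PNG), and a sidecar-free
#' `manifest.json` listing cases with their spacing; plus `taxonomy.json`.
#' The returned in-memory annotation set equals what [read_annotations()]
#' reads back from the directory.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @param taxonomy a `class_taxonomy` (default taxonomy if omitted).
#' @return the in-memory [annotation_set()], invisibly; its `cases` table
#'   carries `image`, `xml` and `mask` paths.
#' @export
generate_cohort <- function(config, out_dir, taxonomy = build_default_taxonomy()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- default_texture_models(taxonomy, config$difficulty)
  anns <- list()
  rows <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    cs <- generate_case(config, models, i)
    cid <- cs$image$case_id
    img_file <- paste0(cid, ".png")
    xml_file <- paste0(cid, ".xml")
    mask_file <- paste0(cid, "_mask.png")
    write_image_png(cs$image$pixels, file.path(out_dir, img_file))
    write_mask_png(cs$image$labels, file.path(out_dir, mask_file))
    write_annotation_xml(cs$annotations, taxonomy,
                         file.path(out_dir, xml_file))
    anns <- c(anns, cs$annotations)
    rows[[i]] <- data.frame(case_id = cid, image = img_file, xml = xml_file,
                            mask = mask_file, spacing = config$spacing,
                            width = config$size, height = config$size,
                            stringsAsFactors = FALSE)
  }
  cases <- do.call(rbind, rows)
  jsonlite::write_json(list(cases = cases, seed = config$seed,
                            difficulty = config$difficulty,
                            coverage = config$coverage),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_taxonomy(taxonomy, file.path(out_dir, "taxonomy.json"))
  cases$image <- file.path(out_dir, cases$image)
  cases$xml <- file.path(out_dir, cases$xml)
  cases$mask <- file.path(out_dir, cases$mask)
  invisible(annotation_set(anns, cases))
}

#' Per-pixel nearest-color-mean baseline classifier
#'
#' Labels each pixel with the class whose texture color mean is nearest in
#' RGB space. A deliberately weak reference used to characterize how
#' `difficulty` degrades class separability.
#'
#' @param pixels H x W x 3 array in 0..255.
#' @param models texture models.
#' @return H x W integer matrix of class ids.
#' @export
nearest_color_classifier <- function(pixels, models) {
  d <- dim(pixels)
  X <- matrix(pixels, d[1] * d[2], 3)
  M <- t(vapply(models, `[[`, numeric(3), "color_mean"))
  # squared distances via expansion; classes are few so this stays small
  d2 <- outer(rowSums(X^2), rep(1, nrow(M))) - 2 * X %*% t(M) +
    outer(rep(1, nrow(X)), rowSums(M^2))
  matrix(max.col(-d2, ties.method = "first") - 1L, d[1], d[2])
}
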