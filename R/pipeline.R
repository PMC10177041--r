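#' Run the full segmentation pipeline on a synthetic cohort
#'
#' End-to-end study emulation: generates a seeded synthetic cohort to disk,
#' reads the annotations back, performs the case-exclusive 70/15/15 split,
#' trains one u-net and one dense-net on patches from the training cases
#' (class-balanced sampling at 0.5 micron per pixel, full augmentation
#' stack), produces tiled whole-image probability maps for the held-out test
#' cases, ensembles the two networks by per-pixel softmax averaging, and
#' scores every source against the held-out test annotations.
#'
#' @param seed integer master seed for cohort, split, weights and sampling.
#' @param work_dir directory for the generated cohort (default: a fresh
#'   temporary directory).
#' @param cohort a [cohort_config()]; its seed is overridden by `seed`.
#' @param epochs,iterations training budget per network.
#' @param patch_unet,patch_densenet training patch shapes per family. The
#'   defaults preserve the reference recipe's relative pixel throughput:
#'   the u-net trains on larger patches at batch 4, the dense-net on
#'   smaller patches at batch 16.
#' @param tile_size,overlap inference tiling parameters.
#' @param verbose print progress.
#' @return list with `metrics` (named list of `metrics_table`s for unet,
#'   densenet, ensemble), `confusions`, `histories`, `split`, and `summary`
#'   (named numeric vector of overall/macro Dice per source).
#' @export
run_pipeline <- function(seed = 1L,
                         work_dir = tempfile("cohort_"),
                         cohort = cohort_config(),
                         epochs = 10, iterations = 50,
                         patch_unet = c(96, 96),
                         patch_densenet = c(48, 48),
                         tile_size = 64, overlap = 8,
                         verbose = FALSE) {
  taxonomy <- build_default_taxonomy()
  cohort$seed <- as.integer(seed)
  generate_cohort(cohort, work_dir, taxonomy)
  annset <- read_annotations(work_dir, taxonomy)
  split <- split_by_case(annset, c(0.70, 0.15, 0.15), seed = seed)

  load_part <- function(part) {
    lapply(split_cases(split, part), function(cid) {
      load_labeled_image(annset, cid)
    })
  }
  train_images <- load_part("train")
  val_images <- load_part("validation")

  aug <- augmenter(augment_config())

  train_one <- function(family, patch_shape, batch_size, seed_off) {
    set.seed((seed + seed_off) %% 2147483647)
    spec <- patch_spec(patch_shape, spacing = 0.5, class_balanced = TRUE)
    sampler <- patch_sampler(train_images, spec)
    val_sampler <- patch_sampler(val_images, spec)
    model <- build_network(network_spec(family, patch_shape,
                                        n_classes(taxonomy), "tiny"))
    cfg <- training_config(epochs = epochs, iterations = iterations,
                           batch_size = batch_size)
    train(model, sampler, aug, cfg, val_sampler, verbose = verbose)
  }
  if (verbose) message("training u-net ...")
  fit_u <- train_one("unet", patch_unet, 4L, 101L)
  if (verbose) message("training dense-net ...")
  fit_d <- train_one("densenet", patch_densenet, 16L, 202L)

  sources <- c("unet", "densenet", "ensemble")
  cms <- setNames(vector("list", 3), sources)
  for (cid in split_cases(split, "test")) {
    img <- load_labeled_image(annset, cid)
    at_working <- resample_labeled_image(img, 0.5)
    shape <- dim(at_working$pixels)[1:2]
    truth <- rasterize(annset, cid, shape, 0.5)
    plan <- plan_tiles(shape, tile_size, overlap)
    pm_u <- predict_map(fit_u$model, at_working$pixels, plan, 0.5, cid,
                        "unet")
    pm_d <- predict_map(fit_d$model, at_working$pixels, plan, 0.5, cid,
                        "densenet")
    maps <- list(unet = pm_u, densenet = pm_d,
                 ensemble = ensemble_average(list(pm_u, pm_d)))
    for (s in sources) {
      cm <- confusion(truth, decode(maps[[s]]), taxonomy)
      cms[[s]] <- if (is.null(cms[[s]])) cm else add_confusions(cms[[s]], cm)
    }
  }
  metrics <- lapply(cms, report, taxonomy = taxonomy)
  overall <- vapply(cms, function(cm) {
    pooled_metrics(cm, taxonomy$classes$id)[["dice"]]
  }, 0)
  macro <- vapply(cms, macro_dice, 0)
  summary <- c(setNames(overall, paste0("overall_dice_", sources)),
               setNames(macro, paste0("macro_dice_", sources)),
               n_test_pixels = sum(cms[[1]]))
  list(metrics = metrics, confusions = cms,
       histories = list(unet = fit_u$history, densenet = fit_d$history),
       split = split, summary = summary)
}
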