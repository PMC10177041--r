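#' Tissue class taxonomy for Wilms tumor segmentation
#'
#' The annotation vocabulary covers 19 tissue components; four (background,
#' anaplasia, adrenal medulla, adrenal cortex) are excluded from modeling,
#' leaving 15 evaluated classes. Classes carry a group tag (vital tumor
#' components, chemotherapy-induced changes, normal renal tissue, extra renal
#' tissue, others) and belong to exactly one of two overarching meta-labels,
#' "tumor" or "non-tumor".
#'
#' @return An object of class `class_taxonomy`: a list with elements
#'   `classes` (data.frame with `name`, `id`, `group`), `groups` (named list
#'   of integer id vectors), `overarching` (named list with `tumor` and
#'   `non_tumor` id vectors), `excluded` (character), and `aliases` (named
#'   character vector mapping alternate spellings to canonical names).
#' @examples
#' tax <- build_default_taxonomy()
#' nrow(tax$classes)          # 15
#' tax$groups[["vital tumor components"]]
#' @export
build_default_taxonomy <- function() {
  classes <- data.frame(
    name = c("Blastema", "Stroma", "Epithelium",
             "Necrosis", "Bleeding", "Regression",
             "Glomeruli", "Tubules",
             "Fat", "Mesenchyme", "Vessels", "Nerves", "Lymph nodes",
             "Urothelium", "Nephrogenic rest"),
    id = 0:14,
    group = c(rep("vital tumor components", 3),
              rep("chemotherapy-induced changes", 3),
              rep("normal renal tissue", 2),
              rep("extra renal tissue", 5),
              rep("others", 2)),
    stringsAsFactors = FALSE
  )
  groups <- lapply(split(classes$id, classes$group), as.integer)
  # meta-label partition: tumor tissue and treatment effects inside the tumor
  # bed (incl. the nephrogenic precursor lesion) vs. surrounding normal tissue
  overarching <- list(
    tumor = c(0L, 1L, 2L, 3L, 4L, 5L, 14L),
    non_tumor = c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)
  )
  aliases <- c(
    "WT-blastema" = "Blastema",
    "WT-stroma" = "Stroma",
    "WT-epithelium" = "Epithelium",
    "Nephrogenic rests" = "Nephrogenic rest",
    "Lymph node" = "Lymph nodes",
    "Connective tissue" = "Mesenchyme",
    "Glomerulus" = "Glomeruli",
    "Tubuli" = "Tubules"
  )
  structure(
    list(classes = classes,
         groups = groups,
         overarching = overarching,
         excluded = c("Background", "Anaplasia",
                      "Adrenal medulla", "Adrenal cortex"),
         aliases = aliases),
    class = "class_taxonomy"
  )
}

#' Look up the canonical class id for a name or alias
#'
#' Matching is case-insensitive and accepts registered aliases (e.g.
#' `"WT-stroma"` for `"Stroma"`). Names of excluded classes raise an error,
#' as do unknown names.
#'
#' @param taxonomy a `class_taxonomy`.
#' @param name character vector of class names or aliases.
#' @return integer vector of class ids.
#' @export
class_of <- function(taxonomy, name) {
  stopifnot(inherits(taxonomy, "class_taxonomy"))
  canon <- tolower(taxonomy$classes$name)
  al <- taxonomy$aliases
  vapply(as.character(name), function(nm) {
    key <- tolower(nm)
    hit <- match(key, canon)
    if (is.na(hit)) {
      ai <- match(key, tolower(names(al)))
      if (!is.na(ai)) hit <- match(tolower(al[[ai]]), canon)
    }
    if (is.na(hit)) {
      if (key %in% tolower(taxonomy$excluded)) {
        stop("class '", nm, "' is excluded from the taxonomy", call. = FALSE)
      }
      stop("unknown class name: '", nm, "'", call. = FALSE)
    }
    taxonomy$classes$id[hit]
  }, integer(1), USE.NAMES = FALSE)
}

#' Canonical class name for an id
#' @param taxonomy a `class_taxonomy`.
#' @param id integer class ids.
#' @return character vector of names.
#' @export
class_name <- function(taxonomy, id) {
  taxonomy$classes$name[match(id, taxonomy$classes$id)]
}

#' Number of evaluated classes
#' @param taxonomy a `class_taxonomy`.
#' @return integer count.
#' @export
n_classes <- function(taxonomy) nrow(taxonomy$classes)

#' Reserved label value for unannotated pixels
#'
#' Label masks are sparse: pixels covered by no annotation carry this value
#' and are excluded from the loss and from evaluation.
#' @return the integer 255.
#' @export
unlabeled_value <- function() 255L

#' Serialize a taxonomy to JSON
#' @param taxonomy a `class_taxonomy`.
#' @param path output file path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  obj <- list(
    classes = taxonomy$classes,
    groups = taxonomy$groups,
    overarching = taxonomy$overarching,
    excluded = taxonomy$excluded,
    aliases = as.list(taxonomy$aliases)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a taxonomy from JSON
#' @param path file written by [write_taxonomy()].
#' @return a `class_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(classes = as.data.frame(obj$classes, stringsAsFactors = FALSE),
         groups = lapply(obj$groups, as.integer),
         overarching = lapply(obj$overarching, as.integer),
         excluded = as.character(obj$excluded),
         aliases = unlist(obj$aliases)),
    class = "class_taxonomy"
  )
}

#' @export
print.class_taxonomy <- function(x, ...) {
  cat("Tissue class taxonomy:", nrow(x$classes), "evaluated classes\n")
  for (g in names(x$groups)) {
    cat("  ", g, ": ", paste(class_name(x, x$groups[[g]]), collapse = ", "),
        "\n", sep = "")
  }
  cat("  excluded: ", paste(x$excluded, collapse = ", "), "\n", sep = "")
  invisible(x)
}
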