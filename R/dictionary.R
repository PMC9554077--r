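# Template dictionary: (single-sided image, manual breast mask) pairs used as
# deformable atlases by the registration pipeline. Persisted as a directory of
# NIfTI files indexed by a JSON manifest.

MANIFEST_VERSION <- "1.0"

#' Construct a template pair
#'
#' A single-sided template image together with its binary breast mask; the
#' dictionary element of the registration pipeline. Templates must already be
#' in canonical right-sided orientation.
#'
#' @param id Unique identifier string.
#' @param image A [single_breast_volume] with `side == "right"`.
#' @param mask A [segmentation_mask] on the same grid, non-empty.
#' @param meta Named list of free-form descriptor tags (size/shape/density).
#' @return An object of class `template_pair`.
#' @export
template_pair <- function(id, image, mask, meta = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(inherits(image, "single_breast_volume"),
            inherits(mask, "segmentation_mask"))
  if (image$side != "right")
    stop("templates must be in canonical right-sided orientation")
  if (!identical(dim(image$image), dim(mask$data)))
    stop("template image and mask shapes differ")
  if (!isTRUE(all.equal(image$spacing, mask$spacing)))
    stop("template image and mask spacing differ")
  if (sum(mask$data) == 0) stop("template mask is empty")
  structure(list(id = id, image = image, mask = mask, meta = meta),
            class = "template_pair")
}

#' Construct a template dictionary
#'
#' @param pairs List of [template_pair] objects with unique ids.
#' @return An object of class `template_dictionary`.
#' @export
template_dictionary <- function(pairs = list()) {
  ids <- vapply(pairs, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate template ids")
  structure(list(pairs = pairs, manifest_version = MANIFEST_VERSION),
            class = "template_dictionary")
}

#' @export
length.template_dictionary <- function(x) length(x$pairs)

dict_ids <- function(dict) vapply(dict$pairs, function(p) p$id, character(1))

#' Retrieve a template pair by id
#'
#' @param dict A [template_dictionary].
#' @param id Template identifier.
#' @return The [template_pair].
#' @export
get_template <- function(dict, id) {
  i <- match(id, dict_ids(dict))
  if (is.na(i)) stop("no template with id '", id, "'")
  dict$pairs[[i]]
}

#' Add a template pair to a dictionary
#'
#' Supports the incremental-curation workflow: a corrected segmentation can be
#' added back to the dictionary as a new template.
#'
#' @param dict A [template_dictionary].
#' @param pair A [template_pair] whose id is not yet present.
#' @return The grown dictionary.
#' @export
add_template <- function(dict, pair) {
  stopifnot(inherits(dict, "template_dictionary"),
            inherits(pair, "template_pair"))
  if (pair$id %in% dict_ids(dict))
    stop("duplicate template id '", pair$id, "'")
  dict$pairs <- c(dict$pairs, list(pair))
  dict
}

#' Save a template dictionary to a directory
#'
#' Writes each pair's image (float32) and mask (uint8) as NIfTI plus a
#' `manifest.json` listing id, relative paths, and meta tags.
#'
#' @param dict A [template_dictionary].
#' @param path Output directory (created if needed).
#' @return Invisibly, `path`.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "template_dictionary"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(dict$pairs, function(p) {
    img_file <- paste0(p$id, "_image.nii.gz")
    mask_file <- paste0(p$id, "_mask.nii.gz")
    write_nifti(p$image$image, file.path(path, img_file),
                spacing = p$image$spacing, datatype = "float32")
    write_nifti(p$image$body_mask, file.path(path, paste0(p$id, "_body.nii.gz")),
                spacing = p$image$spacing, datatype = "uint8")
    write_mask(p$mask, file.path(path, mask_file))
    list(id = p$id, image = img_file, mask = mask_file,
         body = paste0(p$id, "_body.nii.gz"), meta = p$meta)
  })
  manifest <- list(manifest_version = dict$manifest_version,
                   pairs = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a template dictionary from a directory
#'
#' Reads and fully validates a dictionary previously written by
#' [save_dictionary].
#'
#' @param path Directory containing `manifest.json` and the NIfTI files.
#' @return A [template_dictionary].
#' @export
load_dictionary <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("corrupt dictionary: missing manifest.json")
  manifest <- tryCatch(jsonlite::read_json(mf_path),
                       error = function(e) stop("corrupt manifest: ",
                                                conditionMessage(e)))
  if (is.null(manifest$pairs)) stop("corrupt manifest: no pairs field")
  pairs <- lapply(manifest$pairs, function(e) {
    for (f in c("image", "mask", "body")) {
      fp <- file.path(path, e[[f]])
      if (!file.exists(fp))
        stop("dictionary entry '", e$id, "': missing file ", e[[f]])
    }
    img <- read_nifti(file.path(path, e$image))
    body <- read_nifti(file.path(path, e$body))
    sbv <- single_breast_volume(pmin(pmax(img$data, 0), 1), body$data,
                                side = "right", spacing = img$spacing)
    template_pair(e$id, sbv, read_mask(file.path(path, e$mask)),
                  meta = if (is.null(e$meta)) list() else e$meta)
  })
  template_dictionary(pairs)
}
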