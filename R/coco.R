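# COCO-format keypoint annotation containers and JSON I/O.
#
# Keypoints are stored internally as M x 3 matrices (x, y, v) with 0-based
# pixel coordinates, x rightward and y downward; in JSON they are the usual
# flat [x1, y1, v1, ...] list. Visibility flags: 0 = unlabeled (coordinates
# meaningless), 1 = labeled but occluded, 2 = labeled and visible.

#' Construct a single keypoint annotation
#'
#' @param image_id integer id of the image the instance appears in.
#' @param keypoints M x 3 numeric matrix of (x, y, v) rows, v in {0, 1, 2}.
#' @param bbox numeric (x, y, w, h) in pixels.
#' @param area instance area in px^2; defaults to bbox w * h.
#' @param id annotation id (unique within a set).
#' @param category_id COCO category id.
#' @return object of class `coco_annotation`.
#' @export
coco_annotation <- function(image_id, keypoints, bbox, area = NULL, id = 1L,
                            category_id = 1L) {
  keypoints <- matrix(as.numeric(keypoints), ncol = 3L)
  if (!all(keypoints[, 3L] %in% c(0, 1, 2))) stop("visibility flags must be 0, 1 or 2")
  if (any(!is.finite(keypoints))) stop("keypoint coordinates must be finite")
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4L) stop("bbox must be (x, y, w, h)")
  if (is.null(area)) area <- bbox[3L] * bbox[4L]
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  structure(list(id = as.integer(id), image_id = as.integer(image_id),
                 category_id = as.integer(category_id),
                 keypoints = keypoints, bbox = bbox, area = as.numeric(area)),
            class = "coco_annotation")
}

#' Construct an annotation set
#'
#' Bundles image records, instance annotations and the keypoint schema they
#' follow, mirroring the images/annotations/categories blocks of a COCO
#' keypoint JSON file.
#'
#' @param images data.frame with columns id, file_name, width, height.
#' @param annotations list of [coco_annotation()] objects.
#' @param schema a [keypoint_schema()].
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(images, annotations, schema) {
  stopifnot(inherits(schema, "keypoint_schema"))
  images <- as.data.frame(images)
  need <- c("id", "file_name", "width", "height")
  if (!all(need %in% names(images))) stop("images needs columns ", paste(need, collapse = ", "))
  for (a in annotations) {
    if (!inherits(a, "coco_annotation")) stop("annotations must be coco_annotation objects")
    if (nrow(a$keypoints) != schema$M)
      stop(sprintf("annotation %d has %d keypoints, schema '%s' expects %d",
                   a$id, nrow(a$keypoints), schema$name, schema$M))
    if (!a$image_id %in% images$id)
      stop("annotation ", a$id, " references unknown image id ", a$image_id)
  }
  structure(list(images = images, annotations = annotations, schema = schema),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d images, %d instances, schema '%s' (M = %d)\n",
              nrow(x$images), length(x$annotations), x$schema$name, x$schema$M))
  invisible(x)
}

#' Read COCO keypoint annotations
#'
#' Parses a COCO keypoint JSON file against a known schema. Coordinates and
#' visibility flags are preserved exactly; an annotation whose keypoint count
#' does not match the schema is an error, not silently dropped.
#'
#' @param path path to a COCO keypoint JSON file.
#' @param schema the [keypoint_schema()] the file must follow.
#' @return an [annotation_set()].
#' @export
read_coco_keypoints <- function(path, schema) {
  j <- jsonlite::read_json(path)
  if (is.null(j$images)) stop("not a COCO keypoint file (no 'images' block): ", path)
  images <- do.call(rbind, lapply(j$images, function(im)
    data.frame(id = as.integer(im$id), file_name = as.character(im$file_name),
               width = as.integer(im$width), height = as.integer(im$height))))
  if (is.null(images)) images <- data.frame(id = integer(), file_name = character(),
                                            width = integer(), height = integer())
  anns <- lapply(j$annotations, function(a) {
    kp <- as.numeric(unlist(a$keypoints))
    if (length(kp) != 3L * schema$M)
      stop(sprintf("annotation %s lists %d keypoints but schema '%s' expects %d",
                   a$id, length(kp) %/% 3L, schema$name, schema$M))
    coco_annotation(image_id = a$image_id,
                    keypoints = matrix(kp, ncol = 3L, byrow = TRUE),
                    bbox = as.numeric(unlist(a$bbox)),
                    area = if (!is.null(a$area)) as.numeric(a$area) else NULL,
                    id = a$id,
                    category_id = if (!is.null(a$category_id)) a$category_id else 1L)
  })
  annotation_set(images, anns, schema)
}

#' Write COCO keypoint annotations
#'
#' Inverse of [read_coco_keypoints()]: `read_coco_keypoints(write_coco_keypoints(x))`
#' reproduces every field the pipeline uses. Skeleton edges are emitted
#' 1-based in the categories block, following the COCO convention.
#'
#' @param aset an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coco_keypoints <- function(aset, path) {
  stopifnot(inherits(aset, "annotation_set"))
  sc <- aset$schema
  j <- list(
    images = lapply(seq_len(nrow(aset$images)), function(i) {
      im <- aset$images[i, ]
      list(id = im$id, file_name = im$file_name, width = im$width, height = im$height)
    }),
    annotations = lapply(aset$annotations, function(a)
      list(id = a$id, image_id = a$image_id, category_id = a$category_id,
           keypoints = as.numeric(t(a$keypoints)),
           num_keypoints = sum(a$keypoints[, 3L] > 0),
           bbox = a$bbox, area = a$area, iscrowd = 0L)),
    categories = list(list(
      id = 1L, name = "animal", supercategory = "animal",
      keypoints = sc$keypoint_names,
      skeleton = if (is.null(sc$skeleton)) list() else
        lapply(seq_len(nrow(sc$skeleton)), function(i) sc$skeleton[i, ] + 1L))))
  # I(17) significant digits: doubles survive the write/read cycle bit-exactly
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  invisible(path)
}

#' Write top-down prediction results
#'
#' Emits the COCO "results" flavor of keypoint JSON: a flat array of records
#' with image_id, category_id, the flat keypoint list and a confidence score.
#' An `annotation_id` field ties each prediction to the ground-truth instance
#' it was produced for (top-down evaluation is per-instance).
#'
#' @param preds list of prediction records (fields: annotation_id, image_id,
#'   keypoints M x 3 with the score in column 3, score).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coco_results <- function(preds, path) {
  j <- lapply(preds, function(p)
    list(annotation_id = p$annotation_id, image_id = p$image_id,
         category_id = if (!is.null(p$category_id)) p$category_id else 1L,
         keypoints = as.numeric(t(p$keypoints)),
         score = as.numeric(p$score)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read top-down prediction results
#'
#' @param path path to a results JSON written by [write_coco_results()].
#' @param schema the [keypoint_schema()] predictions must follow.
#' @return list of prediction records.
#' @export
read_coco_results <- function(path, schema) {
  j <- jsonlite::read_json(path)
  lapply(j, function(p) {
    kp <- as.numeric(unlist(p$keypoints))
    if (length(kp) != 3L * schema$M)
      stop("prediction keypoint count does not match schema '", schema$name, "'")
    list(annotation_id = as.integer(p$annotation_id),
         image_id = as.integer(p$image_id),
         category_id = as.integer(p$category_id),
         keypoints = matrix(kp, ncol = 3L, byrow = TRUE),
         score = as.numeric(p$score))
  })
}
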