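# Keypoint schemas: ordered landmark names, skeleton edges for drawing, and
# per-keypoint OKS falloff weights k_i.

#' Construct a keypoint schema
#'
#' A schema fixes the ordered list of M anatomical landmarks, the skeleton
#' edges used for visualization, and the per-keypoint OKS weights \eqn{k_i}
#' that control how fast similarity decays with localization error.
#'
#' @param name short identifier.
#' @param keypoint_names character vector of M unique landmark names, in
#'   annotation order.
#' @param skeleton integer matrix with two columns of 0-based keypoint
#'   indices (edges), or `NULL` for none.
#' @param sigmas numeric vector of M positive OKS weights; a single value is
#'   recycled. The weights are configuration, not a claim about any published
#'   evaluation protocol.
#' @return an object of class `keypoint_schema`.
#' @examples
#' sc <- keypoint_schema("toy", c("nose", "tail"), rbind(c(0L, 1L)))
#' sc$M
#' @export
keypoint_schema <- function(name, keypoint_names, skeleton = NULL, sigmas = 0.1) {
  keypoint_names <- as.character(keypoint_names)
  M <- length(keypoint_names)
  if (M < 1L) stop("schema needs at least one keypoint")
  if (anyDuplicated(keypoint_names)) stop("keypoint names must be unique")
  if (length(sigmas) == 1L) sigmas <- rep(as.numeric(sigmas), M)
  if (length(sigmas) != M) stop("sigmas length must equal the number of keypoints")
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) stop("all sigmas must be positive")
  if (!is.null(skeleton)) {
    skeleton <- matrix(as.integer(skeleton), ncol = 2L)
    if (any(skeleton < 0L) || any(skeleton >= M)) stop("skeleton indices out of range")
  }
  structure(list(name = name, keypoint_names = keypoint_names, M = M,
                 skeleton = skeleton, sigmas = sigmas),
            class = "keypoint_schema")
}

#' @export
print.keypoint_schema <- function(x, ...) {
  cat(sprintf("Keypoint schema '%s': %d keypoints, %d skeleton edges\n",
              x$name, x$M, if (is.null(x$skeleton)) 0L else nrow(x$skeleton)))
  cat(" ", paste(x$keypoint_names, collapse = ", "), "\n")
  invisible(x)
}

# The 17-landmark mammal schema used by AP-10K-style annotations.
.ap10k_names <- c(
  "left eye", "right eye", "nose", "neck", "root of tail",
  "left shoulder", "left elbow", "left front paw",
  "right shoulder", "right elbow", "right front paw",
  "left hip", "left knee", "left back paw",
  "right hip", "right knee", "right back paw")

.ap10k_skeleton <- rbind(
  c(0L, 2L), c(1L, 2L), c(2L, 3L), c(3L, 4L),
  c(3L, 5L), c(5L, 6L), c(6L, 7L),
  c(3L, 8L), c(8L, 9L), c(9L, 10L),
  c(4L, 11L), c(11L, 12L), c(12L, 13L),
  c(4L, 14L), c(14L, 15L), c(15L, 16L))

# The 20-landmark quadruped schema used by Animal-Pose-style annotations.
.animalpose_names <- c(
  "left eye", "right eye", "left ear base", "right ear base", "nose",
  "throat", "tail base", "withers",
  "left front elbow", "right front elbow", "left back elbow", "right back elbow",
  "left front knee", "right front knee", "left back knee", "right back knee",
  "left front paw", "right front paw", "left back paw", "right back paw")

.animalpose_skeleton <- rbind(
  c(0L, 4L), c(1L, 4L), c(0L, 2L), c(1L, 3L), c(4L, 5L),
  c(5L, 7L), c(7L, 6L),
  c(7L, 8L), c(7L, 9L), c(6L, 10L), c(6L, 11L),
  c(8L, 12L), c(9L, 13L), c(10L, 14L), c(11L, 15L),
  c(12L, 16L), c(13L, 17L), c(14L, 18L), c(15L, 19L))

#' Load a keypoint schema by name or from a YAML file
#'
#' Two schemas are registered: `"ap10k"` (17 mammal keypoints) and
#' `"animalpose"` (20 quadruped keypoints). Any other value is treated as a
#' path to a YAML file with keys `name`, `keypoints`, and optionally
#' `skeleton` (list of 0-based index pairs) and `sigmas`.
#'
#' @param name registered schema name or path to a schema YAML file.
#' @param sigma default OKS weight used for every keypoint of a registered
#'   schema (the published protocols do not pin these; they are configuration).
#' @return a [keypoint_schema()].
#' @examples
#' load_keypoint_schema("ap10k")$M
#' @export
load_keypoint_schema <- function(name, sigma = 0.1) {
  if (identical(name, "ap10k"))
    return(keypoint_schema("ap10k", .ap10k_names, .ap10k_skeleton, sigma))
  if (identical(name, "animalpose"))
    return(keypoint_schema("animalpose", .animalpose_names, .animalpose_skeleton, sigma))
  if (file.exists(name)) {
    y <- yaml::read_yaml(name)
    if (is.null(y$keypoints)) stop("schema file lacks a 'keypoints' key: ", name)
    skel <- if (!is.null(y$skeleton)) do.call(rbind, lapply(y$skeleton, as.integer))
    sig <- if (!is.null(y$sigmas)) as.numeric(y$sigmas) else sigma
    return(keypoint_schema(if (!is.null(y$name)) y$name else name,
                           unlist(y$keypoints), skel, sig))
  }
  stop("unknown keypoint schema: '", name, "'")
}
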