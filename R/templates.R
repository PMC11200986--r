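# Keypoint sentence templates: prefix, intermediate and suffix forms, each
# with a single {kp} slot that receives the keypoint name.

#' Construct a template set
#'
#' Templates come in three forms depending on where the keypoint name sits in
#' the sentence: prefix (name at the end), intermediate (name mid-sentence)
#' and suffix (name leading). Every template must contain exactly one `{kp}`
#' slot and each form must be non-empty.
#'
#' @param prefix,intermediate,suffix character vectors of templates.
#' @return object of class `template_set`.
#' @export
template_set <- function(prefix, intermediate, suffix) {
  forms <- list(prefix = as.character(prefix),
                intermediate = as.character(intermediate),
                suffix = as.character(suffix))
  for (f in names(forms)) {
    if (length(forms[[f]]) == 0L) stop("template form '", f, "' is empty")
    nslot <- vapply(forms[[f]], function(t) {
      hits <- gregexpr("{kp}", t, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) 0L else length(hits)
    }, integer(1L))
    if (any(nslot != 1L))
      stop("every template must contain exactly one {kp} slot (form '", f, "')")
  }
  structure(forms, class = "template_set")
}

#' Default keypoint templates
#'
#' Three templates per form. These are the package's own wording and are
#' fully replaceable via a YAML file ([read_template_set()]).
#'
#' @return a [template_set()].
#' @export
default_template_set <- function() {
  template_set(
    prefix = c("a photo of the {kp}",
               "a close-up photo of an animal's {kp}",
               "an image showing the {kp}"),
    intermediate = c("the {kp} is a key point of the animal body",
                     "locate the {kp} on the animal in the photo",
                     "this animal's {kp} appears in the image"),
    suffix = c("{kp}, a joint location on an animal",
               "{kp} of the animal in the picture",
               "{kp}, an anatomical landmark of the animal"))
}

#' Read a template set from YAML
#'
#' The file must have keys `prefix`, `intermediate` and `suffix`, each a list
#' of strings containing one `{kp}` slot.
#'
#' @param path YAML file path.
#' @return a [template_set()].
#' @export
read_template_set <- function(path) {
  y <- yaml::read_yaml(path)
  template_set(unlist(y$prefix), unlist(y$intermediate), unlist(y$suffix))
}

#' Fill templates with keypoint names
#'
#' Draws one template per keypoint, uniformly at random over the pooled
#' template inventory (all forms together), and substitutes the keypoint name
#' into the `{kp}` slot. The draw is seeded, so a fixed seed yields a fixed
#' sentence list — templates are selected once per training run, not per
#' batch.
#'
#' @param schema a [keypoint_schema()].
#' @param tset a [template_set()].
#' @param seed integer seed for the template draw.
#' @return character vector of M sentences; the m-th contains the m-th
#'   keypoint name verbatim.
#' @export
fill_templates <- function(schema, tset, seed = 1L) {
  stopifnot(inherits(schema, "keypoint_schema"), inherits(tset, "template_set"))
  pool <- c(tset$prefix, tset$intermediate, tset$suffix)
  if (length(pool) == 0L) stop("empty template set")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(length(pool), schema$M, replace = TRUE)
  vapply(seq_len(schema$M), function(m)
    sub("{kp}", schema$keypoint_names[m], pool[idx[m]], fixed = TRUE),
    character(1L))
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
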