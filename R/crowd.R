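# Crowd-annotation policies: who sees which annotations, and when an image
# counts as done. Three modes:
#   cooperative  — one user verifying the image suffices; everyone sees all
#                  annotations.
#   competitive  — blind: every enrolled user must verify every image and
#                  sees only their own annotations.
#   second_opinion — a configured number of distinct users must confirm
#                  every annotation on the image.

#' Configure a crowd-annotation mode
#'
#' @param mode `"cooperative"`, `"competitive"` or `"second_opinion"`.
#' @param required_verifications Distinct confirming users needed per
#'   annotation (second-opinion mode only); at least 1.
#' @return A `mode_config` object.
#' @export
mode_config <- function(mode = c("cooperative", "competitive", "second_opinion"),
                        required_verifications = 1L) {
  mode <- match.arg(mode)
  required_verifications <- as.integer(required_verifications)
  if (is.na(required_verifications) || required_verifications < 1L) {
    abort("`required_verifications` must be >= 1")
  }
  structure(list(mode = mode, required_verifications = required_verifications),
            class = "mode_config")
}

#' Annotations visible to a user under a crowd mode
#'
#' Cooperative and second-opinion modes show every live annotation;
#' competitive (blind) mode isolates users — each sees only annotations they
#' created, so gradings stay independent.
#'
#' @param annotations A tibble of annotations (e.g. [annotations()]).
#' @param user Viewing user id.
#' @param config A [mode_config()].
#' @return The visible subset, a tibble.
#' @export
visible_annotations <- function(annotations, user, config) {
  check_mode(config)
  live <- filter(annotations, !.data$deleted)
  if (config$mode == "competitive") filter(live, .data$creator == .env$user) else live
}

#' Is an image complete under a crowd mode?
#'
#' Cooperative: at least one user has verified the image. Competitive:
#' every enrolled user has verified it. Second opinion: every live
#' annotation on the image carries confirmed verdicts from at least
#' `required_verifications` distinct users (rejections do not count).
#' Completion is monotone: adding verifications can never undo it.
#'
#' @param prj A [slide_project()].
#' @param image_id Image to check.
#' @param config A [mode_config()].
#' @param enrolled Enrolled user ids (competitive mode); default: all active
#'   project users.
#' @return `TRUE` or `FALSE`.
#' @export
image_complete <- function(prj, image_id, config, enrolled = NULL) {
  check_project(prj)
  check_mode(config)
  get_image(prj, image_id)
  verifiers <- prj$image_verifications$user[prj$image_verifications$image_id == image_id]
  switch(config$mode,
    cooperative = length(unique(verifiers)) >= 1L,
    competitive = {
      enrolled <- enrolled %||% prj$users$user_id[prj$users$active]
      length(enrolled) > 0L && all(enrolled %in% verifiers)
    },
    second_opinion = {
      # base-R path: this predicate is evaluated in tight enumeration loops
      live <- prj$annotations$annotation_id[!prj$annotations$deleted &
                                            prj$annotations$image_id == image_id]
      if (!length(live)) return(TRUE)
      v <- prj$verifications
      keep <- v$verdict == "confirmed" & v$annotation_id %in% live
      pairs <- unique(paste(v$annotation_id[keep], v$user[keep]))
      cnt <- table(sub(" .*", "", pairs))
      all(live %in% names(cnt)[cnt >= config$required_verifications])
    }
  )
}

check_mode <- function(config) {
  if (!inherits(config, "mode_config")) abort("`config` must come from mode_config()")
  invisible(config)
}
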