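#' Classroom layout: dyad pairings and class membership
#'
#' A layout records which participants form collaborating dyads and which
#' class (room) each dyad sat in. Both the compliance statistic and the
#' restricted permutation null are defined relative to a layout: true
#' pairings give the observed mean dyad correlation, while the null
#' re-pairs first members with second members drawn from the same class.
#'
#' @param first_id Integer vector of first-member participant ids.
#' @param second_id Integer vector of second-member participant ids,
#'   parallel to `first_id`.
#' @param class_id Integer vector giving the class of each dyad.
#' @param dyad_id Optional integer dyad labels; defaults to `seq_along(first_id)`.
#'
#' @return An object of class `"classroom_layout"`: a data frame with
#'   columns `dyad_id`, `first_id`, `second_id`, `class_id`.
#'
#' @details Each participant must appear in exactly one dyad. The common
#' convention that second members are numbered `first_id + n_dyads` is not
#' required; any disjoint pairing is accepted.
#'
#' @examples
#' classroom_layout(first_id = 1:4, second_id = 5:8, class_id = c(1, 1, 2, 2))
#' @export
classroom_layout <- function(first_id, second_id, class_id,
                             dyad_id = seq_along(first_id)) {
  if (length(first_id) != length(second_id) ||
      length(first_id) != length(class_id)) {
    stop("first_id, second_id and class_id must have equal length")
  }
  if (length(first_id) == 0L) stop("layout must contain at least one dyad")
  ids <- c(first_id, second_id)
  if (anyDuplicated(ids)) {
    stop("each participant must appear in exactly one dyad (duplicated id: ",
         ids[duplicated(ids)][1L], ")")
  }
  out <- data.frame(
    dyad_id = as.integer(dyad_id),
    first_id = as.integer(first_id),
    second_id = as.integer(second_id),
    class_id = as.integer(class_id)
  )
  class(out) <- c("classroom_layout", "data.frame")
  out
}

#' @export
print.classroom_layout <- function(x, ...) {
  cat("Classroom layout: ", nrow(x), " dyads in ",
      length(unique(x$class_id)), " class(es)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Class membership lookup for a layout
#'
#' @param layout A [classroom_layout()].
#' @return Named integer vector mapping participant id to class id.
#' @keywords internal
layout_class_of <- function(layout) {
  setNames(
    rep(layout$class_id, 2L),
    as.character(c(layout$first_id, layout$second_id))
  )
}

validate_layout <- function(layout) {
  if (!inherits(layout, "classroom_layout")) {
    layout <- classroom_layout(layout$first_id, layout$second_id,
                               layout$class_id,
                               dyad_id = layout$dyad_id %||% seq_len(nrow(layout)))
  }
  layout
}

`%||%` <- function(a, b) if (is.null(a)) b else a
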