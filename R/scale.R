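#' Define a symptom rating scale
#'
#' A symptom scale lists the instrument's items together with their admissible
#' integer score ranges. All items start at 0; the maximum is either 2 or 4,
#' the two item formats found on clinician-rated depression scales such as the
#' HRSD-17.
#'
#' @param labels Character vector of unique item labels.
#' @param max_score Integer vector (recycled) of per-item maxima; each must be
#'   2 or 4.
#'
#' @return An object of class `symptom_scale`: a list with an `items`
#'   data frame (`label`, `min_score`, `max_score`).
#' @seealso [hrsd17_scale()] for the default 17-item instrument.
#' @export
#' @examples
#' symptom_scale(c("mood", "guilt", "insight"), max_score = c(4, 4, 2))
symptom_scale <- function(labels, max_score) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop_noa("a symptom scale needs at least one item")
  if (anyDuplicated(labels)) stop_noa("item labels must be unique")
  max_score <- as.integer(rep_len(max_score, length(labels)))
  if (!all(max_score %in% c(2L, 4L))) {
    stop_noa("max_score must be 2 or 4 for every item")
  }
  structure(
    list(items = data.frame(
      label = labels,
      min_score = 0L,
      max_score = max_score,
      stringsAsFactors = FALSE
    )),
    class = "symptom_scale"
  )
}

#' The 17-item Hamilton depression scale
#'
#' Default instrument: 17 items in standard HRSD ordering. Thirteen items are
#' scored 0-4; the four items on general somatic symptoms, genital symptoms,
#' weight loss, and insight are scored 0-2.
#'
#' The items relevant to remission prediction sit at their standard positions:
#' suicidality is item 3, psychomotor retardation item 8, hypochondriasis
#' item 15.
#'
#' @return A [symptom_scale()] with 17 items.
#' @export
#' @examples
#' sc <- hrsd17_scale()
#' sc$items[sc$items$max_score == 2, "label"]
hrsd17_scale <- function() {
  labels <- c(
    "depressed_mood", "guilt", "suicidality",
    "insomnia_early", "insomnia_middle", "insomnia_late",
    "work_activities", "retardation", "agitation",
    "anxiety_psychic", "anxiety_somatic",
    "somatic_gastrointestinal", "somatic_general",
    "genital_symptoms", "hypochondriasis", "weight_loss", "insight"
  )
  two_point <- c("somatic_general", "genital_symptoms", "weight_loss", "insight")
  symptom_scale(labels, max_score = ifelse(labels %in% two_point, 2L, 4L))
}

n_items <- function(scale) nrow(scale$items)

scale_labels <- function(scale) scale$items$label

#' @export
print.symptom_scale <- function(x, ...) {
  cat(sprintf("<symptom_scale> %d items\n", n_items(x)))
  rng <- sprintf("0-%d", x$items$max_score)
  cat(paste(sprintf("  %-26s %s", x$items$label, rng), collapse = "\n"), "\n")
  invisible(x)
}
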