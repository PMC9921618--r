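# Clinical binarization rules for the four molecular markers.

#' Positivity scheme for a molecular marker
#'
#' Standard clinical cut-offs: ER and PR are negative below 10% of
#' involved cells, Ki67 is negative below 14%, and HER2 (an ordinal score
#' 0-3, possibly written `"2+"`) is negative at 0 or 1 and positive from
#' 2 upwards. Values exactly at a percentage threshold are positive.
#'
#' @param marker one of `"ER"`, `"PR"`, `"HER2"`, `"Ki67"`.
#' @return An object of class `marker_scheme` with elements `marker`,
#'   `type` (`"percentage"` or `"ordinal"`) and `threshold`.
#' @export
marker_scheme <- function(marker = c("ER", "PR", "HER2", "Ki67")) {
  marker <- match.arg(marker)
  scheme <- switch(marker,
    ER = list(type = "percentage", threshold = 10),
    PR = list(type = "percentage", threshold = 10),
    Ki67 = list(type = "percentage", threshold = 14),
    HER2 = list(type = "ordinal", threshold = 2))
  structure(c(list(marker = marker), scheme), class = "marker_scheme")
}

#' Binarize raw marker values
#'
#' Applies the scheme's positivity rule; the rule is "negative if lower
#' than the threshold", so boundary values are positive. HER2 values may
#' carry plus signs (`"2+"`); the leading digit is used. Missing or
#' unparseable values yield `NA` with a message, so the affected samples
#' can be excluded upstream.
#'
#' @param raw_values numeric vector, or character vector for HER2 scores.
#' @param scheme a [marker_scheme()].
#' @return Integer vector of 0/1 labels (`NA` where the raw value was
#'   missing).
#' @export
binarize_marker <- function(raw_values, scheme) {
  stopifnot(inherits(scheme, "marker_scheme"))
  if (scheme$type == "ordinal") {
    vals <- suppressWarnings(as.numeric(sub("^\\s*([0-9]+).*$", "\\1",
                                            as.character(raw_values))))
  } else {
    vals <- suppressWarnings(as.numeric(sub("%$", "", as.character(raw_values))))
  }
  out <- ifelse(vals < scheme$threshold, 0L, 1L)
  n_missing <- sum(is.na(out))
  if (n_missing > 0) {
    message(scheme$marker, ": ", n_missing,
            " sample(s) with missing/unparseable marker value set to NA")
  }
  as.integer(out)
}
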