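#' Residue numbering between native and tagged constructs
#'
#' The deposited full-length channel model carries an eight-residue
#' affinity-tag insertion (WSHPQFEK) after native residue V172, so model
#' numbering runs eight ahead of native numbering from there on: the
#' literature writes this as a dual index, e.g. E414(422). An `index_map`
#' records the insertion site and tag so the two numberings can be converted
#' both ways.
#'
#' @param insertion_site native residue index after which the tag sits.
#' @param tag_sequence one-letter tag sequence.
#' @return An `index_map` object.
#' @export
index_map <- function(insertion_site = 172, tag_sequence = "WSHPQFEK") {
  tag_length <- nchar(tag_sequence)
  structure(
    list(insertion_site = as.integer(insertion_site),
         tag_length = as.integer(tag_length),
         tag_sequence = tag_sequence),
    class = "index_map"
  )
}

#' Convert residue indices between native and model numbering
#'
#' Native indices at or before the insertion site are unchanged; later
#' indices shift up by the tag length. The inverse rejects model indices that
#' fall inside the tag span (no native equivalent).
#'
#' @param i residue index (vectorised).
#' @param map an [index_map()].
#' @return Integer vector of converted indices.
#' @export
native_to_model_index <- function(i, map = index_map()) {
  i <- as.integer(i)
  if (any(i < 1L)) abort("residue indices must be >= 1")
  ifelse(i <= map$insertion_site, i, i + map$tag_length)
}

#' @rdname native_to_model_index
#' @export
model_to_native_index <- function(i, map = index_map()) {
  i <- as.integer(i)
  if (any(i < 1L)) abort("residue indices must be >= 1")
  lo <- map$insertion_site + 1L
  hi <- map$insertion_site + map$tag_length
  bad <- i >= lo & i <= hi
  if (any(bad)) {
    abort(sprintf(
      "model residue(s) %s lie inside the tag span (%d-%d) and have no native equivalent",
      paste(i[bad], collapse = ", "), lo, hi))
  }
  ifelse(i <= map$insertion_site, i, i - map$tag_length)
}

#' Format a native index in the dual native(model) convention
#'
#' @inheritParams native_to_model_index
#' @param prefix optional residue-letter prefix, e.g. `"E"` for E414(422).
#' @return Character vector like `"414(422)"`.
#' @export
dual_numbering <- function(i, map = index_map(), prefix = "") {
  paste0(prefix, i, "(", native_to_model_index(i, map), ")")
}
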