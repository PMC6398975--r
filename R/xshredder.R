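# Comparator strategy: an X-shredding cassette integrated on the Y
# chromosome and expressed in the male germline during meiosis. Carrier
# males whose germline X is destroyed (germline-YO males) transmit Y-bearing
# sperm with probability p_y_yo, otherwise O-bearing sperm (producing XO
# daughters). Every transmitted Y from a carrier carries the cassette.

#' Assign the lifetime germline state of a carrier male
#'
#' X-shredding succeeds in a carrier male's germline with probability `p_x`;
#' the resulting germline-YO status is decided once (at first breeding) and
#' is fixed for life.
#'
#' @param male_carrier Must be `TRUE`; non-carriers have no shredder.
#' @param params An [xshredder_params()].
#' @return Logical: is the male germline YO?
#' @export
assign_germline_state <- function(male_carrier, params) {
  if (!isTRUE(male_carrier))
    stop("`assign_germline_state` applies to carrier males only",
         call. = FALSE)
  runif(1) < params$p_x
}

#' Sample the paternal allosome under the X-shredding Y-drive
#'
#' Non-carriers (and carriers whose germline X survived) transmit X or Y
#' with probability 0.5 each. A germline-YO carrier transmits a Y with
#' probability `p_y_yo` and an O-bearing sperm otherwise.
#'
#' @param father_is_carrier Does the father carry the Y-linked cassette?
#' @param germline_yo Is the father germline YO (carriers only)?
#' @param params An [xshredder_params()].
#' @return `"X"`, `"Y"` or `"O"`.
#' @export
xshredder_paternal_gamete <- function(father_is_carrier, germline_yo,
                                      params) {
  if (isTRUE(germline_yo) && !isTRUE(father_is_carrier))
    stop("`germline_yo` requires a carrier father", call. = FALSE)
  if (isTRUE(father_is_carrier) && isTRUE(germline_yo)) {
    if (runif(1) < params$p_y_yo) "Y" else "O"
  } else {
    if (runif(1) < 0.5) "X" else "Y"
  }
}
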