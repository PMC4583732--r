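#' Money helpers: integer cents
#'
#' All internal money arithmetic is done in integer cents so that sums are
#' associative and CSV round-trips are exact; values are rendered as USD with
#' two decimals at the interface.
#'
#' @param usd numeric vector of dollar amounts.
#' @param cents numeric vector of integer cent amounts.
#' @return `as_cents()` returns integer-valued numerics (cents); `as_usd()`
#'   the dollar value.
#' @examples
#' as_cents(12.345) # 1235
#' as_usd(1235)     # 12.35
#' @export
as_cents <- function(usd) round(usd * 100)

#' @rdname as_cents
#' @export
as_usd <- function(cents) cents / 100

# round half away from zero at 2 decimals (money convention; base round()
# is banker's rounding)
round_money <- function(x) as_usd(as_cents(x))

#' Round half up
#'
#' Rounds to the nearest integer with ties going up, the convention used when
#' deriving integer visit counts from a mean party size (e.g. 2.3 caretakers
#' per patient times 3546 patient visits).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.3 * 3546))
#' @export
round_half_up <- function(x) floor(x + 0.5)
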