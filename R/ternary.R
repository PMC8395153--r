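#' Balanced ternary logical operators
#'
#' The regulatory logic operates on three discrete levels: -1 (downregulated),
#' 0 (nominal) and 1 (upregulated). Signed inputs to a node are aggregated with
#' the ternary OR (`ternary_or`), inverted with the ternary NOT (`ternary_not`),
#' and activator/inhibitor aggregates are combined with the ternary HIGH/LOW
#' PASS operator (`ternary_pass`). The adopted truth tables are:
#' OR = elementwise maximum, NOT = sign flip, PASS(a, i) = sign(a - i).
#' All three are closed on \{-1, 0, 1\} and PASS is antisymmetric:
#' `ternary_pass(a, i) == -ternary_pass(i, a)`.
#'
#' @param values integer vector of ternary values (each in -1, 0, 1).
#' @param v a single ternary value.
#' @param a aggregated activator value (ternary).
#' @param i aggregated inhibitor value (ternary).
#' @return A single ternary value.
#' @examples
#' ternary_or(c(-1, 1))     # 1
#' ternary_not(1)           # -1
#' ternary_pass(1, 1)       # 0
#' @name ternary
NULL

check_ternary <- function(x, what = "value") {
  if (length(x) == 0L)
    stop("empty ", what, ": malformed network input", call. = FALSE)
  if (anyNA(x) || !all(x %in% c(-1L, 0L, 1L)))
    stop(what, " must be ternary (-1, 0 or 1)", call. = FALSE)
  as.integer(x)
}

#' @rdname ternary
#' @export
ternary_or <- function(values) {
  values <- check_ternary(values, "operand list")
  max(values)
}

#' @rdname ternary
#' @export
ternary_not <- function(v) {
  v <- check_ternary(v)
  if (length(v) != 1L) stop("ternary_not takes a single value", call. = FALSE)
  -v
}

#' @rdname ternary
#' @export
ternary_pass <- function(a, i) {
  a <- check_ternary(a); i <- check_ternary(i)
  if (length(a) != 1L || length(i) != 1L)
    stop("ternary_pass takes single values", call. = FALSE)
  as.integer(sign(a - i))
}
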