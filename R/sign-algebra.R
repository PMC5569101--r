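# Sign algebra over the qualitative states {+, -, 0}.
#
# Signs are the characters "+", "-", "0" at the interface and the integers
# 1, -1, 0 internally, so that sign products are plain integer products.

.sign_chr <- c("+", "-", "0")
.sign_int <- c(1L, -1L, 0L)

#' @keywords internal
as_sign_int <- function(x) {
  if (length(x) == 0L) return(stats::setNames(integer(0), names(x)))
  if (is.numeric(x)) {
    xi <- as.integer(x)
    bad <- is.na(xi) | !(xi %in% .sign_int)
    if (any(bad)) {
      stop("invalid sign value(s): ", paste(unique(x[bad]), collapse = ", "))
    }
    names(xi) <- names(x)
    return(xi)
  }
  m <- match(as.character(x), .sign_chr)
  if (anyNA(m)) {
    stop("invalid sign value(s): ",
         paste(unique(as.character(x)[is.na(m)]), collapse = ", "))
  }
  stats::setNames(.sign_int[m], names(x))
}

#' @keywords internal
as_sign_chr <- function(x) {
  xi <- as_sign_int(x)
  stats::setNames(.sign_chr[match(xi, .sign_int)], names(x))
}

#' Propagate a sign along a signed edge
#'
#' The influence a regulator exerts on its target: an activating edge (`"+"`)
#' transmits the regulator's variation unchanged, an inhibiting edge (`"-"`)
#' flips `"+"` and `"-"`. An invariant regulator (`"0"`) transmits no
#' variation regardless of the edge sign.
#'
#' @param edge_sign Edge sign, `"+"` or `"-"` (invariant edges do not exist:
#'   edges are activations or inhibitions).
#' @param source_sign Sign of the source node, one of `"+"`, `"-"`, `"0"`.
#' @return The transmitted sign, one of `"+"`, `"-"`, `"0"`. Vectorised.
#' @examples
#' influence("+", "+") # "+"
#' influence("-", "+") # "-"
#' influence("-", "0") # "0"
#' @export
influence <- function(edge_sign, source_sign) {
  e <- as_sign_int(edge_sign)
  s <- as_sign_int(source_sign)
  if (any(e == 0L)) stop("edge signs must be '+' (activation) or '-' (inhibition)")
  as_sign_chr(e * s)
}

#' Compose two variant signs
#'
#' Sign product used when rewiring paths through removed intermediate nodes:
#' two inhibitions compose to an activation, mixed signs to an inhibition.
#' Associative and commutative; `"0"` operands are rejected because edges
#' carry only variant signs.
#'
#' @param a,b Signs in `{"+", "-"}`.
#' @return The composed sign. Vectorised.
#' @examples
#' compose_signs("-", "-") # "+"
#' compose_signs("+", "-") # "-"
#' @export
compose_signs <- function(a, b) {
  ai <- as_sign_int(a)
  bi <- as_sign_int(b)
  if (any(ai == 0L) || any(bi == 0L)) {
    stop("compose_signs() is defined for variant signs '+' and '-' only")
  }
  as_sign_chr(ai * bi)
}
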