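#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded at \code{seed}, restoring the
#' previous RNG state afterwards. With \code{seed = NULL} the expression is
#' evaluated against the current RNG stream (used internally so that bootstrap
#' iterations consume one stream seeded once at the top).
#'
#' @param seed Integer scalar or \code{NULL}.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

#' Round half away from zero
#'
#' Display rounding for prevalence percentages: .5 always rounds up
#' (base \code{round} rounds to even).
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1L) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a p-value for report tables
#'
#' Three decimals; values below 0.0005 are rendered \code{"<0.001"}.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
formatPValue <- function(p) {
    out <- ifelse(p < 5e-4, "<0.001", sprintf("%.3f", roundHalfUp(p, 3L)))
    out[is.na(p)] <- NA_character_
    out
}
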