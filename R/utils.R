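#' @importFrom stats rnorm runif sd quantile rbinom
#' @importFrom methods new validObject is slot slotNames
NULL

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched, so all package randomness flows from explicit
# seeds and never perturbs (or depends on) global state.
withLocalSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Printed diagnostic tables in the radiology literature use conventional
#' half-away-from-zero rounding rather than IEEE banker's rounding, so
#' reproducing printed percentages requires this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(0.5, 0)   # 1, where round(0.5) is 0
#' roundHalfUp(83.615, 2)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Keep only the largest 8-connected foreground component of a binary mask.
# Returns an integer 0/1 matrix; an all-zero mask comes back unchanged.
largestComponent <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
}

# Stop with a classed condition so callers can distinguish failure modes.
stopWithClass <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
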