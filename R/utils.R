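# internal helpers: classed conditions, seeded evaluation, clipping

#' @noRd
voxnormStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "voxnormError", "error"),
                      call = sys.call(-1)))
}

#' @noRd
geometryError <- function(fmt, ...) voxnormStop("voxnorm_geometry_error", fmt, ...)
#' @noRd
argumentError <- function(fmt, ...) voxnormStop("voxnorm_argument_error", fmt, ...)
#' @noRd
dataError     <- function(fmt, ...) voxnormStop("voxnorm_data_error", fmt, ...)
#' @noRd
configError   <- function(fmt, ...) voxnormStop("voxnorm_config_error", fmt, ...)
#' @noRd
stateError    <- function(fmt, ...) voxnormStop("voxnorm_state_error", fmt, ...)

# Evaluate fn() under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user RNG.
#' @noRd
withSeed <- function(seed, fn) {
  if (is.null(seed) || is.na(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

# pmin/pmax take attributes from their first argument; keep x's dims
#' @noRd
clip01 <- function(x) { x[] <- pmin(1, pmax(0, x)); x }

#' @noRd
clip0 <- function(x) { x[] <- pmax(0, x); x }

# Round half away from zero (base round() is half-even); the convention used
# for reported percentages.
#' @noRd
roundHalfUp <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Re-raise any error from expr with a stage label so pipeline failures name
# the stage that produced them.
#' @noRd
withStage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (is.null(attr(e, "voxnormStage"))) {
      e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
      attr(e, "voxnormStage") <- stage
      stop(e)
    }
  })
}
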