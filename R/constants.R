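## Physical constants and small internal utilities shared across modules.

## Gas constant in kcal mol^-1 K^-1; free energies are kcal/mol throughout,
## rates are min^-1, distances are Angstrom.
.R_KCAL <- 1.98720425e-3

#' Thermal energy RT in kcal/mol
#'
#' Convenience accessor for the thermal energy scale used by all free-energy
#' conversions in the package.
#'
#' @param temperature Absolute temperature in Kelvin (default 298.15 K).
#' @return RT in kcal/mol (0.59248 kcal/mol at 298.15 K).
#' @examples
#' rtKcal()        # 0.59248...
#' rtKcal(310.15)  # physiological
#' @export
rtKcal <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .R_KCAL * temperature
}

## Derive a per-operation substream seed from a master seed.  Linear
## congruential step keeps results < 2^31 so they remain valid R integers.
deriveSeed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(as.numeric(master)) * 7919 + 104729 * as.numeric(index)) %%
               2147483647)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.  `seed = NULL` uses the ambient stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## shared input check helpers -------------------------------------------------

.assertScalarNumeric <- function(x, name, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite numeric value", name),
         call. = FALSE)
  invisible(x)
}
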