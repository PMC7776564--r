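# Seed a block of code without disturbing the caller's RNG stream.
# Returns a function that restores the previous state; use with on.exit().
.restore_seed <- function(seed) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      restore <- function() assign(".Random.seed", old, envir = globalenv())
    } else {
      restore <- function() {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      }
    }
    set.seed(as.integer(seed))
    restore
  } else {
    function() invisible(NULL)
  }
}

# wrap angles in degrees to [0, 360)
.wrap360 <- function(x) x %% 360

# signed angular difference in (-180, 180]
.wrap180 <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi
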