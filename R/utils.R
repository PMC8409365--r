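#' @include AllClasses.R
NULL

#' Strict local maxima of a signal
#'
#' Positions (1-based) of strict local maxima: samples greater than both
#' neighbours. A plateau higher than its surroundings contributes its first
#' index. Endpoints never qualify (they lack a neighbour on one side).
#'
#' @param v numeric vector.
#' @return integer vector of peak positions, possibly empty.
#' @export
#' @examples
#' findPeaks(c(0, 1, 0, 2, 2, 1, 0))   # 2 and 4 (plateau start)
findPeaks <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  r <- rle(as.numeric(v))
  k <- length(r$values)
  if (k < 3L) return(integer())
  starts <- cumsum(c(1L, r$lengths[-k]))
  j <- 2:(k - 1L)
  hit <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  starts[j][hit]
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# logical lateral mask of cells strictly inside the ROI circle
circleMask <- function(nX, nY, center, radius) {
  dx <- (seq_len(nX) - center[1])^2
  dy <- (seq_len(nY) - center[2])^2
  outer(dx, dy, "+") < radius^2
}
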