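# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unit-variance Gaussian random field on a 2D grid
#'
#' White noise convolved with a Gaussian kernel of the requested standard
#' deviation (in pixels), then re-standardized to zero mean / unit variance
#' over the grid. Used by the phantom generator as its texture model: the
#' kernel width sets the spatial correlation length of the field.
#'
#' @param nr,nc grid size
#' @param sigma_px Gaussian kernel standard deviation in pixels; 0 gives
#'   plain white noise
#' @return an `nr` x `nc` matrix with mean 0 and sd 1
#' @keywords internal
unit_grf <- function(nr, nc, sigma_px) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  if (sigma_px > 0) f <- .gauss_smooth_cpp(f, sigma_px)
  s <- stats::sd(as.vector(f))
  if (s < 1e-12) s <- 1
  (f - mean(f)) / s
}

# stop with a classed condition so callers/tests can distinguish error kinds
stop_radpt <- function(class, msg, ...) {
  stop(structure(class = c(class, "radpt_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# restore the caller's RNG state on exit; returns invisibly
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# standardized central moments; kurtosis is *not* excess kurtosis
moment_stat <- function(x, which = c("mean", "sd", "skewness", "kurtosis")) {
  which <- match.arg(which)
  n <- length(x)
  m <- mean(x)
  switch(which,
    mean = m,
    sd = stats::sd(x),
    skewness = {
      s <- sqrt(mean((x - m)^2))
      if (s < 1e-300) 0 else mean((x - m)^3) / s^3
    },
    kurtosis = {
      s2 <- mean((x - m)^2)
      if (s2 < 1e-300) 0 else mean((x - m)^4) / s2^2
    })
}
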