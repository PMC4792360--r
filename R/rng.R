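#' Named random-number streams
#'
#' The simulator draws from three independently seeded streams --
#' `population` (cohort generation), `disease` (state transitions, visits)
#' and `behavior` (message routing, softmax choice) -- so that, e.g.,
#' changing a behavioral parameter does not perturb the clinical event
#' sequence. Each stream is an independently seeded Mersenne-Twister state
#' swapped into R's global generator for the duration of a
#' [with_rng_stream()] call.
#'
#' @param seed integer master seed; sub-seeds are derived deterministically
#'   and kept below 2^31.
#' @param names character vector of stream names.
#' @return an object of class `rng_streams`.
#' @export
make_rng_streams <- function(seed,
                             names = c("population", "disease", "behavior")) {
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  env$states <- vector("list", length(names))
  names(env$states) <- names
  for (i in seq_along(names)) {
    sub <- (abs(as.double(seed)) * 48271 + i * 104729) %% 2147483629
    set.seed(as.integer(sub))
    env$states[[names[i]]] <- get(".Random.seed", envir = globalenv())
  }
  class(env) <- "rng_streams"
  env
}

#' Evaluate an expression under a named RNG stream
#'
#' @param streams an [make_rng_streams()] object.
#' @param name stream name.
#' @param expr expression evaluated with the stream's state installed as the
#'   global generator; the advanced state is saved back to the stream and the
#'   caller's generator state is restored afterwards.
#' @return the value of `expr`.
#' @export
with_rng_stream <- function(streams, name, expr) {
  stopifnot(inherits(streams, "rng_streams"))
  if (is.null(streams$states[[name]])) {
    stop_acosim(sprintf("unknown RNG stream '%s'", name))
  }
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  outer <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", streams$states[[name]], envir = globalenv())
  on.exit({
    streams$states[[name]] <- get(".Random.seed", envir = globalenv())
    assign(".Random.seed", outer, envir = globalenv())
  })
  expr
}
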