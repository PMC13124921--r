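# RNG helpers: all stochastic code in the package draws from an isolated,
# seeded stream and leaves the caller's .Random.seed untouched.

.get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.set_global_seed <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", s, envir = globalenv())
  }
}

# Resumable seeded RNG stream, independent of the global stream.
.seeded_rng <- function(seed) {
  e <- new.env()
  old <- .get_global_seed()
  set.seed(as.integer(seed))
  e$state <- .get_global_seed()
  .set_global_seed(old)
  run <- function(fn) {
    outer <- .get_global_seed()
    .set_global_seed(e$state)
    on.exit({
      e$state <- .get_global_seed()
      .set_global_seed(outer)
    })
    fn()
  }
  list(
    norm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    int = function(n, max) run(function() sample.int(max, n, replace = TRUE)),
    multinom_assign = function(n, prob)
      run(function() sample.int(length(prob), n, replace = TRUE, prob = prob))
  )
}

# Derive a distinct 31-bit sub-seed from a base seed and an index.
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483647)
}
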