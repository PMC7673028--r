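#' @keywords internal
NULL

## Evaluate `code` under a local RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards. seed = NULL means "use the current stream".
withLocalSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    force(code)
}

## Derive a stream-k child seed from a parent seed, kept inside 32-bit range.
deriveSeed <- function(seed, k) {
    as.integer((as.double(seed) * 48271 + 101 * as.double(k)) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stop with a classed error so callers/tests can match on condition class.
stopWith <- function(class, fmt, ...) {
    msg <- sprintf(fmt, ...)
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1L))))
}
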