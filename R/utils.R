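`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic substream seed
#'
#' Generators draw each logical stream (metabolite noise, genotype calls,
#' taxon counts, ...) from its own seed derived from the master seed, so
#' that enlarging one stream (say, adding taxa) does not perturb draws in
#' another.
#'
#' @param seed master integer seed.
#' @param stream small integer index of the logical stream.
#' @return an integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  as.integer((s * 48271 + 7919 * as.double(stream) + 1) %% m)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_config <- function(...) {
  stop(structure(class = c("metabotyper_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop_config(msg)
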