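#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rbinom rnbinom sd var wilcox.test
#' @importFrom utils head read.delim write.table
NULL

# Normalize gene symbols: uppercase, strip surrounding whitespace.
norm_symbol <- function(x) toupper(trimws(as.character(x)))

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_rng_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Package-level logging; silenced with options(drivermod.verbose = FALSE).
dm_log <- function(fmt, ...) {
  if (isTRUE(getOption("drivermod.verbose", TRUE))) {
    message(sprintf(paste0("[drivermod] ", fmt), ...))
  }
}

dm_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "drivermod_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

config_error <- function(fmt, ...) dm_stop("drivermod_config_error", fmt, ...)
validation_error <- function(fmt, ...) dm_stop("drivermod_validation_error", fmt, ...)
domain_error <- function(fmt, ...) dm_stop("drivermod_domain_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
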