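# Internal helpers shared across modules.

#' @importFrom stats pchisq pnorm qnorm plogis rbinom runif uniroot setNames
#'   chisq.test fisher.test
#' @importFrom utils write.table read.table modifyList
NULL

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Deterministic sub-seed from a run seed and a stage name, so every stage
# draws from its own stream; kept below 2^31 (R integers are 32-bit) and
# mixed with multipliers small enough that the arithmetic stays exact in
# doubles (< 2^53).
stage_seed <- function(seed, stage) {
  h <- (abs(seed) %% 2147483647) + 1
  for (b in utf8ToInt(as.character(stage))) {
    h <- (h * 69069 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Rolling-polynomial hash of a character scalar, hex string; used to stamp
# outputs with a configuration fingerprint without extra dependencies.
fnv1a_hex <- function(x) {
  h <- 5381
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- (h * 33 + b) %% 4294967291
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

config_hash <- function(config) {
  # hash the scientific content only: where outputs land must not change
  # the fingerprint of the analysis
  core <- config[setdiff(names(config), "out_dir")]
  fnv1a_hex(paste(deparse(core), collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
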