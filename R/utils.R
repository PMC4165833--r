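# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed error so callers can condition on failure kind rather than message.
refugia_error <- function(kind, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("refugia_", kind), "refugia_error")))
}

refugia_warning <- function(kind, msg) {
  warning(warningCondition(msg,
    class = c(paste0("refugia_", kind), "refugia_warning")
  ))
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. All exported stochastic operations route through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed below 2^31, derived from (master seed, stage
# label) so that no two pipeline stages share an RNG stream.
derive_seed <- function(master_seed, stage) {
  h <- as.double(master_seed) %% 2147483647
  for (k in utf8ToInt(stage)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

HA_PER_M2 <- 1e-4
M2_PER_KM2 <- 1e6
HA_PER_KM2 <- 100
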