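# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds: master seed plus a small offset per
# replicate/stage, kept inside the 32-bit integer range.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) + as.numeric(offset)) %% .Machine$integer.max)
}

# Stage seeds keyed by name so every pipeline stage is independently
# reproducible from the one master seed.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  derive_seed(master, h)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
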