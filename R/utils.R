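# internal helpers shared across modules

# sprintf-style stop/warning/message without call noise
.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
.msgf  <- function(...) message(sprintf(...))

# Derived per-generator RNG streams: one shared integer seed plus a stream
# offset, kept inside 32-bit integer range so adding a generator never
# perturbs the draws of another.
.stream_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    .stopf("seed must be a single integer value, got %s", deparse(seed))
  }
  as.integer((abs(as.numeric(seed)) * 97L + 1009L * stream) %% 2147483647)
}

# numeric parser tolerant of comma decimals ("0,04" -> 0.04)
.as_num <- function(x) {
  if (is.numeric(x)) return(x)
  as.numeric(gsub(",", ".", trimws(as.character(x)), fixed = TRUE))
}

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
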