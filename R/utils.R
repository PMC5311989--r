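# internal helpers shared across modules

# round half away from zero, so 49.5 -> 50 like clinical tables print,
# rather than base R's round-half-even
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# coerce a positive/negative status column to logical (TRUE = positive)
as_binary_status <- function(x, what = "status") {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, NA))) {
      stop(sprintf("numeric %s must be 0/1", what), call. = FALSE)
    }
    return(x == 1)
  }
  x <- tolower(trimws(as.character(x)))
  pos <- c("positive", "pos", "1", "true", "yes", "mdd")
  neg <- c("negative", "neg", "0", "false", "no", "nomdd", "no_mdd")
  out <- rep(NA, length(x))
  out[x %in% pos] <- TRUE
  out[x %in% neg] <- FALSE
  if (anyNA(out[!is.na(x)])) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    stop(sprintf("unrecognized %s value(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

# 32-bit FNV-1a fingerprint of a configuration, for report provenance only.
# The 32-bit modular multiply is done with a 16-bit split so everything stays
# exactly representable in doubles.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(enc2utf8(as.character(s)))
  h <- 2166136261
  p_lo <- 16777619 %% 65536
  p_hi <- 16777619 %/% 65536
  for (b in bytes) {
    # xor in 16-bit halves: h exceeds the integer range bitwXor accepts
    h <- bitwXor(as.integer(h %/% 65536), as.integer(b %/% 65536)) * 65536 +
      bitwXor(as.integer(h %% 65536), as.integer(b %% 65536))
    h <- (h * p_lo + ((h * p_hi) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# run code with a local RNG state; leaves the caller's .Random.seed untouched
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
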