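#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Severity tiers, most severe first; rank 1 = emergency.
SEVERITY_LEVELS <- c("emergency", "severe", "moderate", "mild")

severity_rank <- function(tier) match(tier, SEVERITY_LEVELS)

#' @importFrom stats qnorm rbinom rlnorm rnorm runif setNames
#' @importFrom utils head modifyList
NULL

# FNV-1a 32-bit hash, done in double arithmetic (exact below 2^53).
# Used for stable, deterministic terminology code derivation.
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(x))) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # a < 2^32, b < 2^8: split a to stay inside bitwXor's integer range
  lo <- a %% 2^16
  hi <- a %/% 2^16
  hi * 2^16 + bitwXor(as.integer(lo), as.integer(b))
}

terminology_code <- function(id, version_id) {
  h <- fnv1a32(paste0(id, "@", version_id))
  # render as 8 hex digits without exceeding integer range
  sprintf("TT-%04X%04X", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# half-open interval membership [lo, hi)
in_band <- function(x, lo, hi) x >= lo & x < hi

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

as_chr <- function(x) as.character(unlist(x, use.names = FALSE)) %||% character(0)

# coerce a parsed document scalar to double (NULL passes through)
num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
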