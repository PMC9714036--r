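#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish failure modes.
tcaflux_error <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("tcaflux_", class, "_error"), "tcaflux_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_config     <- function(msg, ...) tcaflux_error("config", msg, ...)
stop_balance    <- function(msg, ...) tcaflux_error("balance", msg, ...)
stop_domain     <- function(msg, ...) tcaflux_error("domain", msg, ...)
stop_validation <- function(msg, ...) tcaflux_error("validation", msg, ...)
stop_data       <- function(msg, ...) tcaflux_error("data", msg, ...)
stop_lookup     <- function(msg, ...) tcaflux_error("lookup", msg, ...)
stop_schema     <- function(msg, ...) tcaflux_error("schema", msg, ...)
stop_index      <- function(msg, ...) tcaflux_error("index", msg, ...)
stop_integration <- function(msg, ...) tcaflux_error("integration", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a over the serialized object; stable provenance fingerprint.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  # skip the serialization header (encoding-dependent first 14 bytes)
  bytes <- bytes[-seq_len(min(14L, length(bytes)))]
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(b))
    # h * p mod 2^32, split to stay inside double precision
    hi <- floor(h / 65536)
    lo <- h - hi * 65536
    h <- ((hi * p) %% 65536 * 65536 + lo * p) %% 4294967296
  }
  paste0(format(as.hexmode(floor(h / 65536)), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
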