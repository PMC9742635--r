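`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# read a delimited table, sniffing tab vs comma from the header line
read_table_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

is_binary01 <- function(x) all(x %in% c(0, 1))

stop_mlnmr <- function(...) stop(..., call. = FALSE)

# deterministic per-chain / per-module seed derivation, kept under 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 104729) %% 2147483629) + 1L
}
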