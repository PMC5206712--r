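# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# truncate (not round) to two decimals; small guard absorbs binary
# representation error in values such as 0.66 * 2 / 6
trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

# directed edge identifier over node indices
edge_id <- function(from, to) paste(from, to, sep = "->")

# order-free key for an unordered pair of names
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "||"), paste(b, a, sep = "||"))
}

normalize_name <- function(x) tolower(trimws(as.character(x)))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
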