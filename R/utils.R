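#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

.up <- function(x) toupper(trimws(as.character(x)))

# Sniff tab vs comma from the first non-empty line.
.sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else ","
}

.read_delim <- function(path, ...) {
  utils::read.table(path, sep = .sniff_delim(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "", ...)
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
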