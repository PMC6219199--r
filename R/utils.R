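# internal helpers shared across modules

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Per-purpose RNG substreams derived from one master seed, so adding draws to
# one stage never perturbs another.  Kept below 2^31 - 1.
.substream <- function(seed, purpose) {
  offsets <- c(topology = 101, heights = 157, dispersal = 211,
               posterior = 307, fit = 401, misc = 503)
  .assert(purpose %in% names(offsets), "unknown RNG purpose '%s'", purpose)
  as.integer((as.numeric(seed) %% 2097143) * 1009 + offsets[[purpose]])
}

#' Format numbers to three significant figures
#'
#' Table output follows the convention that all estimates are printed to
#' three significant digits (node support values are excepted by the table
#' writer).  `NA` renders as an empty string.
#'
#' @param x numeric vector.
#' @return character vector.
#' @keywords internal
fmt_sig3 <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    format(signif(v, 3), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

# split a string on top-level commas (not inside braces or double quotes)
.split_top_commas <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L; inq <- FALSE; out <- character(0); buf <- character(0)
  for (ch in chars) {
    if (ch == '"') inq <- !inq
    if (!inq) {
      if (ch == "{") depth <- depth + 1L
      if (ch == "}") depth <- depth - 1L
      if (ch == "," && depth == 0L) {
        out <- c(out, paste(buf, collapse = "")); buf <- character(0)
        next
      }
    }
    buf <- c(buf, ch)
  }
  c(out, paste(buf, collapse = ""))
}

.num_or_char <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  if (!anyNA(y)) y else x
}
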