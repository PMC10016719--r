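# internal helpers shared across modules

# run `expr` under a fixed RNG seed without touching the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_if_not <- function(cond, msg, class = "neurochar_error") {
  if (!isTRUE(cond)) abort(msg, class = class)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# population (1/n) standard deviation; the clustering pipeline standardizes
# with the 1/n convention
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# md5 of a file, used by the run manifest
file_hash <- function(path) unname(tools::md5sum(path))
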