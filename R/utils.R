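#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# sample one element of x without the length-1 surprise of sample()
resample1 <- function(x) {
  if (length(x) == 0L) return(x)
  x[[sample.int(length(x), 1L)]]
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# deterministic, platform-independent hash of a string onto [0, 1)
key_fraction <- function(key) {
  x <- utf8ToInt(key)
  h <- 0
  for (v in x) h <- (h * 131 + v) %% 1048573
  h / 1048573
}
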