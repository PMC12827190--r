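# Shared helpers. All statistics in this package use the population (1/N)
# convention for means/SDs unless a function documents otherwise.

stopf <- function(fmt, ..., class = "mecg_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mecg_error")))
}

#' @noRd
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# glob -> regex anchored match over channel names
glob_match <- function(pattern, names) {
  grepl(utils::glob2rx(pattern), names)
}
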