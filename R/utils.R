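# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Stop with a message naming the offending argument.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(TRUE))
  check_that(is.numeric(x) && length(x) == 1 && is.finite(x),
             sprintf("'%s' must be a single finite number", name))
  check_that(x >= lower && x <= upper,
             sprintf("'%s' must be in [%s, %s]", name, lower, upper))
  invisible(TRUE)
}

check_flag01 <- function(x, name) {
  check_that(all(x %in% c(0L, 1L)),
             sprintf("'%s' must contain only 0/1 values", name))
  invisible(TRUE)
}

logit <- function(p) log(p / (1 - p))
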