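#' Validate CAS registry numbers
#'
#' A CAS registry number has the form `NNNNNNN-NN-R` (2 to 7 digits, 2
#' digits, 1 check digit). The check digit is the weighted sum of the other
#' digits -- rightmost digit times 1, next times 2, and so on -- modulo 10.
#'
#' @param cas character vector of candidate CAS numbers.
#' @return logical vector, `TRUE` where the string is well-formed and the
#'   check digit verifies.
#' @examples
#' cas_is_valid(c("23135-22-0", "50-00-0", "23135-22-1", "foo"))
#' @export
cas_is_valid <- function(cas) {
  ok <- grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)
  ok[is.na(cas)] <- FALSE
  if (!any(ok)) return(ok)
  check <- vapply(cas[ok], function(x) {
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    n <- length(digits)
    body <- digits[-n]
    sum(rev(body) * seq_along(body)) %% 10 == digits[n]
  }, logical(1))
  ok[ok] <- check
  ok
}

# Append the correct check digit to a digit string like "1234-56".
cas_complete <- function(stem) {
  digits <- as.integer(strsplit(gsub("-", "", stem), "")[[1]])
  check <- sum(rev(digits) * seq_along(digits)) %% 10
  paste0(stem, "-", check)
}
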