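#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x an `ethy_diff` object.
#' @param ... unused.
#' @return a plain tibble of per-feature calls.
#' @export
tidy.ethy_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ethy_diff")
  for (a in c("contrast", "min_fc", "alpha", "unit", "n_filtered")) {
    attr(out, a) <- NULL
  }
  as_tibble(out)
}

#' One-row summary of a differential-expression result
#'
#' @param x an `ethy_diff` object.
#' @param ... unused.
#' @return tibble with `n_tested`, `n_up`, `n_down`, `n_ns`, `min_fc`,
#'   `alpha`, `unit`.
#' @export
glance.ethy_diff <- function(x, ...) {
  tibble(n_tested = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"),
         n_ns = sum(x$direction == "ns"),
         min_fc = attr(x, "min_fc"),
         alpha = attr(x, "alpha"),
         unit = attr(x, "unit"))
}
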