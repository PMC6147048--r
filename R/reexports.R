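#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Turn analysis objects into tidy tibbles
#'
#' Broom-style tidiers for the package's result classes.
#'
#' @name tidy
#' @keywords internal
NULL

#' One-row summaries of analysis objects
#'
#' Broom-style glance methods for the package's result classes.
#'
#' @name glance
#' @keywords internal
NULL
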