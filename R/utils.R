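#' @importFrom rlang %||% .data
#' @importFrom dplyr bind_rows bind_cols
#' @importFrom purrr map imap map_dfr
#' @importFrom tibble tibble
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
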