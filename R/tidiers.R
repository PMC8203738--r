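#' Tidy an LSD result
#'
#' @param x An `lsd_result`.
#' @param ... Unused.
#' @return The per-class tibble (`hap_id`, `n`, `mean`, `sd`, `letter`).
#' @export
tidy.lsd_result <- function(x, ...) x$groups

#' @rdname tidy.lsd_result
#' @return `glance()`: one row with `n_groups`, `mse`, `df`, `alpha`,
#'   `n_significant_pairs`.
#' @export
glance.lsd_result <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$groups), mse = x$mse, df = x$df,
                 alpha = x$alpha, n_significant_pairs = sum(x$pairs$significant))
}

#' Tidy a haplotype network
#'
#' @param x A `haplotype_network`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `weight`).
#' @export
tidy.haplotype_network <- function(x, ...) x$edges

#' @rdname tidy.haplotype_network
#' @export
glance.haplotype_network <- function(x, ...) {
  tibble::tibble(n_observed = sum(x$nodes$type == "observed"),
                 n_median = sum(x$nodes$type == "median"),
                 n_edges = nrow(x$edges),
                 total_weight = sum(x$edges$weight))
}
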