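#' Tidiers for hspcfate result objects
#'
#' Broom-style accessors. `tidy()` returns the per-unit table of a result
#' (gap curve rows, correlation edges, transition-matrix cells); `glance()`
#' returns a one-row (or one-row-per-group) summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name hspcfate-tidiers
NULL

#' @rdname hspcfate-tidiers
#' @method tidy gap_stat
#' @export
tidy.gap_stat <- function(x, ...) x$table

#' @rdname hspcfate-tidiers
#' @method glance gap_stat
#' @export
glance.gap_stat <- function(x, ...) {
  tibble::tibble(
    k_selected = x$k_selected, k_max = x$k_max, n_refs = x$n_refs
  )
}

#' @rdname hspcfate-tidiers
#' @method tidy correlation_networks
#' @export
tidy.correlation_networks <- function(x, ...) x$edges

#' @rdname hspcfate-tidiers
#' @method glance correlation_networks
#' @export
glance.correlation_networks <- function(x, ...) x$counts

#' @rdname hspcfate-tidiers
#' @method tidy phenotype_transition
#' @export
tidy.phenotype_transition <- function(x, ...) {
  cnt <- as.data.frame.table(x$counts, responseName = "n")
  frq <- as.data.frame.table(x$freq, responseName = "freq")
  out <- dplyr::left_join(cnt, frq, by = c("mother", "daughter"))
  tibble::as_tibble(out)
}

#' @rdname hspcfate-tidiers
#' @method glance phenotype_transition
#' @export
glance.phenotype_transition <- function(x, ...) {
  tibble::tibble(
    n_edges = x$n_edges,
    n_no_data_rows = length(x$no_data_rows)
  )
}

#' @rdname hspcfate-tidiers
#' @method glance hspc_clusters
#' @export
glance.hspc_clusters <- function(x, ...) {
  km <- attr(x, "kmeans")
  tibble::tibble(k = km$k, inertia = km$inertia, seed = km$seed)
}
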