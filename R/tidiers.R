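#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a monomer inference result
#'
#' @param x A `monomer_inference` object.
#' @param ... Unused.
#' @return The monomer statistics tibble (one row per monomer).
#' @export
tidy.monomer_inference <- function(x, ...) x$monomers

#' One-row summary of a monomer inference result
#'
#' @param x A `monomer_inference` object.
#' @param ... Unused.
#' @return A one-row tibble: monomer counts by class, block status
#'   fractions, iterations, convergence flag.
#' @export
glance.monomer_inference <- function(x, ...) {
  tibble(
    n_monomers = nrow(x$monomers),
    n_frequent = sum(x$monomers$freq_class == "frequent"),
    n_rare = sum(x$monomers$freq_class == "rare"),
    n_blocks = nrow(x$blocks),
    frac_resolved = mean(x$blocks$status == "resolved"),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Tidy a HOR decomposition
#'
#' @param x A `hor_decomposition` or `super_hor_decomposition` object.
#' @param ... Unused.
#' @return The HOR definition tibble with the expansion flattened to a
#'   string column.
#' @export
tidy.hor_decomposition <- function(x, ...) {
  out <- x$hors
  out$expansion <- vapply(out$expansion, paste, character(1), collapse = "")
  out
}

#' @rdname tidy.hor_decomposition
#' @export
tidy.super_hor_decomposition <- tidy.hor_decomposition

#' One-row summary of a HOR decomposition
#'
#' @param x A `hor_decomposition` object.
#' @param ... Unused.
#' @return A one-row tibble: number of HORs by class, input monostring
#'   length, run-length-encoded decomposition length, compression factor.
#' @export
glance.hor_decomposition <- function(x, ...) {
  tibble(
    n_hors = nrow(x$hors),
    n_frequent = sum(x$hors$freq_class == "frequent"),
    input_length = length(x$input),
    rle_length = length(x$decomposition),
    compression = length(x$input) / max(1L, length(x$decomposition))
  )
}

#' Histogram of block divergences by status
#'
#' @param blocks Block tibble from [decompose()].
#' @param binwidth Histogram bin width on the divergence axis.
#' @return A ggplot object.
#' @export
plot_block_divergence <- function(blocks, binwidth = 0.01) {
  ggplot2::ggplot(blocks, ggplot2::aes(x = .data$div1, fill = .data$status)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "divergence to best monomer", y = "blocks",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_block_divergence HOR counts from a decomposition.
#' @param object A `hor_decomposition` object.
#' @param ... Unused.
#' @export
autoplot.hor_decomposition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$id, -.data$count),
                                   y = .data$count,
                                   fill = .data$freq_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "HOR", y = "count (units at substitution)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a monomer graph
#'
#' Deterministic circular layout; edge width scales with weight.
#'
#' @param object A `monomer_graph` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.monomer_graph <- function(object, ...) {
  v <- object$vertices
  n <- length(v)
  th <- 2 * pi * (seq_len(n) - 1L) / max(1L, n)
  pos <- tibble(id = v, x = cos(th), y = sin(th))
  e <- object$edges |>
    left_join(pos, by = c("from" = "id")) |>
    left_join(pos, by = c("to" = "id"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = pos, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$id)) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::theme_void()
}
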