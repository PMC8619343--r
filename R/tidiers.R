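#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Gath-Geva partition into one row per slot and cluster
#'
#' @param x A \code{gg_partition}.
#' @param ... Unused.
#' @return Tibble with \code{slot}, \code{cluster}, \code{membership} and
#'   the slot's crisp \code{label}.
#' @method tidy gg_partition
#' @export
tidy.gg_partition <- function(x, ...) {
  lab <- apply(x$U, 2, which.max)
  tidyr::expand_grid(slot = seq_len(ncol(x$U)), cluster = seq_len(x$k)) |>
    dplyr::mutate(membership = as.vector(t(x$U)),
                  label = rep(lab, each = x$k))
}

#' @rdname tidy.gg_partition
#' @method glance gg_partition
#' @export
glance.gg_partition <- function(x, ...) {
  tibble::tibble(k = x$k, cc = x$cc, afe = x$afe,
                 iterations = x$iterations, converged = x$converged)
}

#' @rdname tidy.gg_partition
#' @param object A \code{gg_partition}.
#' @method autoplot gg_partition
#' @export
autoplot.gg_partition <- function(object, ...) {
  d <- tidy.gg_partition(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slot, y = .data$membership,
                                  colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = "cluster", y = "membership degree",
                  x = "time slot") +
    ggplot2::theme_minimal()
}

#' Tidy a stage division into one row per stage
#' @param x A \code{stage_division}.
#' @param ... Unused.
#' @method tidy stage_division
#' @export
tidy.stage_division <- function(x, ...) x$ranges

#' @rdname tidy.stage_division
#' @method glance stage_division
#' @export
glance.stage_division <- function(x, ...) {
  tibble::tibble(best_k = x$best_k, cc = x$partition$cc,
                 afe = x$partition$afe,
                 iterations = x$partition$iterations)
}

#' @rdname tidy.stage_division
#' @param object A \code{stage_division}.
#' @method autoplot stage_division
#' @export
autoplot.stage_division <- function(object, ...) {
  autoplot.gg_partition(object$partition) +
    ggplot2::geom_vline(xintercept = object$ranges$end[-nrow(object$ranges)] +
                          0.5, linetype = "dashed", colour = "grey40")
}

#' Tidy a T-S FNN: one row per rule and consequent term
#' @param x A \code{tsfnn}.
#' @param ... Unused.
#' @method tidy tsfnn
#' @export
tidy.tsfnn <- function(x, ...) {
  h <- ncol(x$centers)
  terms <- c("(intercept)", paste0("x", seq_len(h)))
  tidyr::expand_grid(rule = seq_len(nrow(x$centers)), term = terms) |>
    dplyr::mutate(estimate = as.vector(t(x$consequents)))
}

#' @rdname tidy.tsfnn
#' @method glance tsfnn
#' @export
glance.tsfnn <- function(x, ...) {
  tibble::tibble(n_rules = nrow(x$centers), n_inputs = ncol(x$centers),
                 epochs = x$epochs_run,
                 final_error = utils::tail(x$trace, 1))
}

#' @rdname tidy.tsfnn
#' @param object A \code{tsfnn}.
#' @method autoplot tsfnn
#' @export
autoplot.tsfnn <- function(object, ...) {
  d <- tibble::tibble(epoch = seq_along(object$trace), error = object$trace)
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$error)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "mean epoch error", x = "epoch") +
    ggplot2::theme_minimal()
}

#' Tidy an environmental-parameter selection
#' @param x An \code{env_selection}.
#' @param ... Unused.
#' @method tidy env_selection
#' @export
tidy.env_selection <- function(x, ...) x$ranking

#' @rdname tidy.env_selection
#' @method glance env_selection
#' @export
glance.env_selection <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected), tse = x$tse,
                 total_time = x$total_time)
}

#' Tidy a node selection: the selection log
#' @param x A \code{node_selection}.
#' @param ... Unused.
#' @method tidy node_selection
#' @export
tidy.node_selection <- function(x, ...) {
  dplyr::select(x$selected, "id", "x", "y", "gd", "area_after")
}

#' @rdname tidy.node_selection
#' @method glance node_selection
#' @export
glance.node_selection <- function(x, ...) {
  tibble::tibble(n_selected = x$n_selected, area = x$area,
                 area_full = x$area_full, area_limit = x$area_limit)
}

#' @rdname tidy.node_selection
#' @param object A \code{node_selection}.
#' @param field Optional \code{sensor_field} to draw unselected nodes too.
#' @method autoplot node_selection
#' @export
autoplot.node_selection <- function(object, field = NULL, ...) {
  sel <- object$selected
  p <- ggplot2::ggplot()
  if (!is.null(field)) {
    p <- p + ggplot2::geom_point(
      data = field$nodes, ggplot2::aes(.data$x, .data$y),
      colour = "grey70", shape = 1)
  }
  circ <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    th <- seq(0, 2 * pi, length.out = 90)
    tibble::tibble(id = sel$id[i],
                   x = sel$x[i] + object$radius * cos(th),
                   y = sel$y[i] + object$radius * sin(th))
  })
  p + ggplot2::geom_path(data = circ,
                         ggplot2::aes(.data$x, .data$y, group = .data$id),
                         colour = "steelblue", alpha = 0.6) +
    ggplot2::geom_point(data = sel, ggplot2::aes(.data$x, .data$y),
                        colour = "steelblue") +
    ggplot2::coord_fixed(xlim = c(0, object$region[["width"]]),
                         ylim = c(0, object$region[["height"]])) +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a lifecycle dataset's growth indices over time
#' @param ds A \code{lifecycle_data}.
#' @return A ggplot.
#' @export
plot_lifecycle <- function(ds) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(ds)[, c("slot", "stage", attr(ds, "index_names"))],
    -c("slot", "stage"), names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$slot, .data$value,
                                     colour = .data$index)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time slot", y = "growth index value") +
    ggplot2::theme_minimal()
}
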