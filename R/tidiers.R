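#' Tidy and summarise result objects
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per conformer for screening, per step for selection traces and guided
#' runs), `glance()` a one-row summary.
#'
#' @param x A `fret_screen`, `fret_selection` or `guided_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.fret_screen <- function(x, ...) {
  x$stats
}

#' @rdname tidiers
#' @export
glance.fret_screen <- function(x, ...) {
  tibble::tibble(
    n_conformers = nrow(x$stats), n_selected = sum(x$stats$selected),
    n_dof = x$n_dof, best_chi2n = min(x$stats$chi2_n),
    max_rmsd_selected = x$max_rmsd_selected, converged = x$converged)
}

#' @rdname tidiers
#' @export
tidy.fret_selection <- function(x, ...) {
  x$trace
}

#' @rdname tidiers
#' @export
glance.fret_selection <- function(x, ...) {
  vals <- x$trace$expected_rmsd
  tibble::tibble(
    algorithm = x$algorithm, n_selected = length(x$selected),
    final_expected_rmsd = vals[length(vals)], stop = x$stop)
}

#' @rdname tidiers
#' @export
tidy.guided_run <- function(x, ...) {
  x$log
}

#' @rdname tidiers
#' @export
glance.guided_run <- function(x, ...) {
  tibble::tibble(
    n_iterations = nrow(x$log), n_accepted = sum(x$log$accepted),
    best_chi2n = x$best_chi2n, reached_target = x$reached_target,
    validation_chi2n = x$validation_chi2n %||% NA_real_, seed = x$seed)
}

#' Plot methods for result objects
#'
#' `autoplot.fret_screen()` shows the per-conformer normalized chi-squared
#' with the selection threshold; `autoplot.fret_selection()` the expected
#' model uncertainty against the number of chosen pairs (the
#' design curve); `autoplot.guided_run()` the chi2_n trace with the
#' annealing temperature.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name result-plots
NULL

#' @rdname result-plots
#' @export
autoplot.fret_screen <- function(object, ...) {
  df <- object$stats
  df$conformer <- factor(df$conformer, levels = df$conformer)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conformer, y = .data$chi2_n,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(chi[n]^2),
                  title = "FRET screening") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname result-plots
#' @export
autoplot.fret_selection <- function(object, ...) {
  df <- object$trace[!is.na(object$trace$expected_rmsd), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_pairs,
                                   y = .data$expected_rmsd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of FRET pairs",
                  y = "expected model uncertainty ⟨⟨RMSD⟩⟩ (Å)",
                  title = paste0("FRET-pair selection (", object$algorithm,
                                 ")")) +
    ggplot2::theme_minimal()
}

#' @rdname result-plots
#' @export
autoplot.guided_run <- function(object, ...) {
  df <- object$log
  scale <- max(df$chi2n) / max(df$kT)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$kT * scale), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$chi2n,
                                     colour = .data$accepted), size = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "iteration", y = expression(chi[n]^2),
                  title = "FRET-guided sampling",
                  subtitle = "grey: annealing kT (rescaled)") +
    ggplot2::theme_minimal()
}
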