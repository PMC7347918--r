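#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated session into its timecourse
#'
#' @param x An `hd_session`.
#' @param ... Unused.
#' @return The timecourse tibble (one row per output time).
#' @exportS3Method generics::tidy
tidy.hd_session <- function(x, ...) x$timecourse

#' One-row summary of a simulated session
#'
#' @param x An `hd_session`.
#' @param ... Unused.
#' @return A tibble with the session duration, infusion rate, end and
#'   initial concentrations, cumulative removal and elimination, and the
#'   worst mass-balance residual.
#' @exportS3Method generics::glance
glance.hd_session <- function(x, ...) {
  tc <- x$timecourse
  n <- nrow(tc)
  tibble::tibble(
    drug = x$scenario$toxic$name,
    duration_min = x$duration,
    Q_D_mL_min = x$Q_D,
    initial_conc_mgL = tc$plasma_total_toxic_mgL[1],
    end_conc_mgL = tc$plasma_total_toxic_mgL[n],
    removed_dialysate_mg = unname(x$removed_dialysate["toxic"]),
    eliminated_mg = unname(x$eliminated_endogenous["toxic"]),
    mass_residual = x$mass_residual,
    free_cap_margin = x$free_cap_margin
  )
}

#' Tidy a minimal-duration search into its evaluation trace
#'
#' @param x An `hd_min_duration`.
#' @param ... Unused.
#' @return A tibble of every candidate duration evaluated.
#' @exportS3Method generics::tidy
tidy.hd_min_duration <- function(x, ...) x$trace

#' One-row summary of a minimal-duration search
#'
#' @param x An `hd_min_duration`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.hd_min_duration <- function(x, ...) {
  tibble::tibble(
    drug = x$scenario$toxic$name,
    with_infusion = !is.null(x$scenario$infusion),
    min_duration_min = x$min_duration,
    censored = x$censored,
    rebound_peak_mgL = if (x$censored) NA_real_ else x$rebound$peak_mgL,
    step_min = x$step
  )
}

#' Plot plasma concentrations from a timecourse
#'
#' Total and free plasma concentrations of the toxic drug (and the
#' competitor when present) against time.
#'
#' @param object An `hd_timecourse`, `hd_session`, or `hd_rebound`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hd_timecourse <- function(object, ...) {
  keep <- intersect(c("plasma_total_toxic_mgL", "plasma_free_toxic_mgL",
                      "plasma_total_comp_mgL", "plasma_free_comp_mgL"),
                    names(object))
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  dplyr::all_of(c("time_min", keep))),
    -"time_min", names_to = "series", values_to = "conc_mgL")
  long$drug <- ifelse(grepl("toxic", long$series), "toxic drug",
                      "competitor")
  long$fraction <- ifelse(grepl("free", long$series), "free", "total")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_min, y = .data$conc_mgL, colour = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~drug, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "plasma concentration (mg/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.hd_timecourse
#' @exportS3Method ggplot2::autoplot
autoplot.hd_session <- function(object, ...) {
  p <- autoplot.hd_timecourse(object$timecourse)
  tr <- object$scenario$toxic$therapeutic_range
  if (!is.null(tr) && all(is.finite(tr))) {
    p <- p + ggplot2::geom_hline(yintercept = tr[2], linetype = "dashed")
  }
  p
}

#' @rdname autoplot.hd_timecourse
#' @exportS3Method ggplot2::autoplot
autoplot.hd_rebound <- function(object, ...) {
  autoplot.hd_timecourse(object$timecourse) +
    ggplot2::geom_vline(xintercept = object$t_peak_min, linetype = "dotted")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
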