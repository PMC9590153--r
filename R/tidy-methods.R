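#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a haplotyping result
#'
#' One row per block x individual, with the assignment as a compact
#' `haplotype` string (`code+code+...`).
#'
#' @param x A `hap_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hap_result <- function(x, ...) {
  asn <- x$assignments
  asn$haplotypes <- vapply(asn$ghap, function(g)
    if (is.null(g)) NA_character_ else hapcomb_chr(g), character(1L))
  asn[, c("block", "indiv", "category", "stage", "imputed", "assigned",
          "haplotypes")]
}

#' Glance at a haplotyping result
#'
#' @param x A `hap_result`.
#' @param ... Unused.
#' @return One-row tibble with overall counts and percentages.
#' @export
glance.hap_result <- function(x, ...) {
  asn <- x$assignments
  tibble::tibble(
    n_blocks = sum(is.na(x$blocks$error)),
    n_blocks_failed = sum(!is.na(x$blocks$error)),
    n_individuals = length(unique(asn$indiv)),
    pct_haplotyped = 100 * mean(asn$assigned),
    n_families_solved = sum(x$families$status == "solved"),
    n_families_demoted = sum(x$families$status == "demoted"),
    mean_n_haplotypes = mean(tapply(x$inventory$hap, x$inventory$block,
                                    length)))
}

#' Tidy a haplotyping summary
#'
#' @param x A `hap_summary`.
#' @param ... Unused.
#' @return The per-block, per-category tibble.
#' @export
tidy.hap_summary <- function(x, ...) x$by_block

#' Glance at a haplotyping summary
#'
#' @param x A `hap_summary`.
#' @param ... Unused.
#' @return The per-category overall tibble.
#' @export
glance.hap_summary <- function(x, ...) x$overall

#' Tidy a truth-based score
#'
#' @param x A `hap_score`.
#' @param ... Unused.
#' @return The per-block tibble.
#' @export
tidy.hap_score <- function(x, ...) x$by_block

#' Glance at a truth-based score
#'
#' @param x A `hap_score`.
#' @param ... Unused.
#' @return The one-row overall tibble.
#' @export
glance.hap_score <- function(x, ...) x$overall

#' Plot per-block haplotyping rates
#'
#' Bars of the percentage of individuals haplotyped per block, colored by
#' category of material.
#'
#' @param object A `hap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hap_result <- function(object, ...) {
  df <- object$assignments |>
    dplyr::group_by(.data$block, .data$category) |>
    dplyr::summarise(pct = 100 * mean(.data$assigned), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$pct,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% haplotyped", fill = "material") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot scoring results against truth
#'
#' Per-block percentages haplotyped and correct.
#'
#' @param object A `hap_score`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hap_score <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_block,
                            c("pct_haplotyped", "pct_correct"),
                            names_to = "metric", values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$pct,
                                   color = .data$metric, group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = "%", color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
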