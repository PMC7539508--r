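# broom-style accessors and ggplot2 autoplot methods for the result objects.

#' @method tidy seleno_result
#' @export
tidy.seleno_result <- function(x, ...) {
  select(x$calls, -"site_classes", -"secis")
}

#' @method glance seleno_result
#' @export
glance.seleno_result <- function(x, ...) {
  calls <- x$calls
  tibble(species = x$species, n_orfs = x$orf_count,
         n_candidates = x$candidate_count, n_calls = nrow(calls),
         n_sec = sum(calls$overall_class == "Sec" & !calls$pseudogene),
         n_cys = sum(calls$overall_class == "Cys" & !calls$pseudogene),
         n_other = sum(calls$overall_class == "Other" & !calls$pseudogene),
         n_pseudogene = sum(calls$pseudogene),
         n_with_secis = sum(calls$secis_count > 0),
         n_fusions = nrow(x$fusions))
}

#' @method tidy seleno_eval
#' @export
tidy.seleno_eval <- function(x, ...) x$metrics

#' @method glance seleno_eval
#' @export
glance.seleno_eval <- function(x, ...) {
  m <- x$metrics
  tibble(n_truth = sum(m$n_truth), n_called = sum(m$n_called),
         sec_sensitivity = m$sensitivity[m$class == "Sec"],
         pseudogene_sensitivity = m$sensitivity[m$class == "Pseudogene"],
         sec_cys_swaps = sum(
           x$matches$planted_class == "Sec" & x$matches$called_class == "Cys") +
           sum(x$matches$planted_class == "Cys" &
                 x$matches$called_class == "Sec"))
}

#' @method tidy seleno_matrix
#' @export
tidy.seleno_matrix <- function(x, ...) x$cells

#' @method tidy seleno_cohort
#' @export
tidy.seleno_cohort <- function(x, ...) x$truth

#' @method glance seleno_cohort
#' @export
glance.seleno_cohort <- function(x, ...) {
  count(x$truth, .data$species, .data$planted_class) |>
    tidyr::pivot_wider(names_from = "planted_class", values_from = "n",
                       values_fill = 0L)
}

#' Heatmap of a presence matrix
#'
#' Species by family tile plot of presence classes, ordered by the
#' deterministic double clustering.
#'
#' @param object A `seleno_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot seleno_matrix
#' @export
autoplot.seleno_matrix <- function(object, ...) {
  clu <- cluster_matrix(object)
  cells <- object$cells
  cells$species <- factor(cells$species, levels = clu$species_order)
  cells$family <- factor(cells$family, levels = clu$family_order)
  cells$presence <- factor(cells$presence, levels = PRESENCE_CLASSES)
  pal <- c(absent = "grey95", Sec = "#1b7837", Cys = "#e08214",
           Other = "grey55", `Sec&Cys` = "#7fbf7b", `Sec&Other` = "#66a61e",
           `Cys&Other` = "#fdb863", `Sec&Cys&Other` = "#a6dba0")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$species, y = .data$family,
                                      fill = .data$presence)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE,
                               name = "presence") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Confusion-matrix plot for a truth evaluation
#'
#' @param object A `seleno_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot seleno_eval
#' @export
autoplot.seleno_eval <- function(object, ...) {
  conf <- object$confusion
  ggplot2::ggplot(conf, ggplot2::aes(x = .data$called_class,
                                     y = .data$planted_class,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey70", high = "#1b7837") +
    ggplot2::labs(x = "called", y = "planted") +
    ggplot2::theme_minimal()
}

#' Per-class sensitivity/precision plot
#'
#' @param x A `seleno_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_eval_metrics <- function(x, ...) {
  m <- tidyr::pivot_longer(x$metrics, c("sensitivity", "precision"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$class, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @export
print.seleno_result <- function(x, ...) {
  g <- glance(x)
  cat("<seleno_result> species:", x$species, "\n")
  cat("  ORFs:", g$n_orfs, " candidates:", g$n_candidates,
      " calls:", g$n_calls, "\n")
  cat("  Sec:", g$n_sec, " Cys:", g$n_cys, " Other:", g$n_other,
      " pseudogenes:", g$n_pseudogene, " with SECIS:", g$n_with_secis, "\n")
  invisible(x)
}

#' @export
print.seleno_eval <- function(x, ...) {
  cat("<seleno_eval>\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' @export
print.seleno_matrix <- function(x, ...) {
  cat("<seleno_matrix>", length(x$species), "species x",
      length(x$families), "families\n")
  print(utils::head(as.data.frame(x$cells), 10), row.names = FALSE)
  invisible(x)
}

#' @export
print.seleno_cohort <- function(x, ...) {
  cat("<seleno_cohort>", x$spec$n_species, "species,",
      nrow(x$truth), "planted features\n")
  invisible(x)
}
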