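#' Tidy a profile HMM into a long position table
#'
#' @param x A [profile_hmm].
#' @param ... Unused.
#' @return Tibble with `position`, `residue`, `emission`, `consensus`.
#' @export
tidy.profile_hmm <- function(x, ...) {
  cons <- seq_chars(phmm_consensus(x))
  tibble::tibble(
    position = rep(seq_len(x$M), each = 20),
    residue = rep(AA20, times = x$M),
    emission = as.vector(t(x$match_emissions)),
    consensus = rep(cons, each = 20)
  )
}

#' One-row model summary
#'
#' @param x A [profile_hmm].
#' @param ... Unused.
#' @return One-row tibble: `name`, `class_tag`, `n_states`,
#'   `calibrated`, `gumbel_mu`, `gumbel_lambda`, `trusted_cutoff`,
#'   `expected_length`.
#' @export
glance.profile_hmm <- function(x, ...) {
  tibble::tibble(
    name = x$name, class_tag = x$class_tag, n_states = x$M,
    calibrated = !is.na(x$gumbel_mu),
    gumbel_mu = x$gumbel_mu, gumbel_lambda = x$gumbel_lambda,
    trusted_cutoff = x$trusted_cutoff,
    expected_length = phmm_expected_length(x)
  )
}

#' Emission heat map of a profile HMM
#'
#' @param object A [profile_hmm].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_hmm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$emission)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "p(match)") +
    ggplot2::labs(title = object$name, x = "match state", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy an SSN into its edge table
#'
#' @param x An `rre_ssn`.
#' @param ... Unused.
#' @return Edge tibble (`id_a`, `id_b`, `alignment_score`).
#' @export
tidy.rre_ssn <- function(x, ...) x$edges

#' One-row SSN summary
#'
#' @param x An `rre_ssn`.
#' @param ... Unused.
#' @return One-row tibble: node/edge/component counts, threshold,
#'   RepNode identity.
#' @export
glance.rre_ssn <- function(x, ...) {
  tibble::tibble(
    nodes = igraph::vcount(x$graph),
    edges = igraph::ecount(x$graph),
    components = igraph::components(x$graph)$no,
    threshold = x$threshold,
    repnode_identity = x$repnode_identity
  )
}

#' Plot an SSN layout
#'
#' Fruchterman-Reingold layout of the network, components coloured.
#'
#' @param object An `rre_ssn`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rre_ssn <- function(object, seed = 1, ...) {
  g <- object$graph
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  comp <- igraph::components(g)$membership
  nodes <- tibble::tibble(id = igraph::V(g)$name,
                          x = xy[, 1], y = xy[, 2],
                          component = factor(comp))
  edges <- object$edges
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(edges) > 0) {
    e <- dplyr::left_join(edges, nodes[, c("id", "x", "y")],
                          by = c(id_a = "id")) |>
      dplyr::left_join(nodes[, c("id", "x", "y")], by = c(id_b = "id"),
                       suffix = c("", "_b"))
    p <- p + ggplot2::geom_segment(
      data = e, ggplot2::aes(x = .data$x, y = .data$y,
                             xend = .data$x_b, yend = .data$y_b),
      colour = "grey70", linewidth = 0.3)
  }
  p + ggplot2::geom_point(ggplot2::aes(colour = .data$component), size = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("SSN (alignment score >= %s)",
                                  object$threshold))
}

#' Tidy a validation table
#'
#' @param x An `rre_validation`.
#' @param ... Unused.
#' @return The per-tier tibble.
#' @export
tidy.rre_validation <- function(x, ...) x$per_tier

#' Per-tier validation counts plot
#'
#' @param object An `rre_validation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rre_validation <- function(object, ...) {
  df <- object$per_tier |>
    tidyr::pivot_longer(cols = c("hits_in_positive_loci",
                                 "hits_in_negative_loci"),
                        names_to = "label", values_to = "count") |>
    dplyr::mutate(tier = factor(.data$tier,
                                levels = c("tolerant", "moderate", "stringent")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tier, y = .data$count,
                                   fill = .data$label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(hits_in_positive_loci = "#2c7fb8",
                 hits_in_negative_loci = "#d95f0e"),
      labels = c("RiPP loci", "non-RiPP loci"), name = NULL) +
    ggplot2::labs(x = "bit-score tier", y = "hits") +
    ggplot2::theme_minimal()
}
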