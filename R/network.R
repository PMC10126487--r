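# Directed interaction networks: aggregate coupling scores over replicate
# runs into a weighted donor -> recipient edge list, restrict to the species
# detected at a time point, and flag edges lying on feedback loops.

#' Detect species present at a day
#'
#' @param series Abundance series tibble.
#' @param day Day label (must be present in the series).
#' @param min_abundance Detection threshold \eqn{\theta}; a species is
#'   detected when its abundance is at least \eqn{\theta} and positive
#'   (default 0, i.e. presence).
#' @return Character vector of detected species ids.
#' @export
detect_nodes <- function(series, day, min_abundance = 0) {
  validate_series(series)
  day <- as.integer(day)
  hit <- series[series$day == day, , drop = FALSE]
  if (nrow(hit) == 0) stop_invalid(sprintf("day %d is not in the series", day))
  theta <- max(check_nonneg(min_abundance, "min_abundance"), .Machine$double.xmin)
  unique(hit$species[hit$abundance >= theta])
}

#' Build a directed interaction network from replicate coupling runs
#'
#' Keeps a donor -> recipient edge when the mean coupling score across runs
#' exceeds the threshold `tau` and both endpoints are detected; attaches the
#' across-run mean and standard deviation as edge weights and flags edges
#' that lie on feedback loops (both endpoints in one strongly connected
#' component of size >= 2, or self-loops). Arrows follow metabolite flow,
#' donor to recipient.
#'
#' @param runs A `coupling_runs` object (or a single `coupling_result`).
#' @param tau Edge threshold on the mean coupling score (default 0: any
#'   positive mean score creates an edge).
#' @param detected Node set to restrict to (default: all species in the runs).
#' @param day Optional integer day label carried in the result.
#' @return An object of class `interaction_network`: list with `nodes`,
#'   `edges` (tibble `donor`, `recipient`, `weight_mean`, `weight_sd`,
#'   `is_loop`) and `day`.
#' @export
build_network <- function(runs, tau = 0, detected = NULL, day = NA_integer_) {
  if (inherits(runs, "coupling_result")) {
    summary <- runs$scs %>%
      rename(scs_mean = "scs") %>%
      mutate(scs_sd = 0)
  } else if (inherits(runs, "coupling_runs")) {
    summary <- runs$summary
  } else if (is.data.frame(runs) &&
             all(c("donor", "recipient", "scs_mean") %in% names(runs))) {
    summary <- as_tibble(runs)
    if (!"scs_sd" %in% names(summary)) summary$scs_sd <- 0
  } else {
    stop_invalid("`runs` must be coupling_runs, coupling_result, or a summary data frame")
  }
  tau <- check_fraction(tau, "tau")
  all_species <- sort(unique(c(summary$donor, summary$recipient)))
  detected <- as.character(detected %||% all_species)
  edges <- summary %>%
    filter(.data$scs_mean > tau,
           .data$donor %in% detected, .data$recipient %in% detected) %>%
    select("donor", "recipient",
           weight_mean = "scs_mean", weight_sd = "scs_sd") %>%
    distinct(.data$donor, .data$recipient, .keep_all = TRUE) %>%
    arrange(.data$donor, .data$recipient)
  net <- structure(
    list(nodes = detected, edges = edges, day = as.integer(day), tau = tau),
    class = "interaction_network"
  )
  net$edges$is_loop <- flag_loop_edges(net)
  net
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> day %s: %d nodes, %d edges (%d on loops)\n",
              ifelse(is.na(x$day), "?", x$day), length(x$nodes),
              nrow(x$edges), sum(x$edges$is_loop)))
  invisible(x)
}

#' @export
tidy.interaction_network <- function(x, ...) {
  mutate(x$edges, day = x$day, .before = 1)
}

#' Convert an interaction network (or edge list) to igraph
#'
#' @param x An `interaction_network`, a two-column (`from`/`donor`,
#'   `to`/`recipient`) data frame, or an igraph object (returned as is).
#' @param nodes Optional node set including isolated vertices.
#' @return An igraph directed graph.
#' @export
as_dependency_graph <- function(x, nodes = NULL) {
  if (igraph::is_igraph(x)) return(x)
  if (inherits(x, "interaction_network")) {
    return(igraph::graph_from_data_frame(
      x$edges[, c("donor", "recipient")], directed = TRUE, vertices = x$nodes))
  }
  if (is.data.frame(x)) {
    el <- x[, 1:2, drop = FALSE]
    verts <- nodes %||% sort(unique(c(as.character(el[[1]]), as.character(el[[2]]))))
    return(igraph::graph_from_data_frame(el, directed = TRUE, vertices = verts))
  }
  stop_invalid("cannot interpret `x` as a directed graph")
}

# Loop flags for the network's own edge list.
flag_loop_edges <- function(net) {
  if (nrow(net$edges) == 0) return(logical(0))
  g <- as_dependency_graph(net)
  comp <- igraph::components(g, mode = "strong")
  member <- comp$membership[net$edges$donor]
  same <- member == comp$membership[net$edges$recipient]
  big <- comp$csize[member] >= 2
  self <- net$edges$donor == net$edges$recipient
  (same & big) | self
}

#' Edges lying on feedback loops
#'
#' Exactly the edges whose two endpoints share a strongly connected
#' component of size at least two, plus self-loops. The set is empty if and
#' only if the graph is acyclic (orderability 1).
#'
#' @param net An `interaction_network`.
#' @return The subset of `net$edges` on loops.
#' @export
loop_edges <- function(net) {
  if (!inherits(net, "interaction_network")) {
    stop_invalid("`net` must be an interaction_network")
  }
  net$edges[net$edges$is_loop, , drop = FALSE]
}

#' Write a network edge list as TSV or GraphML
#'
#' The TSV carries (day, donor, recipient, weight_mean, weight_sd, is_loop);
#' GraphML export keeps the same edge attributes.
#'
#' @param net An `interaction_network`.
#' @param path Output file path.
#' @export
write_network_tsv <- function(net, path) {
  readr::write_tsv(tidy(net), path)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  g <- as_dependency_graph(net)
  if (nrow(net$edges) > 0) {
    igraph::E(g)$weight_mean <- net$edges$weight_mean
    igraph::E(g)$weight_sd <- net$edges$weight_sd
    igraph::E(g)$is_loop <- net$edges$is_loop
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network edge-list TSV written by [write_network_tsv()]
#'
#' @param path File path.
#' @return An `interaction_network`.
#' @export
read_network_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  day <- if ("day" %in% names(df) && nrow(df) > 0) df$day[1] else NA_integer_
  build_network(
    tibble(donor = as.character(df$donor), recipient = as.character(df$recipient),
           scs_mean = df$weight_mean, scs_sd = df$weight_sd),
    tau = 0, day = day
  )
}

#' @export
autoplot.interaction_network <- function(object, ...) {
  g <- as_dependency_graph(object)
  # fixed layout seed so plots are reproducible; analysis never depends on it
  xy <- withr::with_seed(1L, igraph::layout_with_fr(g))
  nodes <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(object$edges) > 0) {
    edges <- object$edges %>%
      left_join(nodes, by = c(donor = "name")) %>%
      left_join(nodes, by = c(recipient = "name"), suffix = c("", "_to"))
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to,
                   alpha = .data$weight_mean,
                   colour = .data$is_loop),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in")),
      linewidth = 0.6
    ) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                   name = "feedback loop")
  }
  p +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(title = if (!is.na(object$day)) sprintf("Day %d", object$day))
}
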