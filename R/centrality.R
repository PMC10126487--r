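# Keystone-species ranking on directed interaction networks: influence
# (reaching) centrality for upstream "supply chain" positions, PageRank for
# sink positions accumulating inward links.

#' Influence (local reaching) centrality
#'
#' For each node, the fraction of other nodes reachable from it along
#' directed edges: \eqn{I(v) = |\{u \ne v : v \leadsto u\}| / (N - 1)}.
#' Species at the source of a metabolite supply chain score near 1; pure
#' sinks score 0. Edge weights are ignored (reachability only).
#'
#' @inheritParams condense
#' @return Named numeric vector of influence scores in \[0, 1\].
#' @examples
#' chain <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"))
#' influence_centrality(chain) # 1, 2/3, 1/3, 0
#' @export
influence_centrality <- function(graph, nodes = NULL) {
  g <- as_dependency_graph(graph, nodes = nodes)
  n <- igraph::vcount(g)
  if (n < 2) stop_invalid("influence centrality needs at least two nodes")
  d <- igraph::distances(g, mode = "out", algorithm = "unweighted")
  reach <- rowSums(is.finite(d)) - 1L
  setNames(reach / (n - 1), igraph::V(g)$name)
}

#' PageRank centrality by damped power iteration
#'
#' Standard PageRank on the directed graph: a random surfer follows an
#' outgoing edge with probability `damping` (uniformly, or proportionally to
#' edge weights when supplied) and teleports uniformly otherwise; mass on
#' dangling (out-degree-0) nodes is redistributed uniformly. Iterated until
#' the L1 change drops below `tol`. Scores sum to one; species that many
#' well-linked species point at (metabolite sinks) score high.
#'
#' @inheritParams condense
#' @param damping Damping factor d (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap; exceeding it is an error carrying the last
#'   L1 change as diagnostics.
#' @param weights Optional per-edge weight vector (in edge-list order) used
#'   as transition probabilities; default unweighted.
#' @param start Optional initial distribution (named or in vertex order);
#'   default uniform. Convergence is independent of it.
#' @return Named numeric vector of PageRank scores summing to 1, with
#'   attribute `iterations`.
#' @export
pagerank <- function(graph, nodes = NULL, damping = 0.85, tol = 1e-10,
                     max_iter = 1000, weights = NULL, start = NULL) {
  g <- as_dependency_graph(graph, nodes = nodes)
  n <- igraph::vcount(g)
  if (n < 1) stop_invalid("PageRank needs at least one node")
  d <- check_fraction(damping, "damping")
  ids <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  w <- as.numeric(weights %||% rep(1, nrow(el)))
  if (length(w) != nrow(el) || any(w < 0)) {
    stop_invalid("`weights` must be non-negative, one per edge")
  }
  from <- match(el[, 1], ids)
  to <- match(el[, 2], ids)
  out_strength <- as.numeric(tapply(w, factor(from, levels = seq_len(n)), sum))
  out_strength[is.na(out_strength)] <- 0
  x <- if (is.null(start)) rep(1 / n, n) else {
    s <- if (!is.null(names(start))) as.numeric(start[ids]) else as.numeric(start)
    s / sum(s)
  }
  dangling <- out_strength == 0
  for (iter in seq_len(check_count(max_iter, "max_iter"))) {
    inflow <- numeric(n)
    ok <- out_strength[from] > 0
    if (any(ok)) {
      contrib <- x[from[ok]] * w[ok] / out_strength[from[ok]]
      inflow <- as.numeric(tapply(contrib, factor(to[ok], levels = seq_len(n)), sum))
      inflow[is.na(inflow)] <- 0
    }
    x_new <- (1 - d) / n + d * (inflow + sum(x[dangling]) / n)
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tol) {
      return(structure(setNames(x, ids), iterations = iter))
    }
  }
  abort(sprintf("PageRank did not converge in %d iterations (last L1 change %.3e)",
                max_iter, delta),
        class = "facilinet_no_convergence")
}

#' Per-network centrality report
#'
#' @param net An `interaction_network`.
#' @param damping PageRank damping factor.
#' @param weighted Use mean coupling scores as PageRank transition weights
#'   (default `FALSE`, mirroring the unweighted ranking question).
#' @return A tibble with columns `day`, `species`, `influence`, `pagerank`.
#' @export
centrality_report <- function(net, damping = 0.85, weighted = FALSE) {
  if (!inherits(net, "interaction_network")) {
    stop_invalid("`net` must be an interaction_network")
  }
  g <- as_dependency_graph(net)
  w <- if (weighted && nrow(net$edges) > 0) net$edges$weight_mean else NULL
  pr <- pagerank(g, damping = damping, weights = w)
  infl <- influence_centrality(g)
  tibble(day = net$day, species = igraph::V(g)$name,
         influence = unname(infl[igraph::V(g)$name]),
         pagerank = unname(pr[igraph::V(g)$name]))
}

#' Keystone ranking across days and runs
#'
#' Aggregates per-day (optionally per-run) centrality reports into a
#' per-species summary: mean and standard deviation of influence and
#' PageRank, with ranks by each. Species consistently at the top of the
#' influence ranking are keystone candidates — upstream taxa whose
#' secretions many others depend on, possibly despite low abundance.
#'
#' @param reports A data frame binding one or more [centrality_report()]
#'   outputs (columns `day`, `species`, `influence`, `pagerank`; an optional
#'   `run` column is treated as extra replication).
#' @param top_k Rows to keep in the printed top tables (default 5).
#' @return An object of class `keystone_summary`: a tibble with per-species
#'   `influence_mean/sd`, `pagerank_mean/sd`, `n_obs`, `rank_influence`,
#'   `rank_pagerank`; attribute `top_k`.
#' @export
keystone_ranking <- function(reports, top_k = 5) {
  if (!is.data.frame(reports) ||
      !all(c("species", "influence", "pagerank") %in% names(reports))) {
    stop_invalid("`reports` needs columns species, influence, pagerank")
  }
  out <- reports %>%
    group_by(.data$species) %>%
    summarise(
      influence_mean = mean(.data$influence),
      influence_sd = if (n() > 1) sd(.data$influence) else 0,
      pagerank_mean = mean(.data$pagerank),
      pagerank_sd = if (n() > 1) sd(.data$pagerank) else 0,
      n_obs = n(),
      .groups = "drop"
    ) %>%
    mutate(
      rank_influence = rank(-.data$influence_mean, ties.method = "min"),
      rank_pagerank = rank(-.data$pagerank_mean, ties.method = "min")
    ) %>%
    arrange(.data$rank_influence)
  attr(out, "top_k") <- check_count(top_k, "top_k")
  class(out) <- c("keystone_summary", class(out))
  out
}

#' @export
print.keystone_summary <- function(x, ...) {
  k <- attr(x, "top_k") %||% 5L
  cat(sprintf("<keystone_summary> %d species; top %d by influence:\n", nrow(x), k))
  print(as_tibble(head(x, k)))
  invisible(x)
}

#' @export
autoplot.keystone_summary <- function(object, ...) {
  df <- as_tibble(object) %>%
    tidyr::pivot_longer(c("influence_mean", "pagerank_mean"),
                        names_to = "metric", values_to = "value") %>%
    mutate(metric = sub("_mean$", "", .data$metric))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$species, .data$value), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "mean centrality") +
    ggplot2::theme_minimal()
}
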