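# Hierarchy metrics on directed graphs: orderability, and the entropy-based
# treeness / feedforwardness computed on the strongly-connected-component
# condensation. These diagnose feedback loops (low orderability), pyramidal
# top-down organisation (treeness near +1) and upstream-downstream bias
# (feedforwardness near 1) of inferred dependency networks.

#' Condense a directed graph into its DAG of strongly connected components
#'
#' Nodes of the condensation are the SCCs of the input, weighted by their
#' size \eqn{\alpha(v)}; edges are the deduplicated induced edges between
#' distinct SCCs. Self-loops make a singleton SCC count as cyclic but are
#' dropped from the condensation DAG.
#'
#' @param graph An `interaction_network`, igraph object, or edge-list data
#'   frame (first two columns: from, to).
#' @param nodes Optional node set (to keep isolated vertices).
#' @return An object of class `condensation`: list with `dag` (igraph DAG),
#'   `alpha` (named SCC sizes), `membership` (original node -> SCC id),
#'   `cyclic` (named logical: SCC of size >= 2 or self-looped singleton),
#'   `n_original`.
#' @export
condense <- function(graph, nodes = NULL) {
  g <- as_dependency_graph(graph, nodes = nodes)
  if (igraph::vcount(g) == 0) stop_invalid("cannot condense an empty graph")
  comp <- igraph::components(g, mode = "strong")
  scc_ids <- sprintf("scc_%d", seq_len(comp$no))
  membership <- setNames(scc_ids[comp$membership], igraph::V(g)$name)
  alpha <- setNames(as.integer(comp$csize), scc_ids)
  el <- igraph::as_edgelist(g)
  self_looped <- unique(el[el[, 1] == el[, 2], 1])
  cyclic <- setNames(alpha >= 2, scc_ids)
  cyclic[membership[self_looped]] <- TRUE
  dag_el <- unique(cbind(membership[el[, 1]], membership[el[, 2]]))
  dag_el <- dag_el[dag_el[, 1] != dag_el[, 2], , drop = FALSE]
  dag <- igraph::graph_from_data_frame(
    as.data.frame(dag_el, stringsAsFactors = FALSE),
    directed = TRUE, vertices = scc_ids)
  structure(
    list(dag = dag, alpha = alpha, membership = membership, cyclic = cyclic,
         n_original = igraph::vcount(g)),
    class = "condensation"
  )
}

#' @export
print.condensation <- function(x, ...) {
  cat(sprintf("<condensation> %d SCCs over %d nodes (%d cyclic)\n",
              length(x$alpha), x$n_original, sum(x$cyclic)))
  invisible(x)
}

#' Orderability: fraction of nodes outside feedback loops
#'
#' The proportion of nodes lying in acyclic singleton SCCs (size one, no
#' self-loop). 1 means the graph is loop-free; 0 means every node sits on a
#' directed feedback loop.
#'
#' @inheritParams condense
#' @return Orderability in \[0, 1\].
#' @examples
#' cyc <- data.frame(from = c("a","b","c","d","e"), to = c("b","c","d","e","a"))
#' orderability(cyc) # 0: the loop involves every node
#' @export
orderability <- function(graph, nodes = NULL) {
  cond <- if (inherits(graph, "condensation")) graph else condense(graph, nodes)
  sum(cond$alpha[!cond$cyclic & cond$alpha == 1L]) / cond$n_original
}

# Per-node forward path entropy on a DAG, in bits: 0 at sinks, else
# log2(k_out) plus the mean entropy of the successors.
node_entropies <- function(dag) {
  n <- igraph::vcount(dag)
  h <- setNames(numeric(n), igraph::V(dag)$name)
  order <- igraph::topo_sort(dag, mode = "in")$name  # sinks first
  for (v in order) {
    succ <- igraph::neighbors(dag, v, mode = "out")$name
    k <- length(succ)
    if (k > 0) h[v] <- log2(k) + mean(h[succ])
  }
  h
}

#' Forward and backward path entropies of a condensation
#'
#' The forward entropy H_f is the mean, over maximal (in-degree-0) SCCs, of
#' the uncertainty (in bits) of a downstream path taken with uniform
#' branching; the backward entropy H_b is the same quantity on the
#' edge-reversed DAG. A pyramid fans out going down (H_f > H_b); an inverted
#' pyramid concentrates (H_f < H_b).
#'
#' @param cond A `condensation` (or anything [condense()] accepts).
#' @return Named numeric `c(H_f =, H_b =)` in bits.
#' @export
path_entropies <- function(cond) {
  if (!inherits(cond, "condensation")) cond <- condense(cond)
  dag_entropies(cond$dag)
}

dag_entropies <- function(dag) {
  if (igraph::vcount(dag) == 0) return(c(H_f = 0, H_b = 0))
  h_f <- node_entropies(dag)
  h_b <- node_entropies(igraph::reverse_edges(dag))
  maximal <- igraph::V(dag)$name[igraph::degree(dag, mode = "in") == 0]
  minimal <- igraph::V(dag)$name[igraph::degree(dag, mode = "out") == 0]
  c(H_f = mean(h_f[maximal]), H_b = mean(h_b[minimal]))
}

# Entropy asymmetry ratio of one DAG; 0 when both entropies vanish.
f_ratio <- function(dag) {
  h <- dag_entropies(dag)
  if (max(h) == 0) return(0)
  unname((h["H_f"] - h["H_b"]) / max(h))
}

#' Treeness: entropy asymmetry averaged over leaf-removal sequences
#'
#' On the condensation \eqn{g_0}, the asymmetry
#' \eqn{f(g) = (H_f - H_b) / \max(H_f, H_b)} (0 when both entropies vanish)
#' is computed and then averaged over a leaf-removal schedule. The default
#' schedule (`prune = "both"`) follows \eqn{g_0} with two independent
#' sequences — iteratively deleting the minimal (out-degree-0) nodes, and
#' iteratively deleting the maximal (in-degree-0) nodes — each stopping when
#' its graph becomes empty or edgeless. Averaging over both sequences makes
#' treeness exactly antisymmetric under edge reversal, which the one-sided
#' schedule (`prune = "minimal"`, also available) is not. +1 indicates
#' pyramidal top-down structure, -1 its inversion, 0 neither.
#'
#' @inheritParams condense
#' @param prune Leaf-removal schedule: `"both"` (default) or `"minimal"`.
#' @return Treeness in \[-1, 1\] with attribute `f_steps` (the per-step
#'   \eqn{f(g_k)} values, \eqn{f(g_0)} first).
#' @export
treeness <- function(graph, nodes = NULL, prune = c("both", "minimal")) {
  prune <- match.arg(prune)
  cond <- if (inherits(graph, "condensation")) graph else condense(graph, nodes)
  prune_seq <- function(dag, mode) {
    fs <- numeric(0)
    repeat {
      drop <- igraph::V(dag)$name[igraph::degree(dag, mode = mode) == 0]
      dag <- igraph::delete_vertices(dag, drop)
      if (igraph::vcount(dag) == 0 || igraph::ecount(dag) == 0) break
      fs <- c(fs, f_ratio(dag))
    }
    fs
  }
  f_steps <- c(f_ratio(cond$dag), prune_seq(cond$dag, "out"))
  if (prune == "both") f_steps <- c(f_steps, prune_seq(cond$dag, "in"))
  structure(mean(f_steps), f_steps = f_steps)
}

#' Feedforwardness: how much of each top-to-bottom path is loop-free
#'
#' Every directed path of the condensation from a maximal (in-degree-0) SCC
#' to a minimal (out-degree-0) SCC scores \eqn{f(\pi) = |\pi| / \sum_{v \in
#' \pi} \alpha(v)}: the number of SCCs on the path over the number of
#' original nodes they contain. Feedforwardness is the mean over all such
#' paths (isolated SCCs contribute their trivial one-node path). It is 1
#' exactly on loop-free graphs and shrinks as larger cycles sit on the
#' paths.
#'
#' @inheritParams condense
#' @param max_paths Abort (with an error suggesting subsampling) if the
#'   number of maximal-to-minimal paths exceeds this bound (default 1e5).
#' @return Feedforwardness in (0, 1\].
#' @export
feedforwardness <- function(graph, nodes = NULL, max_paths = 1e5) {
  cond <- if (inherits(graph, "condensation")) graph else condense(graph, nodes)
  dag <- cond$dag
  alpha <- cond$alpha
  maximal <- igraph::V(dag)$name[igraph::degree(dag, mode = "in") == 0]
  succ <- lapply(setNames(igraph::V(dag)$name, igraph::V(dag)$name),
                 function(v) igraph::neighbors(dag, v, mode = "out")$name)
  n_paths <- 0L
  f_sum <- 0
  walk <- function(v, len, asum) {
    nxt <- succ[[v]]
    if (length(nxt) == 0) {
      n_paths <<- n_paths + 1L
      if (n_paths > max_paths) {
        abort(sprintf("more than %d maximal-to-minimal paths; raise `max_paths` or subsample the graph", max_paths),
              class = "facilinet_path_explosion")
      }
      f_sum <<- f_sum + len / asum
      return(invisible())
    }
    for (u in nxt) walk(u, len + 1L, asum + alpha[[u]])
  }
  for (v in maximal) walk(v, 1L, alpha[[v]])
  f_sum / n_paths
}

#' Full hierarchy report for one network
#'
#' Computes treeness, feedforwardness and orderability together with the
#' top-level path entropies and the leaf-removal depth used by treeness.
#'
#' @inheritParams feedforwardness
#' @param day Optional day label carried into the report.
#' @return An object of class `hierarchy_report` (also a list) with fields
#'   `treeness`, `feedforwardness`, `orderability`, `H_f`, `H_b`, `depth`,
#'   `f_steps`, `n_nodes`, `day`.
#' @export
hierarchy_report <- function(graph, nodes = NULL, day = NA_integer_,
                             max_paths = 1e5) {
  cond <- if (inherits(graph, "condensation")) graph else condense(graph, nodes)
  tr <- treeness(cond)
  h <- path_entropies(cond)
  structure(
    list(
      treeness = as.numeric(tr),
      feedforwardness = feedforwardness(cond, max_paths = max_paths),
      orderability = orderability(cond),
      H_f = unname(h["H_f"]),
      H_b = unname(h["H_b"]),
      depth = length(attr(tr, "f_steps")) - 1L,
      f_steps = attr(tr, "f_steps"),
      n_nodes = cond$n_original,
      day = as.integer(day)
    ),
    class = "hierarchy_report"
  )
}

#' @export
print.hierarchy_report <- function(x, ...) {
  cat(sprintf("<hierarchy_report>%s %d nodes: T = %.3f, F = %.3f, O = %.3f\n",
              ifelse(is.na(x$day), "", sprintf(" day %d,", x$day)),
              x$n_nodes, x$treeness, x$feedforwardness, x$orderability))
  invisible(x)
}

#' @export
tidy.hierarchy_report <- function(x, ...) {
  tibble(metric = c("treeness", "feedforwardness", "orderability", "H_f", "H_b"),
         value = c(x$treeness, x$feedforwardness, x$orderability, x$H_f, x$H_b))
}

#' @export
glance.hierarchy_report <- function(x, ...) {
  tibble(day = x$day, n_nodes = x$n_nodes, treeness = x$treeness,
         feedforwardness = x$feedforwardness, orderability = x$orderability,
         H_f = x$H_f, H_b = x$H_b, depth = x$depth)
}

#' Plot hierarchy metrics across days
#'
#' @param reports A list of `hierarchy_report`s (e.g. one per day).
#' @return A ggplot object with one line per metric over days.
#' @export
plot_hierarchy_series <- function(reports) {
  df <- purrr::map_dfr(reports, glance) %>%
    tidyr::pivot_longer(c("treeness", "feedforwardness", "orderability"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "index value") +
    ggplot2::theme_minimal()
}
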