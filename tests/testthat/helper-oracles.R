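# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written in the most naive style (set operations,
# explicit path enumeration, matrix-power reachability) and share no code
# with the package internals.

oracle_bc <- function(u, v) sum(abs(u - v)) / sum(u + v)

# naive growth closure on a list-of-sets model description
oracle_closure <- function(species, medium, members = names(species)) {
  available <- medium
  growing <- character(0)
  repeat {
    changed <- FALSE
    for (id in members) {
      if (id %in% growing) next
      if (all(species[[id]]$required %in% available)) {
        growing <- c(growing, id)
        available <- union(available, species[[id]]$secreted)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(growing = growing, available = available)
}

# exhaustive SCS by direct subset enumeration with the naive closure
oracle_scs <- function(species, medium, recipient, donor) {
  others <- setdiff(names(species), c(recipient, donor))
  n_cond <- 0
  n_fail <- 0
  for (k in 0:length(others)) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(others, k, simplify = FALSE)
    for (s in subsets) {
      members <- c(recipient, donor, s)
      if (recipient %in% oracle_closure(species, medium, members)$growing) {
        n_cond <- n_cond + 1
        without <- setdiff(members, donor)
        if (!(recipient %in% oracle_closure(species, medium, without)$growing)) {
          n_fail <- n_fail + 1
        }
      }
    }
  }
  if (n_cond == 0) 0 else n_fail / n_cond
}

# model -> list-of-sets description consumable by the naive oracles
as_set_description <- function(model) {
  sp <- stats::setNames(
    lapply(seq_len(nrow(model$species)), function(i) {
      list(required = model$species$required[[i]],
           secreted = model$species$secreted[[i]])
    }),
    model$species$id
  )
  sp
}

# reachability matrix by repeated boolean multiplication
oracle_reach <- function(edge_df, nodes) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edge_df) > 0) {
    adj[cbind(match(as.character(edge_df[[1]]), nodes),
              match(as.character(edge_df[[2]]), nodes))] <- TRUE
  }
  reach <- adj
  for (k in seq_len(n)) {
    new_reach <- reach | ((reach %*% adj) > 0)
    if (identical(new_reach, reach)) break
    reach <- new_reach
  }
  reach
}

# SCC membership by mutual reachability
oracle_scc <- function(edge_df, nodes) {
  reach <- oracle_reach(edge_df, nodes)
  mutual <- (reach & t(reach)) | diag(TRUE, length(nodes))
  membership <- integer(length(nodes))
  next_id <- 0L
  for (i in seq_along(nodes)) {
    if (membership[i] == 0L) {
      next_id <- next_id + 1L
      membership[mutual[i, ]] <- next_id
    }
  }
  stats::setNames(membership, nodes)
}

# forward path entropy of a node in a DAG by explicit path enumeration:
# each maximal-to-sink path has probability prod(1/k_out) along the way
oracle_path_entropy <- function(edge_df, nodes, v) {
  succ <- lapply(stats::setNames(nodes, nodes), function(x) {
    as.character(edge_df[[2]][as.character(edge_df[[1]]) == x])
  })
  probs <- numeric(0)
  walk <- function(u, p) {
    s <- succ[[u]]
    if (length(s) == 0) {
      probs <<- c(probs, p)
    } else {
      for (w in s) walk(w, p / length(s))
    }
  }
  walk(v, 1)
  -sum(probs * log2(probs))
}

random_digraph <- function(n, p, seed) {
  withr::with_seed(seed, {
    adj <- matrix(stats::runif(n * n) < p, n, n)
    diag(adj) <- FALSE
    el <- which(adj, arr.ind = TRUE)
    ids <- sprintf("v%d", seq_len(n))
    list(edges = data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                            stringsAsFactors = FALSE),
         nodes = ids)
  })
}

# two-species/one-handoff community used across exchange tests:
# medium {m0}; a needs m0 and secretes m1; b needs m1
chain_model <- function() {
  community_model(
    tibble::tibble(
      id = c("a", "b"),
      required = list("m0", "m1"),
      secreted = list("m1", character())
    ),
    medium = "m0"
  )
}

# 4-species community with one essential donor: r requires m (non-medium),
# only d secretes m; two bystanders grow on the medium
essential_donor_model <- function() {
  community_model(
    tibble::tibble(
      id = c("r", "d", "b1", "b2"),
      required = list("m", "e", "e", "e"),
      secreted = list(character(), "m", character(), character())
    ),
    medium = "e"
  )
}

# redundant producers: r requires m, secreted by both d1 and d2
redundant_donor_model <- function() {
  community_model(
    tibble::tibble(
      id = c("r", "d1", "d2", "b"),
      required = list("m", "e", "e", "e"),
      secreted = list(character(), "m", "m", character())
    ),
    medium = "e"
  )
}
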