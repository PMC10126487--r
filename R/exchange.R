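# Set-based cross-feeding model: growth closure, species coupling scores,
# transfer attribution, MIP and MRO. Growth is boolean: a species grows when
# every required metabolite is available (medium plus secretions of growing
# members); growing species secrete their full secretion set. The closure is
# the unique least fixed point, so it is monotone and order-independent.

closure_core <- function(req, sec, member_idx, medium_logical) {
  growing <- rep(FALSE, nrow(req))
  avail <- medium_logical
  is_member <- rep(FALSE, nrow(req))
  is_member[member_idx] <- TRUE
  repeat {
    can <- is_member & !growing & (req %*% (!avail) == 0)[, 1]
    if (!any(can)) break
    growing <- growing | can
    if (sum(can) == 1L) {
      avail <- avail | sec[which(can), ]
    } else {
      avail <- avail | (colSums(sec[can, , drop = FALSE]) > 0)
    }
  }
  list(growing = growing, available = avail)
}

#' Community growth closure
#'
#' Starting from the medium, repeatedly grants growth to any member species
#' whose full requirement set is available and adds its secretions to the
#' available pool, until nothing changes. The result is the least fixed
#' point: it does not depend on the order in which species are considered,
#' and enlarging the member set or the medium can only enlarge it.
#'
#' @param model A [community_model()].
#' @param members Character vector of member species ids (default: all).
#' @param medium Optional medium override (character vector of metabolites).
#' @return A list with `growing` (ids of species that grow) and `available`
#'   (metabolites present at the fixed point).
#' @examples
#' sp <- tibble::tibble(id = c("a", "b"),
#'                      required = list("m0", "m1"),
#'                      secreted = list("m1", character()))
#' mod <- community_model(sp, medium = "m0")
#' growth_closure(mod)$growing
#' @export
growth_closure <- function(model, members = NULL, medium = NULL) {
  members <- check_species(model, members %||% species_ids(model), "member")
  medium <- as.character(medium %||% model$medium)
  bad <- setdiff(medium, model$metabolites)
  if (length(bad) > 0) {
    stop_invalid(sprintf("medium metabolite(s) not in universe: %s",
                         paste(bad, collapse = ", ")))
  }
  res <- closure_core(model$req, model$sec,
                      match(members, species_ids(model)),
                      model$metabolites %in% medium)
  list(growing = species_ids(model)[res$growing],
       available = model$metabolites[res$available])
}

# Growth table over every subset of the full species set, indexed by bitmask
# (subset mask + 1 -> logical vector over species). Only sensible for small n.
subset_growth_table <- function(model) {
  n <- nrow(model$species)
  medium_logical <- model$metabolites %in% model$medium
  masks <- 0:(2^n - 1)
  t(vapply(masks, function(mask) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0)
    closure_core(model$req, model$sec, idx, medium_logical)$growing
  }, logical(n)))
}

#' Species coupling score (set-based analog)
#'
#' Directional dependency of a recipient on a donor: over the sub-communities
#' that contain both species and in which the recipient grows, the fraction
#' in which removing the donor abolishes the recipient's growth. 0 means
#' complete independence, 1 means the donor is essential whenever the
#' recipient grows. Computed by exhaustive enumeration of sub-communities
#' when the community has at most `exhaustive_limit` species, otherwise by
#' uniform Monte-Carlo sampling of sub-communities.
#'
#' @param model A [community_model()].
#' @param recipient,donor Species ids, distinct.
#' @param mode `"auto"` (exhaustive iff small enough), `"exhaustive"` or
#'   `"montecarlo"`.
#' @param n_samples Monte-Carlo sample count (subsets drawn uniformly among
#'   those containing both species).
#' @param seed RNG seed for Monte-Carlo mode.
#' @param exhaustive_limit Species count up to which `"auto"` enumerates all
#'   sub-communities (default 12, i.e. 4096 subsets).
#' @return A score in \[0, 1\]. If no sub-community containing both lets the
#'   recipient grow, the score is 0 with a warning.
#' @export
species_coupling_score <- function(model, recipient, donor,
                                   mode = c("auto", "exhaustive", "montecarlo"),
                                   n_samples = 1000, seed = 1,
                                   exhaustive_limit = 12) {
  mode <- match.arg(mode)
  recipient <- check_species(model, recipient, "recipient")
  donor <- check_species(model, donor, "donor")
  if (identical(recipient, donor)) {
    stop_invalid("`recipient` and `donor` must differ")
  }
  n <- nrow(model$species)
  if (mode == "auto") {
    mode <- if (n <= exhaustive_limit) "exhaustive" else "montecarlo"
  }
  ids <- species_ids(model)
  r <- match(recipient, ids)
  d <- match(donor, ids)
  if (mode == "exhaustive") {
    if (n > 25) stop_invalid("exhaustive enumeration infeasible beyond 25 species")
    tab <- subset_growth_table(model)
    scs_from_table(tab, d, r, n)
  } else {
    others <- setdiff(seq_len(n), c(r, d))
    medium_logical <- model$metabolites %in% model$medium
    cond <- 0L
    fail <- 0L
    # sampled sub-communities repeat often on small instances; memoize closures
    cache <- new.env(parent = emptyenv())
    grows_r <- function(sub) {
      key <- paste(sub, collapse = ",")
      hit <- cache[[key]]
      if (is.null(hit)) {
        hit <- closure_core(model$req, model$sec, sub, medium_logical)$growing[r]
        cache[[key]] <- hit
      }
      hit
    }
    with_seed(seed, {
      for (k in seq_len(check_count(n_samples, "n_samples"))) {
        sub <- c(r, d, others[stats::runif(length(others)) < 0.5])
        if (grows_r(sub)) {
          cond <- cond + 1L
          if (!grows_r(setdiff(sub, d))) fail <- fail + 1L
        }
      }
    })
    if (cond == 0L) {
      warn(sprintf("recipient '%s' grew in no sampled sub-community containing '%s'; score set to 0",
                   recipient, donor))
      return(0)
    }
    fail / cond
  }
}

# Exhaustive SCS for a (donor, recipient) index pair from the subset growth
# table. NA signals an empty conditioning set (caller decides how to report).
scs_from_table <- function(tab, d, r, n, quiet = FALSE) {
  masks <- 0:(2^n - 1)
  both <- bitwAnd(masks, bitwShiftL(1L, d - 1L)) > 0 &
    bitwAnd(masks, bitwShiftL(1L, r - 1L)) > 0
  mask_ids <- masks[both]
  cond <- tab[mask_ids + 1L, r]
  if (!any(cond)) {
    if (!quiet) warn("recipient grows in no sub-community containing the donor; score set to 0")
    return(0)
  }
  removed <- bitwAnd(mask_ids, bitwNot(bitwShiftL(1L, d - 1L)))
  mean(!tab[removed[cond] + 1L, r])
}

#' All pairwise species coupling scores for one run
#'
#' Computes the full donor-by-recipient coupling-score table together with
#' the metabolite-transfer attribution of the full community, as one seeded
#' run. In exhaustive mode the run is deterministic and the seed is only
#' recorded; in Monte-Carlo mode sub-communities are sampled under the seed.
#'
#' @inheritParams species_coupling_score
#' @return An object of class `coupling_result`: list with `scs` (tibble
#'   `donor`, `recipient`, `scs`), `transfers` (see [transfer_attribution()]),
#'   `run_seed`, `mode`, `n_samples`.
#' @export
coupling_run <- function(model, mode = c("auto", "exhaustive", "montecarlo"),
                         n_samples = 1000, seed = 1, exhaustive_limit = 12) {
  mode <- match.arg(mode)
  n <- nrow(model$species)
  if (mode == "auto") {
    mode <- if (n <= exhaustive_limit) "exhaustive" else "montecarlo"
  }
  ids <- species_ids(model)
  pairs <- expand.grid(donor = seq_len(n), recipient = seq_len(n)) %>%
    filter(.data$donor != .data$recipient)
  if (mode == "exhaustive") {
    tab <- subset_growth_table(model)
    scores <- mapply(function(d, r) scs_from_table(tab, d, r, n, quiet = TRUE),
                     pairs$donor, pairs$recipient)
  } else {
    # Shared-sample estimator: draw n_samples uniform sub-communities once,
    # evaluate growth for each subset and each single-member removal, and
    # score every ordered pair from the subsets that contain it. For a pair
    # (d, r) the retained subsets are uniform among those containing both,
    # so this matches the per-pair definition at ~n_samples/4 effective
    # draws per pair while costing |S| + 1 closures per subset instead of
    # 2 * n_samples per pair.
    medium_logical <- model$metabolites %in% model$medium
    cond_mat <- matrix(0L, n, n)
    fail_mat <- matrix(0L, n, n)
    with_seed(seed, {
      for (k in seq_len(check_count(n_samples, "n_samples"))) {
        members <- which(stats::runif(n) < 0.5)
        if (length(members) < 2) next
        grow <- closure_core(model$req, model$sec, members, medium_logical)$growing
        rec_grow <- members[grow[members]]
        for (d in members) {
          rg <- setdiff(rec_grow, d)
          if (length(rg) == 0) next
          cond_mat[d, rg] <- cond_mat[d, rg] + 1L
          grow_wo <- closure_core(model$req, model$sec, setdiff(members, d),
                                  medium_logical)$growing
          lost <- rg[!grow_wo[rg]]
          if (length(lost)) fail_mat[d, lost] <- fail_mat[d, lost] + 1L
        }
      }
    })
    idx <- cbind(pairs$donor, pairs$recipient)
    scores <- ifelse(cond_mat[idx] > 0, fail_mat[idx] / cond_mat[idx], 0)
  }
  structure(
    list(
      scs = tibble(donor = ids[pairs$donor], recipient = ids[pairs$recipient],
                   scs = as.numeric(scores)),
      transfers = transfer_attribution(model),
      run_seed = as.integer(seed),
      mode = mode,
      n_samples = if (mode == "montecarlo") as.integer(n_samples) else NA_integer_
    ),
    class = "coupling_result"
  )
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> %s mode, seed %d, %d positive of %d directed pairs\n",
              x$mode, x$run_seed, sum(x$scs$scs > 0), nrow(x$scs)))
  invisible(x)
}

#' Metabolite transfer attribution
#'
#' For every ordered pair of growing species (donor, recipient) in the
#' community, each metabolite that the donor secretes, the recipient
#' requires, and the medium does not supply contributes one transfer record.
#'
#' @param model A [community_model()].
#' @param members Species subset to evaluate (default: all).
#' @return A tibble with columns `donor`, `recipient`, `metabolite`.
#' @seealso [transfer_frequency()] for per-metabolite counts.
#' @export
transfer_attribution <- function(model, members = NULL) {
  members <- check_species(model, members %||% species_ids(model), "member")
  growing <- growth_closure(model, members)$growing
  ids <- species_ids(model)
  g <- match(growing, ids)
  out <- list()
  for (b in g) {
    for (a in g) {
      if (a == b) next
      m <- model$metabolites[model$sec[b, ] & model$req[a, ]]
      m <- setdiff(m, model$medium)
      if (length(m) > 0) {
        out[[length(out) + 1L]] <- tibble(donor = ids[b], recipient = ids[a],
                                          metabolite = m)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(donor = character(), recipient = character(),
                  metabolite = character()))
  }
  bind_rows(out)
}

#' Per-metabolite transfer frequencies
#'
#' Counts, for each metabolite, the number of distinct (donor, recipient)
#' pairs through which it is inferred to flow. With `standardize = TRUE` the
#' counts are divided by their grand total so that frequencies sum to one —
#' the form used to compare transfer profiles across time points.
#'
#' @param transfers Output of [transfer_attribution()].
#' @param standardize Divide counts by the grand total (default `FALSE`).
#' @return A tibble with columns `metabolite` and `count` (or `frequency`).
#' @export
transfer_frequency <- function(transfers, standardize = FALSE) {
  counts <- transfers %>%
    distinct(.data$donor, .data$recipient, .data$metabolite) %>%
    dplyr::count(.data$metabolite, name = "count") %>%
    arrange(desc(.data$count), .data$metabolite)
  if (standardize) {
    total <- sum(counts$count)
    if (total == 0) stop_invalid("no transfers to standardize")
    counts <- counts %>%
      mutate(frequency = .data$count / total) %>%
      select("metabolite", "frequency")
  }
  counts
}

#' Metabolic interaction potential (MIP)
#'
#' How many external metabolites the community can dispense with thanks to
#' cross-feeding: the size of the minimal medium supporting growth of all
#' species without interspecific exchange (the union of all requirement
#' sets) minus the size of the minimal medium with exchange, found by
#' exact subset search over candidate metabolites (smallest subset of the
#' requirement union under which every species reaches growth closure).
#' Beyond `exact_limit` candidate metabolites the search falls back to a
#' greedy irreducible medium, which can only under-estimate MIP; the result
#' is then flagged `status = "greedy_lower_bound"`.
#'
#' @param model A [community_model()].
#' @param exact_limit Candidate-metabolite count up to which the exact search
#'   runs (default 20).
#' @return Integer MIP with attributes `minimal_medium` (a smallest medium
#'   with exchange) and `status` (`"exact"` or `"greedy_lower_bound"`).
#' @export
metabolic_interaction_potential <- function(model, exact_limit = 20) {
  candidates <- sort(unique(unlist(model$species$required)))
  u <- length(candidates)
  if (u == 0) {
    return(structure(0L, minimal_medium = character(), status = "exact"))
  }
  grows_all <- function(medium) {
    length(growth_closure(model, medium = medium)$growing) == nrow(model$species)
  }
  if (!grows_all(candidates)) {
    stop_invalid("community infeasible: not all species grow even on the full requirement union")
  }
  if (u <= exact_limit) {
    for (k in 0:u) {
      subsets <- combn(candidates, k, simplify = FALSE)
      for (e in subsets) {
        if (grows_all(e)) {
          return(structure(as.integer(u - k), minimal_medium = e,
                           status = "exact"))
        }
      }
    }
    # unreachable: the full candidate set always succeeds
  }
  e <- candidates
  for (m in candidates) {
    trial <- setdiff(e, m)
    if (grows_all(trial)) e <- trial
  }
  structure(as.integer(u - length(e)), minimal_medium = e,
            status = "greedy_lower_bound")
}

#' Metabolic resource overlap (MRO)
#'
#' Mean, over unordered species pairs, of the proportion of shared
#' nutritional requirements — a set-based proxy for the potential of
#' resource competition. The default denominator is the smaller requirement
#' set of the pair; `"union"` (Jaccard) and `"mean"` are recorded variants.
#' Pairs in which the denominator would be zero are skipped.
#'
#' @param model A [community_model()] with at least two species.
#' @param denominator `"min"`, `"union"` or `"mean"`.
#' @return MRO in \[0, 1\] with attribute `denominator`.
#' @export
metabolic_resource_overlap <- function(model,
                                       denominator = c("min", "union", "mean")) {
  denominator <- match.arg(denominator)
  n <- nrow(model$species)
  if (n < 2) stop_invalid("MRO needs at least two species")
  req <- model$species$required
  vals <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(req[[i]], req[[j]]))
      denom <- switch(denominator,
        min = min(length(req[[i]]), length(req[[j]])),
        union = length(union(req[[i]], req[[j]])),
        mean = (length(req[[i]]) + length(req[[j]])) / 2
      )
      if (denom > 0) vals <- c(vals, shared / denom)
    }
  }
  if (length(vals) == 0) stop_invalid("no species pair has a usable requirement set")
  structure(mean(vals), denominator = denominator)
}

#' Replicate seeded coupling runs with mean/SD aggregation
#'
#' Performs `n_runs` coupling runs differing only in their random seed and
#' aggregates per-edge coupling scores and community-level scores (MIP, MRO)
#' as mean and standard deviation across runs. In exhaustive mode every run
#' is identical and all standard deviations are zero; the replicate
#' bookkeeping then simply documents reproducibility.
#'
#' @inheritParams coupling_run
#' @param n_runs Number of replicate runs (default 10).
#' @param base_seed First seed; run k uses `base_seed + k - 1`.
#' @return An object of class `coupling_runs`: list with `runs` (the
#'   individual `coupling_result`s), `summary` (tibble `donor`, `recipient`,
#'   `scs_mean`, `scs_sd`), `transfers`, `scores` (one-row tibble with
#'   mip/mro mean and sd), `seeds`, `mode`.
#' @export
replicate_runs <- function(model, n_runs = 10, base_seed = 1,
                           mode = c("auto", "exhaustive", "montecarlo"),
                           n_samples = 1000, exhaustive_limit = 12) {
  n_runs <- check_count(n_runs, "n_runs")
  mode <- match.arg(mode)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  runs <- lapply(seeds, function(s) {
    coupling_run(model, mode = mode, n_samples = n_samples, seed = s,
                 exhaustive_limit = exhaustive_limit)
  })
  scs_all <- purrr::map_dfr(runs, "scs")
  summary <- scs_all %>%
    group_by(.data$donor, .data$recipient) %>%
    summarise(scs_mean = mean(.data$scs),
              scs_sd = if (n() > 1) sd(.data$scs) else 0,
              .groups = "drop")
  mip <- metabolic_interaction_potential(model)
  mro <- metabolic_resource_overlap(model)
  scores <- tibble(
    mip_mean = as.numeric(mip), mip_sd = 0,
    mro_mean = as.numeric(mro), mro_sd = 0,
    mip_status = attr(mip, "status"),
    mro_denominator = attr(mro, "denominator")
  )
  structure(
    list(runs = runs, summary = summary, transfers = runs[[1]]$transfers,
         scores = scores, seeds = seeds, mode = runs[[1]]$mode),
    class = "coupling_runs"
  )
}

#' @export
print.coupling_runs <- function(x, ...) {
  cat(sprintf("<coupling_runs> %d %s run(s), seeds %d..%d\n",
              length(x$runs), x$mode, min(x$seeds), max(x$seeds)))
  print(x$scores)
  invisible(x)
}

#' @export
tidy.coupling_runs <- function(x, ...) x$summary

#' @export
glance.coupling_runs <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_runs = length(x$runs), mode = x$mode,
           n_edges_positive = sum(x$summary$scs_mean > 0)),
    x$scores
  )
}

#' Write coupling-score and transfer tables as TSV
#'
#' @param runs A `coupling_runs` object.
#' @param scs_path,transfers_path Output file paths (either may be `NULL`).
#' @export
write_coupling_tsv <- function(runs, scs_path = NULL, transfers_path = NULL) {
  if (!is.null(scs_path)) readr::write_tsv(runs$summary, scs_path)
  if (!is.null(transfers_path)) {
    readr::write_tsv(transfer_frequency(runs$transfers), transfers_path)
  }
  invisible(runs)
}
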