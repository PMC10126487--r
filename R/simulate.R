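# Seeded synthetic-data generators. The abundance generator emulates the
# dynamics the pipeline is meant to detect: a community dominated by one
# species set, an instantaneous regime shift transferring most of the total
# abundance to a small disjoint survivor set (a quasi-stable low-diversity
# phase), and an optional staggered recovery of the displaced species late
# in the series. The community generator builds toy metabolic communities
# with controllable cross-feeding density and planted dependency loops.

#' Simulate an abundance time series with a planted abrupt shift
#'
#' A deterministic skeleton (total mass 1 per day) is perturbed by
#' multiplicative log-normal noise. Before `shift_day` the community consists
#' of `n_species - quasi_stable_richness` "early" species with geometrically
#' ranked abundances; at `shift_day` a fraction `shift_magnitude` of the
#' total abundance moves instantaneously to the disjoint survivor set of
#' size `quasi_stable_richness`. If `recovery_day` is given, displaced early
#' species return one by one from that day on, each ramping up linearly, so
#' richness rises again late in the series. Columns are left non-normalized;
#' downstream turnover statistics normalize per day.
#'
#' Defaults mirror a 110-day daily co-culture series of 32 taxa with a rapid
#' compositional shift around day 18 followed by a quasi-stable
#' low-diversity phase.
#'
#' @param n_species Total species count (default 32).
#' @param n_days Days, sampled daily (default 110).
#' @param shift_day 1-based day of the instantaneous shift (default 18).
#' @param shift_magnitude Fraction of total abundance transferred to the
#'   survivor set at the shift, in \[0, 1\] (default 0.9).
#' @param noise_scale Standard deviation of the per-cell log-normal noise on
#'   the log scale (default 0.2; 0 gives the deterministic skeleton).
#' @param quasi_stable_richness Number of survivor species after the shift
#'   (default 4).
#' @param recovery_day Optional day at which displaced species begin to
#'   return (default `NULL`: no recovery).
#' @param seed RNG seed; identical arguments and seed give bit-identical
#'   output.
#' @return A tidy abundance series tibble (see [abundance_series()]) with
#'   attributes `survivors` (ids of the post-shift set) and `early` (ids of
#'   the pre-shift set).
#' @examples
#' ts <- simulate_timeseries(n_species = 8, n_days = 30, shift_day = 10,
#'                           quasi_stable_richness = 2, seed = 1)
#' abruptness(ts)
#' @export
simulate_timeseries <- function(n_species = 32, n_days = 110, shift_day = 18,
                                shift_magnitude = 0.9, noise_scale = 0.2,
                                quasi_stable_richness = 4, recovery_day = NULL,
                                seed = 1) {
  n_species <- check_count(n_species, "n_species")
  n_days <- check_count(n_days, "n_days")
  shift_day <- check_count(shift_day, "shift_day")
  m <- check_fraction(shift_magnitude, "shift_magnitude")
  noise_scale <- check_nonneg(noise_scale, "noise_scale")
  k <- check_count(quasi_stable_richness, "quasi_stable_richness", min = 1L)
  if (shift_day > n_days) {
    stop_invalid(sprintf("`shift_day` (%d) must be <= `n_days` (%d)",
                         shift_day, n_days))
  }
  if (k > n_species) {
    stop_invalid(sprintf("`quasi_stable_richness` (%d) must be <= `n_species` (%d)",
                         k, n_species))
  }
  if (m > 0 && k >= n_species) {
    stop_invalid("a positive shift needs at least one non-survivor species")
  }
  if (!is.null(recovery_day)) {
    recovery_day <- check_count(recovery_day, "recovery_day")
    if (recovery_day <= shift_day || recovery_day > n_days) {
      stop_invalid("`recovery_day` must lie in (shift_day, n_days]")
    }
  }
  ids <- sprintf("sp_%02d", seq_len(n_species))
  n_early <- n_species - k
  early <- ids[seq_len(n_early)]
  survivors <- ids[n_early + seq_len(k)]
  # geometric rank-abundance; the 0.85 ratio keeps a few dominant taxa while
  # leaving the long tail above realistic detection thresholds
  geom_w <- function(n) {
    w <- 0.85^seq_len(n)
    w / sum(w)
  }
  w_early <- if (n_early > 0) geom_w(n_early) else numeric(0)
  w_surv <- geom_w(k)
  # staggered return days for displaced species during recovery
  r_j <- if (!is.null(recovery_day) && n_early > 0) {
    recovery_day + floor((seq_len(n_early) - 1) *
                           (n_days - recovery_day) / n_early)
  }
  skeleton <- vapply(seq_len(n_days), function(t) {
    if (t < shift_day) {
      c(w_early, numeric(k))
    } else {
      e <- w_early * (1 - m)
      if (!is.null(r_j)) {
        ramp <- pmax(0, (t - r_j + 1) / (n_days - r_j + 1))
        e <- e + w_early * m * 0.7 * ramp * (t >= r_j)
      }
      c(e, w_surv * m)
    }
  }, numeric(n_species))
  mat <- with_seed(seed, {
    noise <- matrix(exp(rnorm(n_species * n_days, 0, noise_scale)),
                    n_species, n_days)
    skeleton * noise
  })
  rownames(mat) <- ids
  out <- abundance_series(mat, days = seq_len(n_days))
  attr(out, "survivors") <- survivors
  attr(out, "early") <- early
  out
}

#' Simulate a toy cross-feeding community with planted dependency loops
#'
#' Builds a [community_model()] in which one designated source species grows
#' on the medium alone, every other species is reachable from the medium
#' through a chain of secretions (so the full community always grows), each
#' requirement of a non-loop species is cross-fed (supplied only by another
#' species' secretion) with probability `crossfeed_density` and otherwise
#' drawn from the medium, and exactly `loop_count` mutual-dependency pairs
#' are planted. Each planted pair exchanges two dedicated metabolites that
#' the source species also secretes as a backup, so the loop is a genuine
#' strongly connected component of the dependency digraph while community
#' growth stays feasible. Every cross-fed metabolite is fresh (used by one
#' donor-recipient relation only), so the designed dependency digraph
#' contains exactly the planted cycles and nothing else.
#'
#' @param n_species Species count (default 8; at least `2 * loop_count + 1`).
#' @param n_metabolites Metabolite universe size; default `NULL` sizes it to
#'   accommodate the worst case
#'   (`medium_size + (n_species - 1) * req_size + 2 * loop_count`).
#' @param medium_size Metabolites freely available in the medium (default 4).
#' @param crossfeed_density Probability that each requirement slot of a
#'   non-loop species is cross-fed rather than medium-supplied (default 0.5).
#' @param loop_count Number of planted two-species dependency cycles
#'   (default 0).
#' @param req_size Requirement slots per species (default 2).
#' @param seed RNG seed.
#' @return A [community_model()] with an extra `design` field: tibble
#'   `dependency_edges` (`donor`, `recipient`, `metabolite`), `loop_pairs`,
#'   and the `source` species id.
#' @examples
#' mod <- simulate_exchange_community(n_species = 5, loop_count = 1, seed = 7)
#' growth_closure(mod)$growing
#' @export
simulate_exchange_community <- function(n_species = 8, n_metabolites = NULL,
                                        medium_size = 4, crossfeed_density = 0.5,
                                        loop_count = 0, req_size = 2, seed = 1) {
  n <- check_count(n_species, "n_species", min = 1L)
  medium_size <- check_count(medium_size, "medium_size", min = 0L)
  p <- check_fraction(crossfeed_density, "crossfeed_density")
  loop_count <- check_count(loop_count, "loop_count", min = 0L)
  req_size <- check_count(req_size, "req_size", min = 1L)
  if (2L * loop_count > n - 1L) {
    stop_invalid(sprintf(
      "loop_count = %d needs at least %d species (one source plus two per loop), got %d",
      loop_count, 2L * loop_count + 1L, n))
  }
  need_fresh <- (n - 1L) * req_size + 2L * loop_count
  n_metabolites <- check_count(
    n_metabolites %||% (medium_size + need_fresh), "n_metabolites", min = 1L)
  if (medium_size > n_metabolites) {
    stop_invalid("`medium_size` must be <= `n_metabolites`")
  }
  if (n_metabolites - medium_size < need_fresh && p > 0) {
    stop_invalid(sprintf(
      "need up to %d non-medium metabolites for cross-feeding, universe leaves %d",
      need_fresh, n_metabolites - medium_size))
  }
  mets <- sprintf("m_%03d", seq_len(n_metabolites))
  medium <- mets[seq_len(medium_size)]
  pool <- setdiff(mets, medium)
  ids <- sprintf("sp_%02d", seq_len(n))
  req <- setNames(vector("list", n), ids)
  sec <- setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    req[[i]] <- character()
    sec[[i]] <- character()
  }
  dep <- list()
  loop_pairs <- NULL
  with_seed(seed, {
    # the source grows on the medium alone
    if (medium_size > 0) {
      req[[1]] <- sample(medium, min(req_size, medium_size))
    }
    next_fresh <- 1L
    take_fresh <- function() {
      x <- pool[next_fresh]
      next_fresh <<- next_fresh + 1L
      x
    }
    loop_members <- integer(0)
    helper2 <- 1L
    if (loop_count > 0) {
      # With room to spare, reserve a second medium-growing helper so each
      # loop direction has its own backup producer: then sub-communities
      # exist in which either loop partner is the sole provider for the
      # other, and both loop edges carry positive coupling scores.
      two_helpers <- medium_size > 0 && 2L * loop_count <= n - 2L
      if (two_helpers) {
        helper2 <- 2L
        req[[2]] <- sample(medium, min(req_size, medium_size))
      }
      candidates <- setdiff(2:n, helper2)
      chosen <- candidates[sample.int(length(candidates), 2L * loop_count)]
      loop_pairs <- matrix(chosen, ncol = 2, byrow = TRUE)
      loop_members <- chosen
      for (row in seq_len(loop_count)) {
        a <- loop_pairs[row, 1]
        b <- loop_pairs[row, 2]
        x <- take_fresh()  # b -> a
        y <- take_fresh()  # a -> b
        req[[a]] <- c(req[[a]], x)
        sec[[b]] <- c(sec[[b]], x)
        req[[b]] <- c(req[[b]], y)
        sec[[a]] <- c(sec[[a]], y)
        # backup production keeps the community feasible
        sec[[1]] <- c(sec[[1]], x)
        sec[[helper2]] <- c(sec[[helper2]], y)
        dep[[length(dep) + 1L]] <- tibble(
          donor = ids[c(b, a, 1L, helper2)], recipient = ids[c(a, b, a, b)],
          metabolite = c(x, y, x, y))
      }
    }
    non_loop <- if (n >= 2) setdiff(2:n, c(loop_members, helper2)) else integer(0)
    for (i in non_loop) {
      for (slot in seq_len(req_size)) {
        crossfed <- stats::runif(1) < p || medium_size == 0
        if (crossfed) {
          cand <- setdiff(seq_len(i - 1L), loop_members)
          donor <- cand[sample.int(length(cand), 1L)]
          x <- take_fresh()
          req[[i]] <- c(req[[i]], x)
          sec[[donor]] <- c(sec[[donor]], x)
          dep[[length(dep) + 1L]] <- tibble(
            donor = ids[donor], recipient = ids[i], metabolite = x)
        } else {
          req[[i]] <- unique(c(req[[i]], sample(medium, 1)))
        }
      }
    }
  })
  model <- community_model(
    tibble(id = ids, required = unname(req), secreted = unname(sec)),
    medium = medium, metabolites = mets
  )
  stopifnot(length(growth_closure(model)$growing) == n)
  model$design <- list(
    dependency_edges = if (length(dep)) bind_rows(dep) else
      tibble(donor = character(), recipient = character(), metabolite = character()),
    loop_pairs = if (!is.null(loop_pairs)) {
      tibble(a = ids[loop_pairs[, 1]], b = ids[loop_pairs[, 2]])
    } else tibble(a = character(), b = character()),
    source = ids[1]
  )
  model
}
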