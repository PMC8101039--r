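#' Energy of a haplotype configuration
#'
#' The log-likelihood of a haplotype `S` given all pairwise linkage
#' evidence is, up to an additive constant, the negative energy of a 1D
#' spin model with couplings `M_ij`:
#' `E(S) = -1/2 * sum_{i != j} M_ij s_i s_j` (each unordered pair counted
#' once, with the 1/2 factor kept so that the flip and switch penalties
#' below are exact energy differences and, through the error-probability
#' logistic, exact log-likelihood ratios). Lower energy means a more
#' likely haplotype; the energy is invariant under the global flip
#' `S -> -S` (either parental chromosome may be labelled "plus").
#'
#' @param spins Spin vector (+1/-1), one entry per site.
#' @param pairs Coupling table from [estimate_error_rates()] (must carry a
#'   `weight` column).
#' @return The scalar energy.
#' @export
phase_energy <- function(spins, pairs) {
  check_spins(spins)
  pairs <- check_weights(pairs)
  if (nrow(pairs) > 0 && max(pairs$j) > length(spins)) {
    abort("`spins` is shorter than the largest site index in `pairs`.")
  }
  -0.5 * sum(pairs$weight * spins[pairs$i] * spins[pairs$j])
}

check_weights <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!"weight" %in% names(pairs)) {
    abort("`pairs` has no `weight` column; run estimate_error_rates() first.")
  }
  pairs
}

#' Single-site and boundary perturbation penalties
#'
#' `flip_penalty()` returns the energy change of flipping the spin at each
#' site, `delta_E_i = s_i * sum_j M_ij s_j`; `switch_penalty()` returns the
#' energy change of negating every spin after each boundary,
#' `delta_E_{k|k+1} = sum_{i<=k} sum_{j>k} M_ij s_i s_j` for boundaries
#' `k = 1..N-1`. At a local optimum both are non-negative; a penalty near
#' zero marks a site (or boundary) whose phase the data do not determine.
#'
#' @inheritParams phase_energy
#' @param i,k Optional site index / boundary index to return a single value.
#' @return Numeric vector of penalties (length `N` for flips, `N - 1` for
#'   boundaries), or a single value when `i`/`k` is given.
#' @export
flip_penalty <- function(spins, pairs, i = NULL) {
  check_spins(spins)
  pairs <- check_weights(pairs)
  out <- flip_penalties_cpp(length(spins), pairs$i, pairs$j, pairs$weight,
                            as.integer(spins))
  if (is.null(i)) out else out[i]
}

#' @rdname flip_penalty
#' @export
switch_penalty <- function(spins, pairs, k = NULL) {
  check_spins(spins)
  pairs <- check_weights(pairs)
  out <- switch_penalties_cpp(length(spins), pairs$i, pairs$j, pairs$weight,
                              as.integer(spins))
  if (is.null(k)) out else out[k]
}

#' Probability of a phasing error from an energy penalty
#'
#' The probability that the perturbed configuration (one spin flipped, or
#' every spin after a boundary negated) is the true one is the logistic
#' transform `delta = 1 / (1 + exp(delta_E))`. A penalty near zero gives
#' `delta ~ 0.5` (no confidence); a large penalty gives `delta ~ 0`.
#'
#' @param delta_e Energy penalty (vectorized).
#' @return Error probabilities in `(0, 1)`.
#' @examples
#' error_probability(0)    # 0.5
#' error_probability(10)   # ~ 4.5e-5
#' @export
error_probability <- function(delta_e) {
  if (anyNA(delta_e) || any(!is.finite(delta_e) & delta_e < 0)) {
    abort("`delta_e` must be finite or +Inf.")
  }
  1 / (1 + exp(delta_e))
}

greedy_init <- function(pairs, n_sites) {
  spins <- rep(1L, n_sites)
  if (nrow(pairs) == 0) return(spins)
  # chain each site to its strongest-linked predecessor
  best <- pairs |>
    mutate(absw = abs(.data$weight)) |>
    group_by(.data$j) |>
    slice_max(.data$absw, n = 1, with_ties = FALSE) |>
    ungroup()
  prev <- rep(NA_integer_, n_sites)
  sgn <- rep(1L, n_sites)
  prev[best$j] <- best$i
  sgn[best$j] <- pair_phase_sign(best$n_plus, best$n_minus)
  for (v in seq_len(n_sites)) {
    if (!is.na(prev[v]) && sgn[v] != 0L) {
      spins[v] <- spins[prev[v]] * sgn[v]
    }
  }
  spins
}

#' Minimize the spin-model energy by iterated flips and switches
#'
#' Finds a local optimum of the phasing energy by rounds of two move types:
#' single spin flips (in ascending site order) and suffix switches that
#' negate every spin after a boundary. Moves are accepted only when they
#' strictly lower the energy, so the sweep is deterministic given the
#' initial configuration; the default initialisation chains each site to
#' its strongest-linked predecessor using the sign of `n_plus - n_minus`.
#' At convergence (a full round with no accepted move) no single flip or
#' suffix switch can lower the energy, and the per-site flip penalties and
#' per-boundary switch penalties are recomputed at the optimum as phasing
#' confidence scores.
#'
#' @param pairs Coupling table from [estimate_error_rates()].
#' @param n_sites Number of sites (defaults to the largest index in
#'   `pairs`).
#' @param init Optional initial spin vector; the gauge is fixed by
#'   reporting the solution with the first spin positive.
#' @param max_rounds Maximum number of sweep rounds before returning the
#'   best solution so far with a warning.
#' @return A `hap_fit` object: per-site spins with flip penalties,
#'   per-boundary switch penalties, final energy, and a per-round move log.
#' @export
minimize_energy <- function(pairs, n_sites = NULL, init = NULL,
                            max_rounds = 50) {
  pairs <- check_weights(pairs)
  if (is.null(n_sites)) {
    if (nrow(pairs) == 0) abort("Empty model: supply `n_sites`.")
    n_sites <- max(pairs$j)
  }
  if (is.null(init)) {
    init <- greedy_init(pairs, n_sites)
  } else {
    check_spins(init)
    if (length(init) != n_sites) abort("`init` has the wrong length.")
  }
  res <- ising_minimize_cpp(n_sites, pairs$i, pairs$j, pairs$weight,
                            as.integer(init), as.integer(max_rounds))
  if (!res$converged) {
    warn(paste0("Energy minimization did not converge within ", max_rounds,
                " rounds; returning the current configuration."))
  }
  spins <- res$spins
  if (spins[1] < 0) spins <- -spins
  fp <- flip_penalties_cpp(n_sites, pairs$i, pairs$j, pairs$weight, spins)
  sp <- switch_penalties_cpp(n_sites, pairs$i, pairs$j, pairs$weight, spins)
  fit <- structure(list(
    spins = tibble(site = seq_len(n_sites), spin = spins,
                   flip_penalty = fp,
                   flip_error = error_probability(fp)),
    boundaries = tibble(boundary = seq_len(max(n_sites - 1L, 0L)),
                        switch_penalty = sp,
                        switch_error = error_probability(sp)),
    energy = phase_energy(spins, pairs),
    log = tibble(round = seq_along(res$flips),
                 flips = res$flips, switches = res$switches),
    converged = res$converged,
    n_sites = n_sites,
    epsilon0 = attr(pairs, "epsilon0")
  ), class = "hap_fit")
  fit
}

#' @exportS3Method base::print
print.hap_fit <- function(x, ...) {
  cat("<hap_fit> ", x$n_sites, " sites, energy ", format(x$energy),
      ", ", nrow(x$log), " round(s)",
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  invisible(x)
}

#' Cut a phased chromosome into high-confidence blocks
#'
#' Every boundary whose switch penalty falls below `cutoff` is a possible
#' long-range switching error and becomes a block break; within a block the
#' relative phase of all sites is supported by linkage with penalty at
#' least `cutoff`. Blocks with fewer than `min_report_size` phased variants
#' are flagged `short` (they carry little aggregated Hi-C signal and are
#' usually not displayed).
#'
#' @param fit A `hap_fit` from [minimize_energy()].
#' @param cutoff Switch-penalty cutoff (> 0); see [suggest_cutoff()].
#' @param min_report_size Minimum variants per block before the block is
#'   flagged short (default 50).
#' @return Per-site tibble: `site`, `spin`, `flip_penalty`, `block_id`,
#'   `block_size`, `short`.
#' @export
segment_blocks <- function(fit, cutoff, min_report_size = 50) {
  stopifnot(inherits(fit, "hap_fit"))
  if (cutoff <= 0) abort("`cutoff` must be positive.")
  cuts <- fit$boundaries$switch_penalty < cutoff
  block_id <- cumsum(c(1L, as.integer(cuts)))
  out <- fit$spins |>
    mutate(block_id = block_id) |>
    group_by(.data$block_id) |>
    mutate(block_size = n()) |>
    ungroup() |>
    mutate(short = .data$block_size < min_report_size)
  out
}

#' Suggest a block-switching penalty cutoff
#'
#' The distribution of boundary switch penalties is typically bimodal: a
#' low mode from unphasable junctions (linkage gaps, false variants,
#' chromosome ends) and a high mode from well-supported boundaries, often
#' several orders of magnitude apart. The suggested cutoff is the penalty
#' at the deepest valley of a kernel-smoothed histogram of
#' `log10(penalty + 1)` below the main mode. When no such valley exists
#' (e.g. sparse long-read data with a unimodal distribution), the
#' fallback is `0.1 *` the median number of links per site pair.
#'
#' @param switch_penalties Numeric vector of boundary switch penalties (or
#'   a `hap_fit`, from which they are taken).
#' @param median_link_coverage Median number of links per site pair, used
#'   by the fallback; see [count_linkage()].
#' @return A positive cutoff value.
#' @export
suggest_cutoff <- function(switch_penalties, median_link_coverage = NULL) {
  if (inherits(switch_penalties, "hap_fit")) {
    switch_penalties <- switch_penalties$boundaries$switch_penalty
  }
  pen <- switch_penalties[is.finite(switch_penalties)]
  if (length(pen) == 0) abort("No finite switch penalties supplied.")
  if (length(pen) >= 10 && max(pen) > 0) {
    lp <- log10(pmax(pen, 0) + 1)
    d <- stats::density(lp, n = 512)
    y <- d$y
    mins <- which(diff(sign(diff(y))) == 2) + 1
    main_mode <- which.max(y)
    mins <- mins[mins < main_mode]
    if (length(mins) > 0) {
      valley <- mins[which.min(y[mins])]
      return(10^d$x[valley] - 1)
    }
  }
  if (is.null(median_link_coverage)) {
    abort(paste0("No local minimum in the switch-penalty distribution; ",
                 "supply `median_link_coverage` for the fallback cutoff."))
  }
  0.1 * median_link_coverage
}

#' @export
tidy.hap_fit <- function(x, ...) {
  x$spins |>
    mutate(switch_penalty = c(x$boundaries$switch_penalty, NA_real_),
           switch_error = c(x$boundaries$switch_error, NA_real_))
}

#' @export
glance.hap_fit <- function(x, ...) {
  tibble(n_sites = x$n_sites, energy = x$energy,
         epsilon0 = x$epsilon0 %||% NA_real_,
         rounds = nrow(x$log), converged = x$converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
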