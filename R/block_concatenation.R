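#' Aggregate Hi-C linkage between haplotype blocks
#'
#' Individual Hi-C links between two variants are sparse (usually a single
#' link per pair), but summed over all variant pairs spanning two phase
#' blocks they give a strong relative-phase signal. For blocks s and t,
#' `n_plus` counts links whose spin product agrees with the product of the
#' block-local phases at the two ends (supporting cis concatenation) and
#' `n_minus` counts links supporting trans. The distance cap applies to
#' the variant-to-variant separation of each link; the 10 Mb default is
#' used for the within-arm concatenation stage.
#'
#' @param blocks Per-site block table from [segment_blocks()] (columns
#'   `site`, `spin`, `block_id`).
#' @param links Hi-C molecular link table.
#' @param sites Site table.
#' @param max_distance Maximum variant separation in bp (`Inf` to disable).
#' @return Tibble with one row per linked block pair: `s`, `t` (`s < t`),
#'   `n_plus`, `n_minus`. Links touching sites absent from `blocks` are
#'   skipped; their count is in the `"skipped_links"` attribute.
#' @export
interblock_linkage <- function(blocks, links, sites, max_distance = 1e7) {
  pairs <- count_linkage(links, sites, max_distance = max_distance)
  n <- nrow(validate_sites(sites))
  bl <- rep(NA_integer_, n)
  sp <- rep(NA_integer_, n)
  bl[blocks$site] <- blocks$block_id
  sp[blocks$site] <- blocks$spin
  bi <- bl[pairs$i]
  bj <- bl[pairs$j]
  known <- !is.na(bi) & !is.na(bj)
  cross <- known & bi != bj
  skipped <- sum(pairs$n_plus[!known] + pairs$n_minus[!known])
  pp <- pairs[cross, ]
  ss <- sp[pp$i] * sp[pp$j]
  out <- tibble(
    s = pmin(bi[cross], bj[cross]),
    t = pmax(bi[cross], bj[cross]),
    n_plus = ifelse(ss == 1, pp$n_plus, pp$n_minus),
    n_minus = ifelse(ss == 1, pp$n_minus, pp$n_plus)
  ) |>
    group_by(.data$s, .data$t) |>
    summarise(n_plus = sum(.data$n_plus), n_minus = sum(.data$n_minus),
              .groups = "drop")
  attr(out, "skipped_links") <- skipped
  out
}

#' Solve block phases from aggregated inter-block linkage
#'
#' Re-uses the spin-model minimizer at block scale: each block becomes one
#' spin `b_k`, the aggregated inter-block counts become the couplings, and
#' the same flip/switch sweep solves the joint block phase. Pairs with
#' fewer than `min_links` total links carry zero weight (a single stray
#' link never joins two blocks). Blocks connected through non-zero
#' couplings form one scaffold; disconnected groups of blocks remain
#' separate scaffolds with independent gauges.
#'
#' @param blocks Per-site block table from [segment_blocks()].
#' @param block_pairs Aggregated counts from [interblock_linkage()].
#' @param min_links Minimum links required to couple two blocks (default 2).
#' @param weighting `"chi"` applies the same error-rate weighting as local
#'   phasing to the aggregated counts; `"count"` uses raw `n_plus - n_minus`.
#' @return Block-level tibble: `block_id`, `block_phase`, `scaffold_id`,
#'   `n_sites`.
#' @export
concatenate_blocks <- function(blocks, block_pairs, min_links = 2,
                               weighting = c("chi", "count")) {
  weighting <- match.arg(weighting)
  ids <- sort(unique(blocks$block_id))
  m <- length(ids)
  bp <- as_tibble(block_pairs) |>
    filter(.data$n_plus + .data$n_minus >= min_links) |>
    mutate(i = match(.data$s, ids), j = match(.data$t, ids))
  if (nrow(bp) > 0) {
    if (weighting == "chi") {
      bp <- estimate_error_rates(bp)
    } else {
      bp$weight <- bp$n_plus - bp$n_minus
    }
    fit <- minimize_energy(bp, n_sites = m)
    b <- fit$spins$spin
    g <- igraph::graph_from_data_frame(
      bp[bp$weight != 0, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = seq_len(m))
    )
    comp <- igraph::components(g)$membership
  } else {
    b <- rep(1L, m)
    comp <- seq_len(m)
  }
  # deterministic gauge: first block of each scaffold is "plus"
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (b[members[1]] < 0) b[members] <- -b[members]
  }
  sizes <- blocks |> count(.data$block_id, name = "n_sites")
  tibble(block_id = ids, block_phase = as.integer(b),
         scaffold_id = as.integer(comp)) |>
    left_join(sizes, by = "block_id")
}

#' Apply solved block phases to get a per-site scaffold
#'
#' @param blocks Per-site block table from [segment_blocks()].
#' @param concat Block-level phases from [concatenate_blocks()].
#' @return Per-site scaffold tibble: `site`, `spin`, `block_id`,
#'   `block_phase`, `scaffold_id`, `phase` (`spin * block_phase`; +1 means
#'   the reference allele lies on haplotype A).
#' @export
apply_block_phases <- function(blocks, concat) {
  blocks |>
    select("site", "spin", "block_id") |>
    left_join(concat[, c("block_id", "block_phase", "scaffold_id")],
              by = "block_id") |>
    mutate(phase = .data$spin * .data$block_phase)
}

#' Join p-arm and q-arm scaffolds across the centromere
#'
#' Variant-free centromeric gaps break molecular linkage, so each arm is
#' concatenated separately and the two arm haplotypes are joined using all
#' Hi-C links between the arms (no distance cap). The relative arm phase
#' is the sign of the aggregated `n_plus - n_minus` under the current
#' phases; on a tie (or with no inter-arm links) the arms are left
#' unjoined with a warning.
#'
#' @param scaffold Per-site scaffold tibble (from [apply_block_phases()]).
#' @param links Hi-C molecular link table.
#' @param sites Site table carrying an `arm` column.
#' @return `scaffold` with the q arm flipped onto the p-arm gauge where the
#'   join succeeded, a shared `scaffold_id`, and an `arm` column. The
#'   per-chromosome join outcome is in the `"arm_join"` attribute.
#' @export
join_arms <- function(scaffold, links, sites) {
  sites <- validate_sites(sites)
  if (!"arm" %in% names(sites) || all(is.na(sites$arm))) {
    abort("`sites` must carry p/q arm assignments to join arms.")
  }
  pairs <- count_linkage(links, sites, max_distance = Inf)
  scaffold$arm <- sites$arm[scaffold$site]
  scaffold$chrom <- sites$chrom[scaffold$site]
  ph <- rep(NA_integer_, nrow(sites))
  ph[scaffold$site] <- scaffold$phase
  arm_of <- sites$arm
  chrom_of <- sites$chrom
  report <- list()
  for (ch in unique(scaffold$chrom)) {
    idx <- chrom_of[pairs$i] == ch & !is.na(arm_of[pairs$i]) &
      !is.na(arm_of[pairs$j]) & arm_of[pairs$i] != arm_of[pairs$j]
    pp <- pairs[idx & !is.na(ph[pairs$i]) & !is.na(ph[pairs$j]), ]
    hh <- ph[pp$i] * ph[pp$j]
    n_cis <- sum(ifelse(hh == 1, pp$n_plus, pp$n_minus))
    n_trans <- sum(ifelse(hh == 1, pp$n_minus, pp$n_plus))
    joined <- n_cis != n_trans
    if (!joined) {
      warn(paste0("Chromosome ", ch, ": no decisive inter-arm Hi-C linkage; ",
                  "arms left unjoined."))
    } else if (n_trans > n_cis) {
      flip <- scaffold$chrom == ch & !is.na(scaffold$arm) &
        scaffold$arm == "q"
      scaffold$phase[flip] <- -scaffold$phase[flip]
    }
    if (joined) {
      on_ch <- scaffold$chrom == ch
      scaffold$scaffold_id[on_ch] <- min(scaffold$scaffold_id[on_ch])
    }
    report[[ch]] <- tibble(chrom = ch, n_cis = n_cis, n_trans = n_trans,
                           joined = joined)
  }
  attr(scaffold, "arm_join") <- bind_rows(report)
  scaffold
}

#' Expected cis fraction between blocks with internal switching
#'
#' If two blocks carry fractions `f1` and `f2` of their genotypes on
#' haplotype A, the fraction of Hi-C links between them that appear cis is
#' `rho = f1 * f2 + (1 - f1) * (1 - f2)`. Error-free blocks (`f` of 0 or 1)
#' give `rho` of 0 or 1 (fully informative); a single mid-block switch
#' drives `f` toward 0.5 and `rho` toward 0.5, destroying the signal --
#' which is why block boundaries are cut conservatively before
#' concatenation.
#'
#' @param f1,f2 Haplotype-A fractions in `[0, 1]` (vectorized).
#' @return The expected apparent cis fraction.
#' @examples
#' switched_block_specificity(1, 1)    # 1
#' switched_block_specificity(0.5, 0.9)  # 0.5
#' @export
switched_block_specificity <- function(f1, f2) {
  if (any(f1 < 0 | f1 > 1 | f2 < 0 | f2 > 1)) {
    abort("`f1` and `f2` must lie in [0, 1].")
  }
  f1 * f2 + (1 - f1) * (1 - f2)
}

#' Cis/trans consistency report for a solved scaffold
#'
#' After concatenation, every linked block pair should show a cis-link
#' majority under the final phases; a pair with `n_minus >= n_plus` marks
#' an inconsistent join worth inspecting.
#'
#' @param scaffold Per-site scaffold tibble (with final `phase`).
#' @param links Hi-C molecular link table.
#' @param sites Site table.
#' @param max_distance Distance cap matching the one used for
#'   concatenation.
#' @return Per-block-pair tibble: `s`, `t`, `n_plus`, `n_minus`, `flagged`.
#' @export
cis_trans_report <- function(scaffold, links, sites, max_distance = Inf) {
  final_blocks <- scaffold |>
    transmute(site = .data$site, spin = .data$phase,
              block_id = .data$block_id)
  interblock_linkage(final_blocks, links, sites,
                     max_distance = max_distance) |>
    mutate(flagged = .data$n_minus >= .data$n_plus)
}
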