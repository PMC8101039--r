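#' Two-tier whole-chromosome phasing pipeline
#'
#' Runs the full method on in-memory tables: (1) local phasing of the
#' linked-read (or long-read) linkage by energy minimization, with the
#' distance cap suppressing barcode-collision noise; (2) segmentation into
#' high-confidence blocks at the switch-penalty cutoff; (3) concatenation
#' of blocks with aggregated Hi-C links, first within each chromosome arm
#' (variant-to-variant distance cap) and then joining the p and q arms
#' with all inter-arm links; (4) re-phasing of every variant against the
#' scaffold with the linkage filter applied.
#'
#' @param sites Site table.
#' @param local_links Molecular links for local phasing (linked reads or
#'   long reads).
#' @param hic_links Hi-C molecular links for concatenation.
#' @param max_link_distance Distance cap for local pairwise linkage (bp).
#' @param cutoff Switch-penalty cutoff, or `"auto"` for
#'   [suggest_cutoff()].
#' @param min_report_size Minimum block size before a block is flagged
#'   short.
#' @param min_links Minimum aggregated links to couple two blocks.
#' @param within_arm_max_distance Distance cap for the within-arm
#'   concatenation stage (bp).
#' @param max_rounds Maximum minimizer rounds.
#' @param molecule_gap Gap used by [split_molecules()] to break collided
#'   barcodes into molecules (`NULL` skips splitting).
#' @return A `hap_pipeline` list: `fit`, `cutoff`, `blocks`, `block_phases`,
#'   `scaffold`, `solution`, `arm_join`.
#' @export
phase_pipeline <- function(sites, local_links, hic_links,
                           max_link_distance = 1e5, cutoff = "auto",
                           min_report_size = 50, min_links = 2,
                           within_arm_max_distance = 1e7, max_rounds = 50,
                           molecule_gap = 5e4) {
  sites <- validate_sites(sites)
  if (!is.null(molecule_gap)) {
    local_links <- split_molecules(local_links, sites, max_gap = molecule_gap)
  }
  pairs <- count_linkage(local_links, sites,
                         max_distance = max_link_distance) |>
    estimate_error_rates()
  fit <- minimize_energy(pairs, n_sites = nrow(sites),
                         max_rounds = max_rounds)
  if (identical(cutoff, "auto")) {
    cutoff <- suggest_cutoff(
      fit, median_link_coverage = median(pairs$n_plus + pairs$n_minus))
  }
  blocks <- segment_blocks(fit, cutoff, min_report_size = min_report_size)

  # only high-confidence blocks enter the scaffold; sites in short blocks
  # (including the low-coverage chromosome ends and isolated false
  # variants) are re-phased against the finished scaffold instead
  hq <- blocks |> filter(!.data$short)
  if (nrow(hq) == 0) abort("No block reaches `min_report_size` sites.")
  block_pairs <- interblock_linkage(hq, hic_links, sites,
                                    max_distance = within_arm_max_distance)
  have_arms <- "arm" %in% names(sites) && !all(is.na(sites$arm))
  if (have_arms) {
    # stage 1 couples blocks within one chromosome arm only
    block_arm <- hq |>
      mutate(arm = sites$arm[.data$site]) |>
      distinct(.data$block_id, .data$arm)
    arm_of <- setNames(block_arm$arm, block_arm$block_id)
    block_pairs <- block_pairs |>
      filter(arm_of[as.character(.data$s)] == arm_of[as.character(.data$t)])
  }
  concat <- concatenate_blocks(hq, block_pairs, min_links = min_links)
  scaffold <- apply_block_phases(hq, concat)
  arm_join <- NULL
  if (have_arms) {
    scaffold <- join_arms(scaffold, hic_links, sites)
    arm_join <- attr(scaffold, "arm_join")
  }
  solution <- finalize_phase(bind_rows(local_links, hic_links),
                             scaffold, sites)
  structure(list(fit = fit, cutoff = cutoff, blocks = blocks,
                 block_phases = concat, scaffold = scaffold,
                 solution = solution, arm_join = arm_join),
            class = "hap_pipeline")
}

#' @exportS3Method base::print
print.hap_pipeline <- function(x, ...) {
  cat("<hap_pipeline> ", x$fit$n_sites, " sites, ",
      max(x$blocks$block_id), " block(s), cutoff ", format(x$cutoff),
      ", ", sum(x$solution$phased), " phased\n", sep = "")
  invisible(x)
}
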