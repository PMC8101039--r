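#' Intra-block phasing accuracy against a truth haplotype
#'
#' For each block, `f` is the fraction of phased genotypes agreeing with
#' the truth haplotype and the accuracy is `max(f, 1 - f)` -- the fraction
#' consistent with the block's majority haplotype assignment. The metric
#' ranges from 0.5 (random, or a single mid-block switch) to 1 and is
#' deliberately sensitive to long-range switching errors, which push a
#' large fraction of genotypes onto the minor haplotype.
#'
#' @param blocks Per-site block table (`site`, `spin`, `block_id`).
#' @param truth Truth haplotype tibble (`site`, `spin`).
#' @return Per-block tibble: `block_id`, `n_truth` (overlapping truth
#'   sites), `f`, `accuracy`. Blocks with no truth overlap are skipped.
#' @export
intra_block_accuracy <- function(blocks, truth) {
  t_spin <- setNames(truth$spin, truth$site)
  blocks |>
    mutate(truth_spin = unname(t_spin[as.character(.data$site)])) |>
    filter(!is.na(.data$truth_spin)) |>
    group_by(.data$block_id) |>
    summarise(n_truth = n(),
              f = mean(.data$spin == .data$truth_spin),
              .groups = "drop") |>
    mutate(accuracy = pmax(.data$f, 1 - .data$f))
}

#' Length-weighted N50 of block spans
#'
#' @param spans Numeric vector of block lengths (bp).
#' @return The largest length `L` such that blocks of length `>= L` cover
#'   at least half the total span.
#' @export
block_n50 <- function(spans) {
  spans <- sort(spans[spans > 0], decreasing = TRUE)
  if (length(spans) == 0) return(NA_real_)
  spans[which(cumsum(spans) >= sum(spans) / 2)[1]]
}

#' Benchmark a haplotype solution against truth haplotypes
#'
#' Computes the completeness (fraction of truth variants that are phased
#' in the solution) and the global accuracy (per chromosome, the larger of
#' the agreement fraction and its complement: parental labels are a gauge
#' choice, so a solution equal to the complement of the truth is perfect).
#' When a per-site block table is supplied, the N50 of block spans is
#' reported as well.
#'
#' @param solution Tibble with `site` and `phase` (+1/-1/NA) -- the final
#'   solution or a scaffold.
#' @param truth Truth haplotype tibble (`site`, `spin`).
#' @param sites Site table (for chromosomes and positions).
#' @param blocks Optional per-site block table for the N50.
#' @return A `hap_benchmark` object with per-chromosome and overall
#'   metrics; see [glance()].
#' @export
benchmark_phasing <- function(solution, truth, sites, blocks = NULL) {
  sites <- validate_sites(sites)
  phased <- solution |> filter(!is.na(.data$phase))
  joined <- inner_join(phased[, c("site", "phase")],
                       truth[, c("site", "spin")], by = "site")
  if (nrow(joined) == 0) {
    abort("Solution and truth share no phased sites.")
  }
  joined$chrom <- sites$chrom[joined$site]
  per_chrom <- joined |>
    group_by(.data$chrom) |>
    summarise(n_compared = n(),
              f = mean(.data$phase == .data$spin), .groups = "drop") |>
    mutate(accuracy = pmax(.data$f, 1 - .data$f))
  truth_chrom <- tibble(chrom = sites$chrom[truth$site]) |>
    count(.data$chrom, name = "n_truth")
  per_chrom <- left_join(per_chrom, truth_chrom, by = "chrom") |>
    mutate(completeness = .data$n_compared / .data$n_truth)
  overall <- tibble(
    n_truth = nrow(truth),
    n_compared = nrow(joined),
    completeness = nrow(joined) / nrow(truth),
    accuracy = sum(per_chrom$accuracy * per_chrom$n_compared) /
      sum(per_chrom$n_compared)
  )
  n50 <- NA_real_
  if (!is.null(blocks)) {
    spans <- blocks |>
      mutate(pos = sites$pos[.data$site]) |>
      group_by(.data$block_id) |>
      summarise(span = max(.data$pos) - min(.data$pos) + 1, .groups = "drop")
    n50 <- block_n50(spans$span)
  }
  structure(list(overall = overall, per_chromosome = per_chrom, n50 = n50),
            class = "hap_benchmark")
}

#' @exportS3Method base::print
print.hap_benchmark <- function(x, ...) {
  cat("<hap_benchmark> accuracy ",
      sprintf("%.4f", x$overall$accuracy),
      ", completeness ", sprintf("%.4f", x$overall$completeness),
      " (", x$overall$n_compared, "/", x$overall$n_truth, " sites)",
      if (!is.na(x$n50)) paste0(", block N50 ", format(x$n50), " bp"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.hap_benchmark <- function(x, ...) x$per_chromosome

#' @export
glance.hap_benchmark <- function(x, ...) {
  x$overall |> mutate(n50 = x$n50)
}

#' Read-count threshold for allelic coverage in a single cell
#'
#' A variant site in a single-cell genome is considered to show reference
#' (or alternate) coverage only when at least `d* = max(2, 1 + 0.1 * mean
#' chromosome depth)` reads support that allele: the floor of 2 reads
#' removes random sequencing errors and the 10%-of-depth term removes
#' low-frequency amplification errors.
#'
#' @param mean_depth Mean sequencing depth of the chromosome (vectorized).
#' @return The threshold in reads.
#' @examples
#' coverage_threshold(30)  # 4
#' coverage_threshold(8)   # 2
#' @export
coverage_threshold <- function(mean_depth) {
  if (any(mean_depth < 0)) abort("`mean_depth` must be non-negative.")
  pmax(2, 1 + 0.1 * mean_depth)
}

#' Normalized heterozygosity of a chromosome in a single cell
#'
#' The fraction of heterozygous sites showing both alleles at or above the
#' read threshold `d_star`, divided by the square of the mean allelic
#' coverage fraction `(p_ref + p_alt) / 2`. A disomic chromosome with
#' adequate depth gives values near 1; a monosomic chromosome, carrying
#' one parental haplotype, gives values near 0.
#'
#' @param cell_counts Per-site counts for one cell and chromosome:
#'   `ref_count`, `alt_count` at parental heterozygous sites.
#' @param d_star Read threshold from [coverage_threshold()].
#' @return The normalized heterozygosity (NA when no allele reaches the
#'   threshold at any site).
#' @export
normalized_heterozygosity <- function(cell_counts, d_star) {
  ref_ok <- cell_counts$ref_count >= d_star
  alt_ok <- cell_counts$alt_count >= d_star
  p_ref <- mean(ref_ok)
  p_alt <- mean(alt_ok)
  if (p_ref + p_alt == 0) return(NA_real_)
  mean(ref_ok & alt_ok) / (((p_ref + p_alt) / 2)^2)
}

#' Select monosomic (cell, chromosome) pairs
#'
#' A chromosome in a cell is called completely monosomic when its
#' normalized heterozygosity falls below 0.1 times the median normalized
#' heterozygosity of the diploid calibration cells (which is close to 1).
#'
#' @param nh_table Tibble with `cell`, `chrom`, `nh`.
#' @param diploid_cells Character vector of calibration cell ids known to
#'   be disomic.
#' @param factor Multiple of the diploid median used as the cutoff.
#' @return The monosomic rows of `nh_table`, with the cutoff in the
#'   `"cutoff"` attribute.
#' @export
select_monosomies <- function(nh_table, diploid_cells, factor = 0.1) {
  cal <- nh_table |> filter(.data$cell %in% diploid_cells)
  if (nrow(cal) == 0) abort("No diploid calibration cells found.")
  cutoff <- factor * median(cal$nh, na.rm = TRUE)
  out <- nh_table |> filter(!is.na(.data$nh), .data$nh < cutoff)
  attr(out, "cutoff") <- cutoff
  out
}

#' Assemble reference haplotypes from monosomic cells
#'
#' Each monosomic cell exposes one parental haplotype directly: the allele
#' it shows (at coverage `>= d_star`) at a heterozygous site is the allele
#' of the retained homolog. Cells may carry either homolog, so homolog
#' identity is first resolved per chromosome by orienting each cell to
#' maximize allele agreement with the consensus of the cells before it;
#' the reference allele call at each site is then the consensus across
#' oriented cells, requiring at least `min_agreement` of the votes (and at
#' least one vote); conflicted sites are dropped.
#'
#' @param cell_counts Long tibble for monosomic (cell, chromosome) pairs:
#'   `cell`, `chrom`, `site`, `ref_count`, `alt_count`.
#' @param sites Site table.
#' @param d_star Read threshold, a single value or named per cell.
#' @param min_agreement Consensus fraction required to keep a site.
#' @return A truth-haplotype tibble: `site`, `spin` (+1 = reference allele
#'   on the reference homolog "A"), `n_cells` voting.
#' @export
reference_from_monosomies <- function(cell_counts, sites, d_star = 2,
                                      min_agreement = 2 / 3) {
  sites <- validate_sites(sites)
  cc <- as_tibble(cell_counts)
  ds <- if (length(d_star) > 1) d_star[cc$cell] else d_star
  obs <- cc |>
    mutate(d = as.numeric(ds),
           ref_ok = .data$ref_count >= .data$d,
           alt_ok = .data$alt_count >= .data$d,
           spin = ifelse(.data$ref_ok & !.data$alt_ok, 1L,
                         ifelse(.data$alt_ok & !.data$ref_ok, -1L,
                                NA_integer_))) |>
    filter(!is.na(.data$spin))
  result <- list()
  for (ch in unique(obs$chrom)) {
    oc <- obs |> filter(.data$chrom == ch)
    cells <- unique(oc$cell)
    consensus <- numeric(0)  # named by site: running oriented vote sum
    oriented <- list()
    for (cl in cells) {
      o <- oc |> filter(.data$cell == cl)
      v <- setNames(o$spin, o$site)
      common <- intersect(names(v), names(consensus))
      flip <- 1L
      if (length(common) > 0) {
        agree <- mean(sign(consensus[common]) == v[common], na.rm = TRUE)
        if (!is.nan(agree) && agree < 0.5) flip <- -1L
      }
      v <- v * flip
      oriented[[cl]] <- tibble(site = as.integer(names(v)), spin = unname(v))
      add <- setdiff(names(v), names(consensus))
      consensus[add] <- 0
      consensus[names(v)] <- consensus[names(v)] + v
    }
    votes <- bind_rows(oriented) |>
      group_by(.data$site) |>
      summarise(n_cells = n(),
                n_plus = sum(.data$spin == 1L), .groups = "drop") |>
      mutate(frac = pmax(.data$n_plus, .data$n_cells - .data$n_plus) /
               .data$n_cells,
             spin = ifelse(.data$n_plus >= .data$n_cells - .data$n_plus,
                           1L, -1L)) |>
      filter(.data$frac >= min_agreement)
    result[[ch]] <- votes[, c("site", "spin", "n_cells")]
  }
  bind_rows(result) |> arrange(.data$site)
}
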