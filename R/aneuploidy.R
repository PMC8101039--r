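#' Haplotype-specific coverage in genomic bins
#'
#' For each fixed-width bin i the haplotype-specific coverage is
#' `C_A = D * R_A` and `C_B = D * R_B`, where `D` is the normalized mean
#' sequence depth of the bin (genome mean 1) and `R_A` is the mean, over
#' phased variants in the bin, of the fraction of allelic reads supporting
#' the allele on haplotype A (`R_B = 1 - R_A`). The haplotype fraction is
#' averaged per variant, then per bin, making it robust to coverage spikes
#' at single sites.
#'
#' @param depth Per-bin depth track: tibble with `chrom`, `start`, `end`
#'   (0-based half-open, width `bin_bp`), `depth`. Renormalized to mean 1.
#' @param allele_counts Per-site read counts: `site`, `ref_count`,
#'   `alt_count`.
#' @param phase Per-site phase (+1 = reference allele on haplotype A):
#'   tibble with `site`, `phase` (e.g. the final solution).
#' @param sites Site table.
#' @param bin_bp Bin width in bp (default 250 kb).
#' @return Per-bin tibble: `chrom`, `start`, `end`, `depth`, `r_a`, `r_b`,
#'   `c_a`, `c_b`, `n_sites`, `covered` (FALSE where no phased variant
#'   falls in the bin and the haplotype fractions are undefined).
#' @export
bin_coverage <- function(depth, allele_counts, phase, sites,
                         bin_bp = 250000) {
  sites <- validate_sites(sites)
  depth <- as_tibble(depth)
  depth$depth <- depth$depth / mean(depth$depth)
  ph <- phase[!is.na(phase$phase), c("site", "phase")]
  ac <- as_tibble(allele_counts) |>
    inner_join(ph, by = "site") |>
    mutate(
      chrom = sites$chrom[.data$site],
      start = (sites$pos[.data$site] - 1) %/% bin_bp * bin_bp,
      total = .data$ref_count + .data$alt_count,
      reads_a = ifelse(.data$phase == 1L, .data$ref_count, .data$alt_count)
    ) |>
    filter(.data$total > 0)
  frac <- ac |>
    group_by(.data$chrom, .data$start) |>
    summarise(r_a = mean(.data$reads_a / .data$total), n_sites = n(),
              .groups = "drop")
  out <- depth |>
    left_join(frac, by = c("chrom", "start")) |>
    mutate(
      covered = !is.na(.data$r_a) & .data$n_sites > 0,
      n_sites = coalesce(.data$n_sites, 0L),
      r_b = 1 - .data$r_a,
      c_a = .data$depth * .data$r_a,
      c_b = .data$depth * .data$r_b
    )
  out
}

#' Haplotype-specific DNA copy number
#'
#' For a genome whose modal state is diploid, the median of the per-bin
#' haplotype coverages `C_A`, `C_B` (pooled over both haplotypes, covered
#' bins only) estimates the coverage of a single homolog. Dividing by this
#' unit converts coverage to copy number: 1 per haplotype in unaltered
#' bins, 0 on a lost homolog, non-integer values for subclonal changes
#' (e.g. ~1.45 for a gain present in ~45% of cells).
#'
#' @param bins Output of [bin_coverage()].
#' @return `bins` with `cn_a`, `cn_b` columns (copy number per haplotype).
#' @export
copy_number <- function(bins) {
  unit <- median(c(bins$c_a[bins$covered], bins$c_b[bins$covered]),
                 na.rm = TRUE)
  if (!is.finite(unit) || unit <= 0) {
    abort("Degenerate single-homolog coverage unit (median <= 0).")
  }
  bins |>
    mutate(cn_a = .data$c_a / unit, cn_b = .data$c_b / unit)
}

#' Phased Hi-C contact map
#'
#' Assigns each end of a Hi-C link to a parental haplotype through the
#' phased variant it covers (spin x phase: +1 = haplotype A) and
#' accumulates contact counts per bin pair and haplotype combination
#' (AA/AB/BA/BB, first letter = lower-coordinate end). Rearrangement
#' junctions appear as contact enrichment confined to one combination,
#' which phases the junction and lets derivative chromosomes be walked.
#'
#' @param links Hi-C molecular link table.
#' @param phase Per-site phase tibble (`site`, `phase`).
#' @param sites Site table.
#' @param bin_bp Bin width in bp (default 1 Mb).
#' @return Sparse contact tibble: `chrom_i`, `bin_i`, `chrom_j`, `bin_j`
#'   (bin start coordinates), `combo`, `count`. The number of link ends
#'   skipped for lacking a phased variant is in the `"skipped"` attribute.
#' @export
phased_contacts <- function(links, phase, sites, bin_bp = 1e6) {
  sites <- validate_sites(sites)
  links <- validate_links(links, sites)
  ph <- rep(NA_integer_, nrow(sites))
  ph[phase$site[!is.na(phase$phase)]] <- phase$phase[!is.na(phase$phase)]
  obs <- links |>
    mutate(h = ph[.data$site] * .data$spin,
           chrom = sites$chrom[.data$site],
           bin = (sites$pos[.data$site] - 1) %/% bin_bp * bin_bp)
  n_unphased <- sum(is.na(obs$h))
  obs <- obs |> filter(!is.na(.data$h))
  # all unordered pairs of phased ends within each molecule; the common
  # case (a read pair with two phased ends) is handled vectorized
  obs <- obs |>
    arrange(.data$molecule, .data$chrom, .data$bin) |>
    group_by(.data$molecule) |>
    mutate(n_obs = n()) |>
    ungroup() |>
    filter(.data$n_obs >= 2)
  two <- obs |> filter(.data$n_obs == 2)
  a <- two[seq(1, nrow(two), by = 2), ]
  b <- two[seq(2, nrow(two), by = 2), ]
  pairs <- tibble(chrom_i = a$chrom, bin_i = a$bin, hap_i = a$h,
                  chrom_j = b$chrom, bin_j = b$bin, hap_j = b$h)
  many <- obs |> filter(.data$n_obs > 2)
  if (nrow(many) > 0) {
    extra <- many |>
      group_by(.data$molecule) |>
      reframe({
        idx <- which(upper.tri(diag(n())), arr.ind = TRUE)
        tibble(
          chrom_i = .data$chrom[idx[, 1]], bin_i = .data$bin[idx[, 1]],
          hap_i = .data$h[idx[, 1]],
          chrom_j = .data$chrom[idx[, 2]], bin_j = .data$bin[idx[, 2]],
          hap_j = .data$h[idx[, 2]]
        )
      }) |>
      select(-"molecule")
    pairs <- bind_rows(pairs, extra)
  }
  out <- pairs |>
    mutate(combo = paste0(ifelse(.data$hap_i == 1L, "A", "B"),
                          ifelse(.data$hap_j == 1L, "A", "B"))) |>
    count(.data$chrom_i, .data$bin_i, .data$chrom_j, .data$bin_j,
          .data$combo, name = "count")
  attr(out, "skipped") <- n_unphased
  out
}
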