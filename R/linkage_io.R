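#' Load heterozygous variant sites from a VCF
#'
#' Reads a VCF (4.x, plain text or bgzipped), keeps bi-allelic heterozygous
#' sites of the first sample, and assigns dense site indices in coordinate
#' order. By default only SNVs are retained; `include_indels = TRUE` also
#' keeps bi-allelic heterozygous indels (used when re-phasing variants
#' against a finished scaffold, where indel genotyping errors no longer
#' propagate into the energy model). Sites overlapping `exclusion_bed`
#' (e.g. centromeric, pericentric, or acrocentric bands) are flagged and
#' dropped from the phasing input.
#'
#' @param vcf_path Path to the VCF file. Records must be coordinate-sorted.
#' @param exclusion_bed Optional BED file of regions to exclude.
#' @param centromeres Optional tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open) locating the centromere; used to assign sites to
#'   the `"p"` or `"q"` arm. Sites inside the interval are excluded.
#' @param include_indels Keep bi-allelic heterozygous indels as well as SNVs.
#' @param keep_excluded Return excluded sites (with `excluded = TRUE` and
#'   `index = NA`) instead of dropping them.
#' @return A site tibble (see [validate_sites()]) with columns `index`,
#'   `chrom`, `pos`, `ref`, `alt`, `arm`, `excluded`. The number of sites
#'   removed by each rule is stored in the `"dropped"` attribute.
#' @export
read_vcf_sites <- function(vcf_path, exclusion_bed = NULL, centromeres = NULL,
                           include_indels = FALSE, keep_excluded = FALSE) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix_m <- vcfR::getFIX(v)
  if (is.null(dim(fix_m))) {  # single-record VCFs come back as a vector
    fix_m <- matrix(fix_m, nrow = 1, dimnames = list(NULL, names(fix_m)))
  }
  fix <- as_tibble(as.data.frame(fix_m, stringsAsFactors = FALSE))
  if (nrow(fix) == 0) abort("VCF contains no records.")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(gt) && is.null(dim(gt))) gt <- matrix(gt, ncol = 1)
  raw <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gt = if (is.null(gt)) NA_character_ else gt[, 1]
  )
  sorted <- raw |>
    group_by(.data$chrom) |>
    summarise(ok = !is.unsorted(.data$pos, strictly = FALSE), .groups = "drop")
  if (!all(sorted$ok)) abort("VCF records are not coordinate-sorted.")

  is_biallelic <- !is.na(raw$alt) & !grepl(",", raw$alt, fixed = TRUE)
  is_snv <- nchar(raw$ref) == 1 & nchar(raw$alt) == 1 &
    raw$ref != raw$alt & raw$ref %in% c("A", "C", "G", "T")
  alleles <- strsplit(gsub("\\|", "/", raw$gt), "/", fixed = TRUE)
  is_het <- vapply(alleles, function(a) {
    length(a) == 2 && all(c("0", "1") %in% a)
  }, logical(1))
  keep <- is_biallelic & is_het & (is_snv | include_indels)
  dropped <- c(
    multiallelic = sum(!is_biallelic),
    not_het = sum(is_biallelic & !is_het),
    indel = if (include_indels) 0L else sum(is_biallelic & is_het & !is_snv)
  )
  sites <- raw[keep, c("chrom", "pos", "ref", "alt")]
  if (nrow(sites) == 0) abort("No heterozygous sites survive filtering.")

  sites$excluded <- FALSE
  if (!is.null(exclusion_bed)) {
    sites$excluded <- sites$excluded | in_bed_regions(sites, exclusion_bed)
  }
  sites$arm <- NA_character_
  if (!is.null(centromeres)) {
    cen <- as_tibble(centromeres)
    for (k in seq_len(nrow(cen))) {
      on_chrom <- sites$chrom == cen$chrom[k]
      sites$arm[on_chrom & sites$pos <= cen$start[k]] <- "p"
      sites$arm[on_chrom & sites$pos > cen$end[k]] <- "q"
      sites$excluded[on_chrom & sites$pos > cen$start[k] &
                       sites$pos <= cen$end[k]] <- TRUE
    }
  }
  dropped <- c(dropped, excluded = sum(sites$excluded))
  if (!keep_excluded) sites <- sites[!sites$excluded, ]
  if (nrow(sites) == 0 || all(sites$excluded)) {
    abort("No heterozygous sites survive filtering.")
  }
  sites$index <- NA_integer_
  sites$index[!sites$excluded] <- seq_len(sum(!sites$excluded))
  out <- sites[, c("index", "chrom", "pos", "ref", "alt", "arm", "excluded")]
  attr(out, "dropped") <- dropped
  out
}

in_bed_regions <- function(sites, bed_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    abort("BED exclusion requires the rtracklayer and GenomicRanges packages.")
  }
  regions <- rtracklayer::import(bed_path, format = "BED")
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  GenomicRanges::countOverlaps(gr, regions) > 0
}

#' Write or read a fragment file of molecular links
#'
#' The fragment file is the plain-text interchange for molecular linkage
#' evidence: one molecule per line, with tab-separated fields
#' `molecule_id`, `source`, `chrom`, followed by a single field of
#' space-separated `site:spin` pairs where spin is `+` (reference allele)
#' or `-` (alternate allele) and `site` is the 1-based index into the site
#' table. Lines are newline-terminated with no trailing whitespace, so a
#' write/read round trip is byte-stable.
#'
#' @param links Molecular link table (see [validate_links()]).
#' @param sites Site table, used to record the chromosome of each molecule.
#' @param path Output (or input) file path.
#' @return `write_fragments()` returns `path` invisibly; `read_fragments()`
#'   returns a link tibble.
#' @export
write_fragments <- function(links, sites, path) {
  links <- validate_links(links, sites)
  chrom <- sites$chrom[links$site]
  body <- tibble(
    molecule = links$molecule, source = links$source, chrom = chrom,
    pair = paste0(links$site, ":", ifelse(links$spin > 0, "+", "-"))
  ) |>
    group_by(.data$molecule, .data$source, .data$chrom) |>
    summarise(obs = paste(.data$pair, collapse = " "), .groups = "drop") |>
    arrange(.data$molecule)
  lines <- paste(body$molecule, body$source, body$chrom, body$obs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path, sites = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(molecule = character(), source = character(),
                  site = integer(), spin = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4)
  if (length(bad) > 0) {
    abort(paste0("Malformed fragment line ", bad[1], ": expected 4 fields."))
  }
  mol <- vapply(fields, `[`, character(1), 1)
  src <- vapply(fields, `[`, character(1), 2)
  pairs <- strsplit(vapply(fields, `[`, character(1), 4), " ", fixed = TRUE)
  n_obs <- lengths(pairs)
  flat <- unlist(pairs, use.names = FALSE)
  m <- regmatches(flat, regexec("^([0-9]+):([+-])$", flat))
  ok <- lengths(m) == 3
  if (!all(ok)) {
    line_of <- rep(seq_along(lines), n_obs)
    abort(paste0("Malformed fragment line ", line_of[which(!ok)[1]],
                 ": bad site:spin token '", flat[which(!ok)[1]], "'."))
  }
  links <- tibble(
    molecule = rep(mol, n_obs),
    source = rep(src, n_obs),
    site = as.integer(vapply(m, `[`, character(1), 2)),
    spin = ifelse(vapply(m, `[`, character(1), 3) == "+", 1L, -1L)
  )
  validate_links(links, sites)
}

#' Reconstruct molecules by splitting barcode groups at large gaps
#'
#' A molecular barcode tags every fragment of one long DNA molecule, but by
#' chance it can also tag unrelated molecules ("barcode collisions"), whose
#' apparent linkage is ~50% cis / 50% trans and would contaminate both the
#' energy model and the final per-molecule votes. Since distinct molecules
#' sharing a barcode rarely lie close together, splitting a barcode's
#' observations wherever consecutive covered sites are separated by more
#' than `max_gap` (or lie on different chromosomes) recovers the underlying
#' molecules. Hi-C molecules are left untouched: their two distant ends
#' are the signal.
#'
#' @param links Molecular link table.
#' @param sites Site table (for positions).
#' @param max_gap Maximum within-molecule gap in bp (default 50 kb).
#' @return A link table with collided molecules split into parts.
#' @export
split_molecules <- function(links, sites, max_gap = 5e4) {
  links <- validate_links(links, sites)
  sites <- validate_sites(sites)
  keep <- links |> filter(.data$source == "hic")
  lr <- links |> filter(.data$source != "hic")
  if (nrow(lr) == 0) return(links)
  pos <- sites$pos[lr$site]
  chrom <- sites$chrom[lr$site]
  brk <- lr$molecule != lag(lr$molecule, default = "") |
    chrom != lag(chrom, default = "") |
    pos - lag(pos, default = 0) > max_gap
  part <- cumsum(brk)
  lr$molecule <- paste0(lr$molecule, "#", part)
  bind_rows(lr, keep)
}

#' Count pairwise haplotype linkage between variant sites
#'
#' For every pair of sites co-observed by at least one molecule and
#' separated by at most `max_distance` base pairs, counts the number of
#' molecules supporting cis linkage (`n_plus`: both spins equal, i.e.
#' ref-ref or alt-alt) and trans linkage (`n_minus`: opposite spins). Each
#' molecule contributes at most one link per pair. The default distance cap
#' of 100 kb matches the useful range of linked-read molecules; linkage
#' beyond the molecule size is dominated by barcode-collision noise with
#' ~50% cis consistency and is excluded from local phasing.
#'
#' @param links Molecular link table.
#' @param sites Site table (for positions).
#' @param max_distance Maximum site separation in bp (`Inf` to disable).
#' @return Tibble with columns `i`, `j` (site indices, `i < j`), `n_plus`,
#'   `n_minus`.
#' @export
count_linkage <- function(links, sites, max_distance = 1e5) {
  links <- validate_links(links, sites)
  sites <- validate_sites(sites)
  if (nrow(links) == 0) {
    return(tibble(i = integer(), j = integer(),
                  n_plus = integer(), n_minus = integer()))
  }
  mol <- match(links$molecule, unique(links$molecule))
  chrom_code <- match(sites$chrom, unique(sites$chrom))
  res <- count_pair_links_cpp(mol, as.integer(links$site),
                              as.integer(links$spin), chrom_code,
                              as.numeric(sites$pos), max_distance)
  as_tibble(res)
}

#' Estimate per-pair linkage error rates and coupling weights
#'
#' The error rate of the linkage between sites i and j is estimated from
#' the observed fraction of minor (discordant) linkage,
#' `min(n_plus, n_minus) / (n_plus + n_minus)`, floored at the dataset-level
#' random-error rate `epsilon0` (by default the average minor-linkage
#' fraction over all pairs). The coupling weight of the pair is
#' `M_ij = (n_plus - n_minus) * chi_ij` with
#' `chi_ij = log((1 - epsilon_ij) / epsilon_ij)`, so pairs whose discordant
#' linkage is large (false variants, mapping artefacts) are automatically
#' down-weighted.
#'
#' @param pairs Pair-count tibble from [count_linkage()].
#' @param epsilon0 Optional override for the dataset-level error floor.
#' @param epsilon_max Upper clamp on `epsilon_ij` keeping `chi_ij` positive
#'   and finite; a majority-discordant pair then carries near-zero weight.
#' @param epsilon_min Lower clamp keeping `chi_ij` finite when no
#'   discordant linkage at all is observed (error-free data would
#'   otherwise give infinite weights).
#' @return `pairs` with columns `epsilon`, `chi`, `weight` added and the
#'   floor recorded in the `"epsilon0"` attribute.
#' @export
estimate_error_rates <- function(pairs, epsilon0 = NULL, epsilon_max = 0.49,
                                 epsilon_min = 1e-4) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) abort("No linkage pairs to estimate error rates from.")
  total <- pairs$n_plus + pairs$n_minus
  if (any(total < 1)) abort("Every pair must have at least one link.")
  frac <- pmin(pairs$n_plus, pairs$n_minus) / total
  if (is.null(epsilon0)) epsilon0 <- mean(frac)
  if (epsilon0 >= 0.5) {
    abort("Majority of linkage is discordant (epsilon0 >= 0.5); check input.")
  }
  eps <- pmin(pmax(epsilon0, frac, epsilon_min), epsilon_max)
  pairs$epsilon <- eps
  pairs$chi <- log((1 - eps) / eps)
  pairs$weight <- (pairs$n_plus - pairs$n_minus) * pairs$chi
  attr(pairs, "epsilon0") <- epsilon0
  pairs
}

#' Linkage density and accuracy by genomic distance
#'
#' Computes, per genomic-distance bin: the fraction of site pairs linked by
#' at least one molecule, the mean number of links between linked pairs,
#' and (when a truth haplotype is supplied) the fraction of links
#' consistent with cis linkage. These diagnostics characterise a linkage
#' data type: linked reads show a molecule-length-limited range with a
#' ~50% cis-consistency plateau from barcode collisions beyond it, while
#' Hi-C shows a power-law density decay with >90% cis consistency
#' throughout.
#'
#' @param links Molecular link table.
#' @param sites Site table.
#' @param truth Optional truth haplotype tibble with columns `site`, `spin`
#'   (+1 when the reference allele lies on haplotype A).
#' @param breaks Distance bin edges in bp.
#' @return One row per distance bin: `distance_lo`, `distance_hi`,
#'   `n_pairs`, `n_linked`, `frac_linked`, `mean_links`, `cis_fraction`.
#' @export
linkage_statistics <- function(links, sites, truth = NULL,
                               breaks = c(0, 1e3, 2e3, 5e3, 1e4, 2e4, 5e4,
                                          1e5, 2e5, 5e5, 1e6)) {
  sites <- validate_sites(sites)
  breaks <- sort(unique(breaks))
  pairs <- count_linkage(links, sites, max_distance = max(breaks))
  dist <- sites$pos[pairs$j] - sites$pos[pairs$i]
  bin <- cut(dist, breaks, right = TRUE, labels = FALSE)

  # total pairs per bin, counted analytically from sorted positions
  pair_count_upto <- function(d) {
    sum(vapply(split(sites$pos, sites$chrom), function(p) {
      sum(findInterval(p + d, p) - seq_along(p))
    }, numeric(1)))
  }
  cum <- vapply(breaks, pair_count_upto, numeric(1))
  totals <- diff(cum)

  per_pair <- tibble(bin = bin,
                     n_links = pairs$n_plus + pairs$n_minus,
                     n_plus = pairs$n_plus, n_minus = pairs$n_minus,
                     i = pairs$i, j = pairs$j)
  if (!is.null(truth)) {
    t_spin <- rep(NA_integer_, nrow(sites))
    t_spin[truth$site] <- truth$spin
    tt <- t_spin[per_pair$i] * t_spin[per_pair$j]
    per_pair$n_cis <- ifelse(tt == 1, per_pair$n_plus,
                             ifelse(tt == -1, per_pair$n_minus, NA_integer_))
  }
  agg <- per_pair |>
    filter(!is.na(.data$bin)) |>
    group_by(.data$bin) |>
    summarise(
      n_linked = n(),
      mean_links = mean(.data$n_links),
      cis_fraction = if (!is.null(truth)) {
        sum(.data$n_cis, na.rm = TRUE) /
          sum(.data$n_links[!is.na(.data$n_cis)])
      } else NA_real_,
      .groups = "drop"
    )
  out <- tibble(
    bin = seq_len(length(breaks) - 1),
    distance_lo = breaks[-length(breaks)],
    distance_hi = breaks[-1],
    n_pairs = totals
  ) |>
    left_join(agg, by = "bin") |>
    mutate(
      n_linked = coalesce(.data$n_linked, 0L),
      frac_linked = ifelse(.data$n_pairs > 0, .data$n_linked / .data$n_pairs, NA_real_),
      mean_links = coalesce(.data$mean_links, 0)
    ) |>
    select(-"bin")
  out
}
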