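#' Linkage between individual variants and the scaffold haplotype
#'
#' Once a chromosome-scale scaffold exists, every variant (scaffold
#' members, previously unphased SNVs, and indels) is re-phased against it.
#' Each molecule covering the variant and at least one other scaffold site
#' casts one vote: the molecule is assigned to scaffold haplotype A or B by
#' a strict majority of its scaffold-site genotypes (ties discard the
#' molecule), and the combination of its genotype at the variant (ref/alt)
#' with that assignment increments exactly one of the four counts
#' `n_ref_a`, `n_alt_a`, `n_ref_b`, `n_alt_b`. The variant's own scaffold
#' contribution is excluded from its votes.
#'
#' Distinct scaffolds (e.g. unjoined arms of one chromosome) carry
#' independent haplotype gauges, so a molecule's vote is computed within a
#' single scaffold -- the one contributing most of its sites -- and each
#' variant is phased relative to the scaffold used by most of its voting
#' molecules. Scaffolds with fewer than `min_scaffold_sites` phased sites
#' (isolated mini-blocks whose gauge is arbitrary) are not used as a
#' reference frame; their sites are re-phased like any other variant.
#'
#' @param links Molecular link table (all sources may be pooled).
#' @param scaffold Per-site scaffold tibble with `phase` (+1 when the
#'   reference allele lies on haplotype A) and `scaffold_id` columns.
#' @param sites Optional site table for validation.
#' @param min_scaffold_sites Minimum sites for a scaffold to serve as a
#'   phase reference.
#' @return One row per variant site covered by any molecule: the four
#'   unique-molecule counts, the combined evidence `eta_ra`, `eta_rb` from
#'   [combined_evidence()], and the reference `scaffold_id`.
#' @export
scaffold_linkage <- function(links, scaffold, sites = NULL,
                             min_scaffold_sites = 50) {
  links <- validate_links(links, sites)
  if (!"scaffold_id" %in% names(scaffold)) scaffold$scaffold_id <- 1L
  use <- scaffold |>
    group_by(.data$scaffold_id) |>
    filter(n() >= min_scaffold_sites) |>
    ungroup()
  if (nrow(use) == 0) abort("No scaffold is large enough to phase against.")
  n_max <- max(links$site, scaffold$site)
  ph <- rep(NA_integer_, n_max)
  sc <- rep(0L, n_max)  # 0 = not a scaffold site
  ph[use$site] <- use$phase
  sc[use$site] <- match(use$scaffold_id, sort(unique(use$scaffold_id)))
  scaf_ids <- sort(unique(use$scaffold_id))
  n_scaf <- length(scaf_ids)

  mol <- match(links$molecule, unique(links$molecule))
  n_mol <- max(mol)
  site <- links$site
  spin <- links$spin
  scaf <- sc[site]
  vote <- ifelse(scaf > 0L, spin * ph[site], 0L)

  # dominant scaffold per molecule (most scaffold sites observed)
  cnt <- matrix(tabulate((mol - 1L) * n_scaf + scaf,
                         nbins = n_mol * n_scaf),
                nrow = n_mol, byrow = TRUE)
  dom <- max.col(cnt, ties.method = "first")
  dom[rowSums(cnt) == 0] <- 0L

  # each molecule votes with its dominant scaffold's sites only
  in_dom <- scaf > 0L & scaf == dom[mol]
  v <- as.numeric(vote) * in_dom
  msum <- numeric(n_mol)
  sums <- rowsum(v, mol)
  msum[as.integer(rownames(sums))] <- sums[, 1]
  hap <- as.integer(sign(msum[mol] - v))
  keep <- hap != 0L & dom[mol] > 0L

  # phase each variant in the gauge of its molecules' modal scaffold
  site_k <- site[keep]
  dom_k <- dom[mol[keep]]
  sk_cnt <- matrix(tabulate((site_k - 1L) * n_scaf + dom_k,
                            nbins = n_max * n_scaf),
                   nrow = n_max, byrow = TRUE)
  site_scaf <- max.col(sk_cnt, ties.method = "first")
  keep2 <- keep & dom[mol] == site_scaf[site]

  cls <- 1L + (spin[keep2] == -1L) + 2L * (hap[keep2] == -1L)
  tab <- matrix(tabulate((site[keep2] - 1L) * 4L + cls, nbins = n_max * 4L),
                nrow = n_max, byrow = TRUE)
  covered <- which(rowSums(tab) > 0)
  counts <- tibble(
    site = covered,
    n_ref_a = tab[covered, 1], n_alt_a = tab[covered, 2],
    n_ref_b = tab[covered, 3], n_alt_b = tab[covered, 4],
    scaffold_id = scaf_ids[site_scaf[covered]]
  )
  combined_evidence(counts)
}

#' Combined linkage evidence for a variant
#'
#' The two ways a variant can segregate with the scaffold are "reference on
#' A" (supported by ref-A and alt-B molecules) and "reference on B"
#' (supported by ref-B and alt-A molecules):
#' `eta_ra = n_ref_a + n_alt_b`, `eta_rb = n_ref_b + n_alt_a`.
#'
#' @param counts Tibble with columns `n_ref_a`, `n_alt_a`, `n_ref_b`,
#'   `n_alt_b` (e.g. from [scaffold_linkage()]).
#' @return `counts` with `eta_ra` and `eta_rb` columns added.
#' @export
combined_evidence <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("n_ref_a", "n_alt_a", "n_ref_b", "n_alt_b")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    abort(paste0("Missing count column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(unlist(counts[need]) < 0)) abort("Counts must be non-negative.")
  counts |>
    mutate(eta_ra = .data$n_ref_a + .data$n_alt_b,
           eta_rb = .data$n_ref_b + .data$n_alt_a)
}

#' Linkage filter for true heterozygous variants
#'
#' A true heterozygous variant has both genotypes present on complementary
#' haplotypes, so (I) all four marginal counts must be positive --
#' (Ia) `n_ref_a + n_ref_b > 0`, (Ib) `n_alt_a + n_alt_b > 0`,
#' (Ic) `n_ref_a + n_alt_a > 0`, (Id) `n_ref_b + n_alt_b > 0` -- and (II)
#' its linkage must segregate: the minor combined evidence may not exceed
#' `max(2, 0.1 * (eta_ra + eta_rb))`. False variants typically show
#' balanced linkage to both haplotypes and fail criterion (II).
#'
#' @param counts Tibble from [scaffold_linkage()] /
#'   [combined_evidence()].
#' @return `counts` with logical `filter_pass` and `filter_reason` (`"pass"`
#'   or the first violated criterion, `"Ia"`..`"Id"`, `"II"`).
#' @export
linkage_filter <- function(counts) {
  counts <- combined_evidence(counts)
  ia <- counts$n_ref_a + counts$n_ref_b > 0
  ib <- counts$n_alt_a + counts$n_alt_b > 0
  ic <- counts$n_ref_a + counts$n_alt_a > 0
  id <- counts$n_ref_b + counts$n_alt_b > 0
  ii <- pmin(counts$eta_ra, counts$eta_rb) <=
    pmax(2, 0.1 * (counts$eta_ra + counts$eta_rb))
  reason <- rep("pass", nrow(counts))
  reason[!ii] <- "II"
  reason[!id] <- "Id"
  reason[!ic] <- "Ic"
  reason[!ib] <- "Ib"
  reason[!ia] <- "Ia"
  counts$filter_pass <- ia & ib & ic & id & ii
  counts$filter_reason <- reason
  counts
}

#' Final phase call from combined evidence
#'
#' Filter-passing variants are phased to the side with the larger combined
#' evidence: reference on haplotype A (`phase = +1`) when
#' `eta_ra > eta_rb`, reference on B (`phase = -1`) when `eta_rb > eta_ra`,
#' and left unphased on a tie. Filtered variants are never phased.
#'
#' @param counts Tibble from [linkage_filter()].
#' @return `counts` with `phase` (+1 / -1 / `NA`) and logical `phased`.
#' @export
phase_final <- function(counts) {
  if (!"filter_pass" %in% names(counts)) counts <- linkage_filter(counts)
  phase <- ifelse(counts$eta_ra > counts$eta_rb, 1L,
                  ifelse(counts$eta_rb > counts$eta_ra, -1L, NA_integer_))
  phase[!counts$filter_pass] <- NA_integer_
  counts$phase <- phase
  counts$phased <- !is.na(phase)
  counts
}

#' Re-phase all variants against a scaffold and apply the linkage filter
#'
#' Convenience wrapper chaining [scaffold_linkage()], [linkage_filter()]
#' and [phase_final()], and attaching site coordinates and scaffold ids.
#'
#' @param links Molecular link table (pool linked-read and Hi-C links).
#' @param scaffold Per-site scaffold tibble.
#' @param sites Site table.
#' @param min_scaffold_sites Passed to [scaffold_linkage()].
#' @return The final haplotype solution: one row per covered variant with
#'   counts, evidence, filter verdict, `phase`, and `scaffold_id`.
#' @export
finalize_phase <- function(links, scaffold, sites, min_scaffold_sites = 50) {
  sites <- validate_sites(sites)
  sol <- scaffold_linkage(links, scaffold, sites,
                          min_scaffold_sites = min_scaffold_sites) |>
    linkage_filter() |>
    phase_final()
  sol |>
    mutate(chrom = sites$chrom[.data$site], pos = sites$pos[.data$site]) |>
    select("site", "chrom", "pos", everything())
}

#' Write a phased VCF
#'
#' Emits a minimal VCF 4.2 with diploid genotypes: phased variants carry
#' `GT` `0|1` (reference allele on haplotype A) or `1|0`, with the
#' phase-set annotation `PS` set to the scaffold id; unphased or filtered
#' variants carry `0/1`. The linkage-filter verdict goes to the FILTER
#' column (`PASS` or the violated criterion).
#'
#' @param solution Final solution from [finalize_phase()].
#' @param sites Site table.
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(solution, sites, path, sample = "SAMPLE") {
  sites <- validate_sites(sites)
  sol <- solution[order(solution$site), ]
  s <- sites[match(sol$site, sites$index), ]
  gt <- ifelse(is.na(sol$phase), "0/1",
               ifelse(sol$phase == 1L, "0|1", "1|0"))
  ps <- ifelse(is.na(sol$phase) | is.na(sol$scaffold_id), ".",
               as.character(sol$scaffold_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hapforge",
    "##FILTER=<ID=Ia,Description=\"No molecule links the reference allele to either haplotype\">",
    "##FILTER=<ID=Ib,Description=\"No molecule links the alternate allele to either haplotype\">",
    "##FILTER=<ID=Ic,Description=\"No molecule links haplotype A to either allele\">",
    "##FILTER=<ID=Id,Description=\"No molecule links haplotype B to either allele\">",
    "##FILTER=<ID=II,Description=\"Minor combined linkage exceeds max(2, 0.1 x total): non-segregating\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set (scaffold id)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  filt <- ifelse(sol$filter_reason == "pass", "PASS", sol$filter_reason)
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", filt, ".",
                "GT:PS", paste0(gt, ":", ps), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
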