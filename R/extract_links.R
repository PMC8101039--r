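#' Extract molecular links from coordinate-sorted alignments
#'
#' Converts aligned reads into molecular links: the set of variant-site
#' genotypes observed on one DNA molecule. The molecule is defined by the
#' data type: in `"linked_read"` mode all reads sharing a molecular barcode
#' tag on one chromosome form a molecule, split wherever the gap between
#' consecutive reads exceeds `max_gap` (suppressing barcode collisions,
#' which tag unrelated molecules and carry ~50%-accurate linkage); in
#' `"hic"` mode the two mates of a read pair form a molecule; in
#' `"long_read"` mode each read is a molecule. A read base matching the
#' reference allele contributes spin +1, one matching the alternate allele
#' contributes -1, and any other base is ignored. Duplicate-flagged and
#' low-mapping-quality reads are skipped, and a molecule observing a site
#' with conflicting bases contributes no spin there.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param sites Site table from [read_vcf_sites()].
#' @param mode One of `"linked_read"`, `"hic"`, `"long_read"`.
#' @param barcode_tag BAM tag holding the molecular barcode
#'   (`"BX"` for 10x-style linked reads).
#' @param min_mapq Minimum mapping quality.
#' @param max_gap Maximum gap (bp) between consecutive reads of one
#'   barcode before the molecule is split (linked-read mode only).
#' @return A molecular link tibble (see [validate_links()]); counts of
#'   skipped reads are stored in the `"skipped"` attribute.
#' @export
extract_links <- function(bam, sites,
                          mode = c("linked_read", "hic", "long_read"),
                          barcode_tag = "BX", min_mapq = 20, max_gap = 5e4) {
  mode <- match.arg(mode)
  for (pkg in c("Rsamtools", "GenomicAlignments", "GenomicRanges",
                "IRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(paste0("extract_links() requires the ", pkg, " package."))
    }
  }
  sites <- validate_sites(sites)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    abort("BAM file must be indexed (.bai not found).")
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE,
                                 isSecondaryAlignment = FALSE)
  what <- c("qname", "mapq", "seq")
  tags <- if (mode == "linked_read") barcode_tag else character()
  param <- Rsamtools::ScanBamParam(flag = flag, what = what, tag = tags)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(gal)
  mapq_ok <- !is.na(md$mapq) & md$mapq >= min_mapq
  skipped <- c(low_mapq = sum(!mapq_ok), no_barcode = 0L)
  gal <- gal[mapq_ok]
  md <- S4Vectors::mcols(gal)

  if (mode == "linked_read") {
    bx <- md[[barcode_tag]]
    has_bx <- !is.na(bx)
    skipped["no_barcode"] <- sum(!has_bx)
    gal <- gal[has_bx]
    md <- S4Vectors::mcols(gal)
  }
  if (length(gal) == 0) {
    out <- tibble(molecule = character(), source = character(),
                  site = integer(), spin = integer())
    attr(out, "skipped") <- skipped
    return(out)
  }

  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(sgr, GenomicRanges::granges(gal))
  si <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  if (length(si) == 0) {
    out <- tibble(molecule = character(), source = character(),
                  site = integer(), spin = integer())
    attr(out, "skipped") <- skipped
    return(out)
  }
  laid <- GenomicAlignments::sequenceLayer(md$seq[ri],
                                           GenomicAlignments::cigar(gal)[ri])
  offset <- sites$pos[si] - GenomicRanges::start(gal)[ri] + 1L
  base <- as.character(Biostrings::subseq(laid, start = offset, width = 1L))
  spin <- ifelse(base == sites$ref[si], 1L,
                 ifelse(base == sites$alt[si], -1L, NA_integer_))

  obs <- tibble(
    read = md$qname[ri],
    read_pos = GenomicRanges::start(gal)[ri],
    chrom = as.character(GenomicRanges::seqnames(gal))[ri],
    barcode = if (mode == "linked_read") {
      S4Vectors::mcols(gal)[[barcode_tag]][ri]
    } else NA_character_,
    site = sites$index[si],
    spin = spin
  ) |>
    filter(!is.na(.data$spin))

  source_label <- c(linked_read = "linked_read", hic = "hic",
                    long_read = "long_read")[[mode]]
  if (mode == "linked_read") {
    # split barcode groups at gaps > max_gap to break collision molecules
    obs <- obs |>
      arrange(.data$barcode, .data$chrom, .data$read_pos) |>
      group_by(.data$barcode, .data$chrom) |>
      mutate(part = cumsum(c(0, diff(.data$read_pos)) > .env$max_gap)) |>
      ungroup() |>
      mutate(molecule = paste(.data$barcode, .data$chrom, .data$part,
                              sep = "#"))
  } else {
    obs$molecule <- obs$read
  }

  links <- obs |>
    group_by(.data$molecule, .data$site) |>
    summarise(spin = if (length(unique(.data$spin)) == 1) {
      .data$spin[1]
    } else NA_integer_, .groups = "drop") |>
    filter(!is.na(.data$spin)) |>
    mutate(source = source_label) |>
    select("molecule", "source", "site", "spin")
  out <- validate_links(links, sites)
  attr(out, "skipped") <- skipped
  out
}
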