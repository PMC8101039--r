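#' Simulate a diploid genome with known haplotypes
#'
#' Generates heterozygous SNV sites with a known truth phase, plus the
#' artefacts the phasing method must cope with: false variants (genotyping
#' artefacts whose "genotypes" do not segregate with either haplotype),
#' loss-of-heterozygosity intervals empty of true heterozygous sites, and
#' a variant-free centromeric gap splitting each chromosome into p and q
#' arms. Site density follows a Poisson process at `het_density_per_kb`
#' (about 1/kb in a typical human genome).
#'
#' @param seed Integer seed; the output is fully deterministic given it.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Chromosome length(s) in bp, recycled.
#' @param het_density_per_kb Expected true heterozygous sites per kb.
#' @param loh_intervals Optional tibble `chrom`, `start`, `end` (0-based
#'   half-open) of loss-of-heterozygosity regions.
#' @param false_variant_rate False variants as a fraction of the expected
#'   true variant count.
#' @param centromere_gap_bp Width of the centromeric variant-free gap.
#' @return A `hap_genome` list: `sites` (with `is_false`), `truth`
#'   (`site`, `spin`: +1 = reference allele on haplotype A), `centromeres`,
#'   `chrom_lengths`.
#' @export
simulate_genome <- function(seed, n_chrom = 1, chrom_length_bp = 30e6,
                            het_density_per_kb = 1, loh_intervals = NULL,
                            false_variant_rate = 0.01,
                            centromere_gap_bp = 3e6) {
  stopifnot(het_density_per_kb > 0)
  lens <- rep_len(chrom_length_bp, n_chrom)
  if (any(centromere_gap_bp >= lens)) {
    abort("`centromere_gap_bp` must be smaller than the chromosome length.")
  }
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  bases <- c("A", "C", "G", "T")
  all_sites <- list()
  cens <- list()
  for (k in seq_len(n_chrom)) {
    L <- lens[k]
    cen_start <- floor(L / 2 - centromere_gap_bp / 2)
    cen_end <- cen_start + centromere_gap_bp
    n_true <- rpois(1, L * het_density_per_kb / 1000)
    n_false <- rpois(1, L * het_density_per_kb / 1000 * false_variant_rate)
    pos_true <- sample.int(L, n_true)
    pos_false <- sample.int(L, n_false)
    in_gap <- function(p) p > cen_start & p <= cen_end
    in_loh <- function(p) {
      if (is.null(loh_intervals)) return(rep(FALSE, length(p)))
      iv <- loh_intervals[loh_intervals$chrom == chroms[k], ]
      out <- rep(FALSE, length(p))
      for (r in seq_len(nrow(iv))) {
        out <- out | (p > iv$start[r] & p <= iv$end[r])
      }
      out
    }
    pos_true <- pos_true[!in_gap(pos_true) & !in_loh(pos_true)]
    pos_false <- pos_false[!in_gap(pos_false)]
    pos_false <- setdiff(pos_false, pos_true)
    df <- tibble(
      chrom = chroms[k],
      pos = c(pos_true, pos_false),
      is_false = rep(c(FALSE, TRUE), c(length(pos_true), length(pos_false)))
    ) |>
      arrange(.data$pos)
    df$ref <- sample(bases, nrow(df), replace = TRUE)
    df$alt <- vapply(df$ref, function(r) sample(setdiff(bases, r), 1),
                     character(1))
    df$arm <- ifelse(df$pos <= cen_start, "p", "q")
    all_sites[[k]] <- df
    cens[[k]] <- tibble(chrom = chroms[k], start = cen_start, end = cen_end)
  }
  sites <- bind_rows(all_sites) |>
    mutate(excluded = FALSE, index = seq_len(n())) |>
    select("index", "chrom", "pos", "ref", "alt", "arm", "excluded",
           "is_false")
  truth <- tibble(site = sites$index[!sites$is_false],
                  spin = sample(c(-1L, 1L), sum(!sites$is_false),
                                replace = TRUE))
  structure(list(sites = sites, truth = truth,
                 centromeres = bind_rows(cens),
                 chrom_lengths = setNames(lens, chroms)),
            class = "hap_genome")
}

#' @exportS3Method base::print
print.hap_genome <- function(x, ...) {
  cat("<hap_genome> ", length(x$chrom_lengths), " chromosome(s), ",
      nrow(x$sites), " sites (", sum(x$sites$is_false), " false)\n", sep = "")
  invisible(x)
}

truth_spin_lookup <- function(genome) {
  t_spin <- rep(NA_integer_, nrow(genome$sites))
  t_spin[genome$truth$site] <- genome$truth$spin
  t_spin
}

# emitted spin of a site on a given haplotype (+1 = A), with genotyping
# error; false variants emit random, non-segregating genotypes
emit_spins <- function(site, hap, t_spin, spin_error) {
  spin <- t_spin[site] * hap
  false_idx <- is.na(spin)
  spin[false_idx] <- sample(c(-1L, 1L), sum(false_idx), replace = TRUE)
  flip <- rbinom(length(spin), 1, spin_error) == 1
  spin[flip] <- -spin[flip]
  as.integer(spin)
}

#' Simulate linked-read molecular links
#'
#' Draws DNA molecules with exponentially distributed lengths from a
#' random parental haplotype, placed uniformly; each heterozygous site a
#' molecule covers emits that haplotype's allele, flipped with probability
#' `spin_error`. When `molecules_per_barcode > 1`, several unrelated
#' molecules share one barcode and are reported as a single molecular link
#' (barcode collisions): their cross-molecule "linkage" is ~50% cis and
#' ~50% trans, reproducing the accuracy plateau seen beyond the molecule
#' length in real linked-read data.
#'
#' @param genome A `hap_genome` from [simulate_genome()].
#' @param coverage Mean sequence coverage contributed by molecules.
#' @param mean_molecule_bp Mean molecule length (exponential).
#' @param molecules_per_barcode Molecules sharing each barcode (1 disables
#'   collisions).
#' @param spin_error Per-observation genotype error probability.
#' @param seed Integer seed.
#' @return A molecular link tibble (`source = "linked_read"`).
#' @export
simulate_linked_reads <- function(genome, coverage = 60,
                                  mean_molecule_bp = 5e4,
                                  molecules_per_barcode = 2,
                                  spin_error = 0.01, seed = 1) {
  stopifnot(coverage > 0, mean_molecule_bp > 0, molecules_per_barcode >= 1)
  set.seed(seed)
  t_spin <- truth_spin_lookup(genome)
  obs <- list()
  mol_offset <- 0L
  for (ch in names(genome$chrom_lengths)) {
    L <- genome$chrom_lengths[[ch]]
    s <- genome$sites[genome$sites$chrom == ch, ]
    n_mol <- round(coverage * L / mean_molecule_bp)
    start <- runif(n_mol, 1, L)
    len <- rexp(n_mol, 1 / mean_molecule_bp)
    hap <- sample(c(-1L, 1L), n_mol, replace = TRUE)
    lo <- findInterval(start - 1, s$pos) + 1L
    hi <- findInterval(start + len, s$pos)
    n_cov <- pmax(hi - lo + 1L, 0L)
    keep <- n_cov > 0
    site <- s$index[sequence(n_cov[keep], from = lo[keep])]
    mol <- rep(seq_len(n_mol)[keep], n_cov[keep]) + mol_offset
    obs[[ch]] <- tibble(
      mol = mol, site = site,
      spin = emit_spins(site, rep(hap[keep], n_cov[keep]), t_spin,
                        spin_error)
    )
    mol_offset <- mol_offset + n_mol
  }
  obs <- bind_rows(obs)
  if (molecules_per_barcode > 1) {
    n_mol <- mol_offset
    k <- as.integer(molecules_per_barcode)
    bc_of <- ceiling(sample.int(n_mol) / k)
    obs$mol <- bc_of[obs$mol]
    # a barcode may observe one site through two collided molecules:
    # concordant duplicates collapse, conflicting ones are dropped
    key <- obs$mol * (nrow(genome$sites) + 1) + obs$site
    dup_keys <- unique(key[duplicated(key)])
    if (length(dup_keys) > 0) {
      in_dup <- key %in% dup_keys
      resolved <- obs[in_dup, ] |>
        group_by(.data$mol, .data$site) |>
        summarise(spin = if (length(unique(.data$spin)) == 1) {
          .data$spin[1]
        } else NA_integer_, .groups = "drop") |>
        filter(!is.na(.data$spin))
      obs <- bind_rows(obs[!in_dup, ], resolved)
    }
  }
  obs |>
    transmute(molecule = sprintf("LR%07d", .data$mol),
              source = "linked_read",
              site = .data$site, spin = .data$spin) |>
    arrange(.data$molecule, .data$site)
}

#' Simulate Hi-C molecular links
#'
#' Each link is a proximity-ligation read pair: with probability
#' `1 - trans_fraction` both ends come from the same parental chromosome,
#' separated by a distance drawn from a truncated power law (density
#' proportional to `d^-powerlaw_exponent`, `d >= min_separation`);
#' otherwise the two ends come from independently chosen haplotypes.
#' Each end is snapped to the nearest heterozygous site and emits that
#' haplotype's allele with error `spin_error`.
#'
#' @param genome A `hap_genome`.
#' @param n_links Number of variant-informative link pairs to draw.
#' @param powerlaw_exponent Distance-decay exponent (> 1).
#' @param trans_fraction Fraction of inter-homolog (noise) links.
#' @param spin_error Per-observation genotype error probability.
#' @param seed Integer seed.
#' @param min_separation Lower truncation of the distance law (bp).
#' @return A molecular link tibble (`source = "hic"`, two observations per
#'   molecule).
#' @export
simulate_hic <- function(genome, n_links = 5e4, powerlaw_exponent = 1.5,
                         trans_fraction = 0.05, spin_error = 0.02,
                         seed = 1, min_separation = 1000) {
  stopifnot(powerlaw_exponent > 1, n_links > 0)
  set.seed(seed)
  t_spin <- truth_spin_lookup(genome)
  lens <- genome$chrom_lengths
  ch_idx <- sample(seq_along(lens), n_links, replace = TRUE,
                   prob = lens / sum(lens))
  out <- list()
  for (k in seq_along(lens)) {
    n <- sum(ch_idx == k)
    if (n == 0) next
    L <- lens[[k]]
    s <- genome$sites[genome$sites$chrom == names(lens)[k], ]
    p1 <- runif(n, 1, L)
    # inverse-CDF sample of d ~ d^-alpha on [min_separation, L]
    a1 <- 1 - powerlaw_exponent
    u <- runif(n)
    d <- (min_separation^a1 + u * (L^a1 - min_separation^a1))^(1 / a1)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    p2 <- p1 + sgn * d
    flip_dir <- p2 < 1 | p2 > L
    p2[flip_dir] <- p1[flip_dir] - (sgn * d)[flip_dir]
    p2 <- pmin(pmax(p2, 1), L)
    snap <- function(p) {
      lo <- findInterval(p, s$pos)
      lo_c <- pmax(lo, 1L)
      hi_c <- pmin(lo + 1L, nrow(s))
      use_hi <- lo < 1L |
        (lo < nrow(s) & (s$pos[hi_c] - p) < (p - s$pos[lo_c]))
      s$index[ifelse(use_hi, hi_c, lo_c)]
    }
    e1 <- snap(p1)
    e2 <- snap(p2)
    hap1 <- sample(c(-1L, 1L), n, replace = TRUE)
    is_trans <- runif(n) < trans_fraction
    hap2 <- hap1
    hap2[is_trans] <- sample(c(-1L, 1L), sum(is_trans), replace = TRUE)
    keep <- e1 != e2
    mol_id <- which(ch_idx == k)[keep]
    out[[k]] <- tibble(
      mol = c(mol_id, mol_id),
      site = c(e1[keep], e2[keep]),
      hap = c(hap1[keep], hap2[keep])
    )
  }
  obs <- bind_rows(out)
  obs$spin <- emit_spins(obs$site, obs$hap, t_spin, spin_error)
  obs |>
    transmute(molecule = sprintf("HIC%07d", .data$mol), source = "hic",
              site = .data$site, spin = .data$spin) |>
    arrange(.data$molecule, .data$site)
}

#' Simulate single-cell allele counts with monosomies
#'
#' Disomic chromosomes emit reads from both parental haplotypes at about
#' half the cell's mean depth each; monosomic chromosomes emit only the
#' retained haplotype. A fraction `error_rate` of sites additionally
#' carries a low-frequency amplification artifact: spurious reads of the
#' opposite allele at 2-8% of the chromosome depth, the kind of false
#' heterozygosity the depth-scaled read threshold `d*` is designed to
#' suppress.
#'
#' @param genome A `hap_genome`.
#' @param cells Tibble with one row per (cell, chromosome): `cell`,
#'   `chrom`, `copies` (1 or 2), `hap` (+1/-1 homolog retained when
#'   `copies == 1`; `NA` draws one at random).
#' @param mean_depth Mean sequencing depth of a disomic chromosome.
#' @param error_rate Fraction of sites carrying an amplification artifact.
#' @param seed Integer seed.
#' @return A list: `counts` (tibble `cell`, `chrom`, `site`, `ref_count`,
#'   `alt_count` over true heterozygous sites) and `cell_chrom` (per
#'   (cell, chromosome) `copies`, `hap`, `mean_depth`).
#' @export
simulate_single_cells <- function(genome, cells, mean_depth = 10,
                                  error_rate = 0.05, seed = 1) {
  set.seed(seed)
  cells <- as_tibble(cells)
  t_spin <- truth_spin_lookup(genome)
  lambda <- mean_depth / 2  # per-homolog depth
  res <- list()
  meta <- list()
  for (r in seq_len(nrow(cells))) {
    ch <- cells$chrom[r]
    copies <- cells$copies[r]
    hap <- cells$hap[r]
    if (copies == 1 && is.na(hap)) hap <- sample(c(-1L, 1L), 1)
    s <- genome$sites[genome$sites$chrom == ch & !genome$sites$is_false, ]
    n <- nrow(s)
    t <- t_spin[s$index]
    if (copies == 2) {
      reads_a <- rpois(n, lambda)
      reads_b <- rpois(n, lambda)
    } else {
      reads_a <- if (hap == 1L) rpois(n, lambda) else integer(n)
      reads_b <- if (hap == -1L) rpois(n, lambda) else integer(n)
    }
    ref <- ifelse(t == 1L, reads_a, reads_b)
    alt <- ifelse(t == 1L, reads_b, reads_a)
    chrom_depth <- copies * lambda
    artifact <- runif(n) < error_rate
    err_reads <- integer(n)
    err_reads[artifact] <- rpois(sum(artifact),
                                 runif(sum(artifact), 0.02, 0.08) *
                                   chrom_depth)
    err_on_alt <- runif(n) < 0.5
    ref <- ref + ifelse(err_on_alt, 0L, err_reads)
    alt <- alt + ifelse(err_on_alt, err_reads, 0L)
    res[[r]] <- tibble(cell = cells$cell[r], chrom = ch, site = s$index,
                       ref_count = as.integer(ref),
                       alt_count = as.integer(alt))
    meta[[r]] <- tibble(cell = cells$cell[r], chrom = ch, copies = copies,
                        hap = if (copies == 1) hap else NA_integer_,
                        mean_depth = chrom_depth)
  }
  list(counts = bind_rows(res), cell_chrom = bind_rows(meta))
}

#' Simulate bulk coverage and allele counts for an aneuploid genome
#'
#' A mixture of clones, each with its own per-haplotype integer copy
#' number over genomic segments, generates a depth track proportional to
#' the clone-averaged total copy number (diploid = 1) with multiplicative
#' noise, and per-site allelic read counts proportional to the
#' clone-averaged copy number of each haplotype.
#'
#' @param genome A `hap_genome`.
#' @param segments Tibble `clone`, `chrom`, `start`, `end` (0-based
#'   half-open), `cn_a`, `cn_b`; regions not covered default to 1/1.
#' @param clone_fractions Named numeric vector of clone fractions summing
#'   to 1 (names matching `segments$clone`).
#' @param depth_noise Multiplicative (lognormal-like) noise sd on bin
#'   depth.
#' @param reads_per_site Mean allelic reads per site in a diploid region.
#' @param bin_bp Depth bin width.
#' @param seed Integer seed.
#' @return A list: `depth` (tibble `chrom`, `start`, `end`, `depth`) and
#'   `allele_counts` (tibble `site`, `ref_count`, `alt_count`).
#' @export
simulate_aneuploid_coverage <- function(genome, segments = NULL,
                                        clone_fractions = c(clone1 = 1),
                                        depth_noise = 0.02,
                                        reads_per_site = 60,
                                        bin_bp = 250000, seed = 1) {
  stopifnot(abs(sum(clone_fractions) - 1) < 1e-8)
  set.seed(seed)
  t_spin <- truth_spin_lookup(genome)
  cn_at <- function(chrom, pos) {
    # clone-averaged per-haplotype copy number at positions
    cn_a <- rep(0, length(pos))
    cn_b <- rep(0, length(pos))
    for (cl in names(clone_fractions)) {
      a <- rep(1, length(pos))
      b <- rep(1, length(pos))
      if (!is.null(segments)) {
        seg <- segments[segments$clone == cl & segments$chrom == chrom, ]
        for (r in seq_len(nrow(seg))) {
          hit <- pos > seg$start[r] & pos <= seg$end[r]
          a[hit] <- seg$cn_a[r]
          b[hit] <- seg$cn_b[r]
        }
      }
      cn_a <- cn_a + clone_fractions[[cl]] * a
      cn_b <- cn_b + clone_fractions[[cl]] * b
    }
    list(a = cn_a, b = cn_b)
  }
  depth <- list()
  counts <- list()
  for (ch in names(genome$chrom_lengths)) {
    L <- genome$chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = bin_bp)
    mid <- pmin(starts + bin_bp / 2, L)
    cn <- cn_at(ch, mid)
    d <- (cn$a + cn$b) / 2 * rnorm(length(mid), 1, depth_noise)
    depth[[ch]] <- tibble(chrom = ch, start = starts,
                          end = pmin(starts + bin_bp, L), depth = d)
    s <- genome$sites[genome$sites$chrom == ch & !genome$sites$is_false, ]
    cn_s <- cn_at(ch, s$pos)
    reads_a <- rpois(nrow(s), reads_per_site / 2 * cn_s$a)
    reads_b <- rpois(nrow(s), reads_per_site / 2 * cn_s$b)
    t <- t_spin[s$index]
    counts[[ch]] <- tibble(
      site = s$index,
      ref_count = as.integer(ifelse(t == 1L, reads_a, reads_b)),
      alt_count = as.integer(ifelse(t == 1L, reads_b, reads_a))
    )
  }
  list(depth = bind_rows(depth), allele_counts = bind_rows(counts))
}
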