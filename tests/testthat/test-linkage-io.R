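write_toy_vcf <- function(path, rows) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  writeLines(c(header, rows), path)
}

test_that("read_vcf_sites keeps bi-allelic het SNVs and indexes them", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, c(
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1",   # het SNV: keep
    "chr1\t200\t.\tC\tT\t.\t.\t.\tGT\t0/0",   # hom ref: drop
    "chr1\t300\t.\tG\tGA\t.\t.\t.\tGT\t0|1",  # het indel: drop by default
    "chr1\t400\t.\tT\tA,C\t.\t.\t.\tGT\t1/2", # multi-allelic: drop
    "chr1\t500\t.\tT\tC\t.\t.\t.\tGT\t1|0"    # het SNV: keep
  ))
  s <- read_vcf_sites(vcf)
  expect_identical(s$pos, c(100L, 500L))
  expect_identical(s$index, 1:2)
  si <- read_vcf_sites(vcf, include_indels = TRUE)
  expect_identical(si$pos, c(100L, 300L, 500L))
})

test_that("read_vcf_sites errors on unsorted input and empty results", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, c(
    "chr1\t500\t.\tA\tG\t.\t.\t.\tGT\t0/1",
    "chr1\t100\t.\tC\tT\t.\t.\t.\tGT\t0/1"
  ))
  expect_error(read_vcf_sites(vcf), "sorted")
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(vcf2, "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0")
  expect_error(read_vcf_sites(vcf2), "No heterozygous sites")
})

test_that("sites in excluded regions are flagged and dropped", {
  skip_if_not_installed("rtracklayer")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, c(
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1",
    "chr1\t250\t.\tC\tT\t.\t.\t.\tGT\t0/1",
    "chr1\t900\t.\tG\tA\t.\t.\t.\tGT\t0/1"
  ))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t200\t400", bed)
  s <- read_vcf_sites(vcf, exclusion_bed = bed)
  expect_identical(s$pos, c(100L, 900L))
  sk <- read_vcf_sites(vcf, exclusion_bed = bed, keep_excluded = TRUE)
  expect_identical(sk$excluded, c(FALSE, TRUE, FALSE))
  expect_true(is.na(sk$index[2]))
})

test_that("centromere interval assigns arms and excludes interior sites", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, c(
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1",
    "chr1\t550\t.\tC\tT\t.\t.\t.\tGT\t0/1",
    "chr1\t900\t.\tG\tA\t.\t.\t.\tGT\t0/1"
  ))
  cen <- tibble::tibble(chrom = "chr1", start = 500, end = 600)
  s <- read_vcf_sites(vcf, centromeres = cen)
  expect_identical(s$arm, c("p", "q"))
  expect_identical(s$pos, c(100L, 900L))
})

test_that("fragment files round-trip losslessly and byte-stably", {
  sites <- toy_sites(50)
  set.seed(42)
  links <- dplyr::bind_rows(lapply(1:20, function(k) {
    n <- sample(1:6, 1)
    st <- sort(sample(50, n))
    tibble::tibble(molecule = sprintf("mol%02d", k),
                   source = sample(c("linked_read", "hic", "long_read"), 1),
                   site = st,
                   spin = sample(c(-1L, 1L), n, replace = TRUE))
  }))
  f1 <- withr::local_tempfile(fileext = ".frag")
  write_fragments(links, sites, f1)
  back <- read_fragments(f1, sites)
  expect_equal(dplyr::arrange(back, molecule, site),
               dplyr::arrange(links, molecule, site))
  f2 <- withr::local_tempfile(fileext = ".frag")
  write_fragments(back, sites, f2)
  expect_identical(readLines(f1), readLines(f2))

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_identical(nrow(read_fragments(empty)), 0L)

  badf <- withr::local_tempfile()
  writeLines(c("m1\tlinked_read\tchr1\t1:+", "m2\tlinked_read\tchr1"), badf)
  expect_error(read_fragments(badf), "line 2")
  badf2 <- withr::local_tempfile()
  writeLines("m1\tlinked_read\tchr1\t1:x", badf2)
  expect_error(read_fragments(badf2), "bad site:spin")
})

test_that("count_linkage matches a brute-force double loop", {
  sites <- toy_sites(30, spacing = 500)
  set.seed(7)
  links <- dplyr::bind_rows(lapply(1:40, function(k) {
    n <- sample(2:6, 1)
    st <- sort(sample(30, n))
    tibble::tibble(molecule = sprintf("m%03d", k), source = "linked_read",
                   site = st, spin = sample(c(-1L, 1L), n, replace = TRUE))
  }))
  for (cap in c(Inf, 5000, 2000)) {
    got <- count_linkage(links, sites, max_distance = cap)
    want <- brute_pair_counts(links, sites, max_distance = cap)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("count_linkage applies the distance cap and counting rules", {
  sites <- toy_sites(3, spacing = 75000)  # 75 kb apart
  links <- toy_links(c(`1` = 1, `2` = 1), c(`1` = -1, `2` = -1),
                     c(`1` = 1, `2` = -1), c(`1` = 1, `3` = 1))
  got <- count_linkage(links, sites, max_distance = 1e5)
  expect_identical(nrow(got), 1L)  # pair (1,3) at 150 kb is absent
  expect_identical(got$n_plus, 2L)
  expect_identical(got$n_minus, 1L)
})

test_that("link totals are bounded by per-molecule pair counts", {
  sites <- toy_sites(20, spacing = 100)
  set.seed(11)
  links <- dplyr::bind_rows(lapply(1:15, function(k) {
    n <- sample(2:8, 1)
    st <- sort(sample(20, n))
    tibble::tibble(molecule = paste0("m", k), source = "linked_read",
                   site = st, spin = sample(c(-1L, 1L), n, replace = TRUE))
  }))
  pairs <- count_linkage(links, sites, max_distance = Inf)
  per_mol <- links |> dplyr::count(molecule)
  expect_equal(sum(pairs$n_plus + pairs$n_minus),
               sum(choose(per_mol$n, 2)))
  capped <- count_linkage(links, sites, max_distance = 500)
  expect_lte(sum(capped$n_plus + capped$n_minus),
             sum(pairs$n_plus + pairs$n_minus))
})

test_that("error-rate estimation follows the minor-fraction rule", {
  pairs <- tibble::tibble(i = c(1L, 1L), j = c(2L, 3L),
                          n_plus = c(9L, 10L), n_minus = c(1L, 0L))
  est <- estimate_error_rates(pairs, epsilon0 = 0.02)
  expect_equal(est$epsilon[1], 0.1)
  expect_equal(est$chi[1], log(9))
  expect_equal(est$weight[1], 8 * log(9))
  expect_equal(est$epsilon[2], 0.02)  # floored at epsilon0
  # epsilon0 defaults to the mean minor fraction
  est2 <- estimate_error_rates(pairs)
  expect_equal(attr(est2, "epsilon0"), mean(c(0.1, 0)))
  # idempotent: re-estimating with the same floor changes nothing
  est3 <- estimate_error_rates(est, epsilon0 = 0.02)
  expect_equal(est3$weight, est$weight)
  # the minor fraction is at most 0.5, reached only on exact ties
  expect_error(
    estimate_error_rates(tibble::tibble(i = 1L, j = 2L, n_plus = 5L,
                                        n_minus = 5L)),
    "discordant")
  # a majority-discordant pair still gets the minor fraction as epsilon
  sw <- estimate_error_rates(tibble::tibble(i = 1L, j = 2L, n_plus = 1L,
                                            n_minus = 9L), epsilon0 = 0.02)
  expect_equal(sw$epsilon, 0.1)
  expect_lt(sw$weight, 0)
})

test_that("molecule splitting breaks collided barcodes at large gaps", {
  sites <- toy_sites(10, spacing = 3e4)  # 30 kb spacing
  links <- toy_links(c(`1` = 1, `2` = 1, `8` = -1, `9` = -1))
  split <- split_molecules(links, sites, max_gap = 5e4)
  expect_identical(length(unique(split$molecule)), 2L)
  # hi-c links are never split
  hic <- toy_links(c(`1` = 1, `9` = 1), source = "hic")
  expect_identical(length(unique(split_molecules(hic, sites)$molecule)), 1L)
})

test_that("linkage statistics report density, multiplicity and accuracy", {
  sites <- toy_sites(4, spacing = 1000)
  truth <- tibble::tibble(site = 1:4, spin = c(1L, 1L, -1L, 1L))
  links <- toy_links(c(`1` = 1, `2` = 1), c(`1` = 1, `2` = 1),
                     c(`1` = 1, `3` = 1))  # pair (1,3) is trans in truth
  st <- linkage_statistics(links, sites, truth = truth,
                           breaks = c(0, 1500, 2500))
  expect_equal(st$n_pairs, c(3, 2))      # (1,2),(2,3),(3,4) then (1,3),(2,4)
  expect_equal(st$n_linked, c(1L, 1L))
  expect_equal(st$mean_links, c(2, 1))
  expect_equal(st$cis_fraction, c(1, 0))
  # bins with no linked pairs report zero density
  st2 <- linkage_statistics(links[1:2, ], sites,
                            breaks = c(0, 1500, 2500))
  expect_equal(st2$n_linked, c(1L, 0L))
  expect_equal(st2$frac_linked[2], 0)
})
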