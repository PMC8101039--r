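# Independent brute-force oracles used to check the optimized code paths.

# pairwise linkage counts by a double loop over molecules
brute_pair_counts <- function(links, sites, max_distance = Inf) {
  out <- list()
  for (m in unique(links$molecule)) {
    lm <- links[links$molecule == m, ]
    lm <- lm[order(lm$site), ]
    n <- nrow(lm)
    if (n < 2) next
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        i <- lm$site[a]; j <- lm$site[b]
        if (sites$chrom[i] != sites$chrom[j]) next
        if (abs(sites$pos[j] - sites$pos[i]) > max_distance) next
        key <- paste(i, j)
        e <- out[[key]] %||% c(i = i, j = j, n_plus = 0, n_minus = 0)
        if (lm$spin[a] * lm$spin[b] == 1) e["n_plus"] <- e["n_plus"] + 1
        else e["n_minus"] <- e["n_minus"] + 1
        out[[key]] <- e
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(i = integer(), j = integer(),
                          n_plus = integer(), n_minus = integer()))
  }
  df <- do.call(rbind, out)
  df <- tibble::as_tibble(as.data.frame(df))
  df[order(df$i, df$j), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive global minimum of the spin-model energy (gauge s1 = +1)
brute_energy_min <- function(pairs, n) {
  stopifnot(n <= 16)
  best <- Inf
  best_s <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    s <- c(1L, ifelse(bitwAnd(2^(0:(n - 2)), mask) > 0, -1L, 1L))
    e <- phase_energy(s, pairs)
    if (e < best) { best <- e; best_s <- s }
  }
  list(energy = best, spins = best_s)
}

# random sparse coupling instance with counts drawn around a planted truth
random_instance <- function(n, n_pairs, eps = 0.05, links_per_pair = 10,
                            seed = 1) {
  set.seed(seed)
  truth <- c(1L, sample(c(-1L, 1L), n - 1, replace = TRUE))
  ij <- t(utils::combn(n, 2))
  pick <- sample(nrow(ij), min(n_pairs, nrow(ij)))
  ij <- ij[pick, , drop = FALSE]
  cis <- rbinom(nrow(ij), links_per_pair, 1 - eps)
  tt <- truth[ij[, 1]] * truth[ij[, 2]]
  pairs <- tibble::tibble(
    i = ij[, 1], j = ij[, 2],
    n_plus = ifelse(tt == 1, cis, links_per_pair - cis),
    n_minus = ifelse(tt == 1, links_per_pair - cis, cis)
  )
  pairs <- pairs[pairs$n_plus + pairs$n_minus > 0, ]
  list(pairs = estimate_error_rates(pairs, epsilon0 = eps), truth = truth)
}

# per-molecule tally of variant-to-scaffold linkage (single scaffold frame)
brute_scaffold_counts <- function(links, scaffold_phase, v) {
  # scaffold_phase: named vector site -> phase
  res <- c(n_ref_a = 0L, n_alt_a = 0L, n_ref_b = 0L, n_alt_b = 0L)
  for (m in unique(links$molecule)) {
    lm <- links[links$molecule == m, ]
    if (!v %in% lm$site) next
    sv <- lm$spin[lm$site == v]
    others <- lm[lm$site != v & lm$site %in% as.integer(names(scaffold_phase)), ]
    # include the variant's own scaffold contribution? no: exclude v itself
    if (nrow(others) == 0) next
    vote <- sum(others$spin * scaffold_phase[as.character(others$site)])
    # self-votes at scaffold sites other than v ARE counted; only v excluded
    if (vote == 0) next
    hap <- sign(vote)
    if (sv == 1 && hap == 1) res["n_ref_a"] <- res["n_ref_a"] + 1L
    if (sv == -1 && hap == 1) res["n_alt_a"] <- res["n_alt_a"] + 1L
    if (sv == 1 && hap == -1) res["n_ref_b"] <- res["n_ref_b"] + 1L
    if (sv == -1 && hap == -1) res["n_alt_b"] <- res["n_alt_b"] + 1L
  }
  res
}

# small site table on one chromosome, evenly spaced
toy_sites <- function(n, spacing = 1000, chrom = "chr1") {
  tibble::tibble(index = seq_len(n), chrom = chrom,
                 pos = seq_len(n) * spacing,
                 ref = "A", alt = "G", arm = NA_character_,
                 excluded = FALSE)
}

# link table from a list of molecules given as site -> spin vectors
toy_links <- function(..., source = "linked_read") {
  mols <- list(...)
  out <- lapply(seq_along(mols), function(k) {
    v <- mols[[k]]
    tibble::tibble(molecule = sprintf("m%03d", k), source = source,
                   site = as.integer(names(v)), spin = as.integer(v))
  })
  dplyr::bind_rows(out)
}
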