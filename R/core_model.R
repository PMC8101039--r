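#' Spin representation of variant genotypes
#'
#' Genotypes at heterozygous variants are encoded as spins: `+1` for the
#' reference allele and `-1` for the alternate allele. A haplotype over `N`
#' sites is a vector of spins defined up to a global sign (either parental
#' chromosome may be called "plus"); `complement_spins()` returns the
#' opposite homolog.
#'
#' @param spins Integer vector with entries `+1`/`-1`.
#' @return The elementwise negation of `spins`.
#' @examples
#' complement_spins(c(1L, -1L, 1L))
#' @export
complement_spins <- function(spins) {
  check_spins(spins)
  -spins
}

check_spins <- function(spins, allow_empty = FALSE) {
  if (!allow_empty && length(spins) == 0) {
    abort("`spins` must be non-empty.")
  }
  if (anyNA(spins) || !all(spins %in% c(-1L, 1L))) {
    abort("`spins` must only contain +1 or -1.")
  }
  invisible(spins)
}

#' Phase of a site pair from its linkage counts
#'
#' The maximum-likelihood relative phase of two sites given `n_plus` links
#' supporting cis linkage (ref-ref or alt-alt co-observations) and `n_minus`
#' links supporting trans linkage (ref-alt or alt-ref) is the sign of
#' `n_plus - n_minus`: `+1` for cis, `-1` for trans, `0` when the counts tie
#' and the phase is undetermined. A tied pair contributes zero coupling
#' weight downstream; no arbitrary phase is invented.
#'
#' @param n_plus,n_minus Non-negative link counts (vectorized).
#' @return Integer vector in `{-1, 0, +1}`.
#' @examples
#' pair_phase_sign(5, 1)
#' pair_phase_sign(2, 2)
#' @export
pair_phase_sign <- function(n_plus, n_minus) {
  if (any(n_plus < 0) || any(n_minus < 0)) {
    abort("Linkage counts must be non-negative.")
  }
  as.integer(sign(n_plus - n_minus))
}

#' Validate a variant site table
#'
#' A site table has one row per candidate heterozygous site with columns
#' `index` (dense 1-based id in coordinate order), `chrom`, `pos` (1-based),
#' `ref`, `alt`, and optionally `arm` (`"p"`/`"q"`) and `excluded`.
#' Positions must be strictly increasing within a chromosome.
#'
#' @param sites A data frame of variant sites.
#' @return `sites` as a tibble, invisibly usable downstream.
#' @export
validate_sites <- function(sites) {
  sites <- as_tibble(sites)
  need <- c("index", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0) {
    abort(paste0("Site table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(sites) == 0) abort("Site table is empty.")
  if (!identical(sites$index, seq_len(nrow(sites)))) {
    abort("Site indices must be 1..n in row order.")
  }
  bad <- sites |>
    group_by(.data$chrom) |>
    summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    abort("Site positions must be strictly increasing within a chromosome.")
  }
  sites
}

#' Validate a molecular link table
#'
#' Molecular links are stored in long form: one row per (molecule, site)
#' observation with columns `molecule` (barcode, read pair, or read name),
#' `source` (`"linked_read"`, `"hic"`, or `"long_read"`), `site` (site
#' index), and `spin` (+1 ref / -1 alt). A molecule observes a site at most
#' once.
#'
#' @param links A data frame of molecular link observations.
#' @param sites Optional site table to check indices against.
#' @return `links` as a tibble sorted by (molecule, site).
#' @export
validate_links <- function(links, sites = NULL) {
  links <- as_tibble(links)
  need <- c("molecule", "source", "site", "spin")
  miss <- setdiff(need, names(links))
  if (length(miss) > 0) {
    abort(paste0("Link table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(links) > 0) {
    check_spins(links$spin)
    if (!is.null(sites) && !all(links$site %in% sites$index)) {
      abort("Link table references unknown site indices.")
    }
    # grouping only requires each molecule to be one contiguous run with
    # ascending sites; skip the (expensive) sort when that already holds
    code <- match(links$molecule, unique(links$molecule))
    run_start <- c(TRUE, code[-1] != code[-length(code)])
    ordered <- !anyDuplicated(code[run_start]) &&
      all(run_start[-1] | diff(links$site) > 0)
    if (!ordered) {
      links <- arrange(links, .data$molecule, .data$site)
      code <- match(links$molecule, unique(links$molecule))
    }
    key <- code * (max(links$site) + 1) + links$site
    if (anyDuplicated(key) > 0) {
      abort("A molecule may observe a site at most once.")
    }
  }
  links
}
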