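# Cross-population frequency comparison: per-allele ratio tables against a
# reference population, flagged when the ratio exceeds twofold or falls
# below half (strict inequalities), and population-specific allele reports.

# round half up for display; flags and comparisons always use unrounded values
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-12) / scale
}

as_freq_vector <- function(x) {
  if (inherits(x, "frequency_table")) return(x$freqs)
  stopifnot(is.numeric(x), !is.null(names(x)))
  x
}

#' Per-allele frequency ratios against a reference population
#'
#' For every allele in the union of both tables (absent alleles count as
#' frequency 0) the ratio `pop_freq / ref_freq` is computed. A ratio above 2
#' is flagged `"over"`, below 0.5 `"under"` (both strict, so exactly twofold
#' is unflagged); flags are decided on the unrounded ratio while
#' `ratio_display` is rounded half-up to `round_digits` decimals. Alleles
#' absent from the reference have no defined ratio and carry the marker
#' `"-"` instead of a number.
#'
#' @param ref reference `frequency_table` or named frequency vector.
#' @param pop comparison `frequency_table` or named frequency vector.
#' @param round_digits decimals for the display column (default 2).
#' @param reference_population,population optional labels (taken from
#'   `frequency_table` inputs automatically).
#' @return a `ratio_table` data frame (rows ordered by descending reference
#'   frequency) with columns `allele`, `ref_freq`, `pop_freq`, `ratio`
#'   (numeric, `NA` when undefined), `ratio_display` (character),
#'   `flag` (`"over"`, `"under"`, `"none"`).
#' @examples
#' de <- c("MICA*008" = 0.44, "MICA*002#" = 0.11, "MICA*004" = 0.07)
#' cl <- c("MICA*008" = 0.19, "MICA*002#" = 0.31, "MICA*004" = 0.10)
#' ratio_table(de, cl)
#' @export
ratio_table <- function(ref, pop, round_digits = 2,
                        reference_population = NULL, population = NULL) {
  if (is.null(reference_population) && inherits(ref, "frequency_table")) {
    reference_population <- ref$population
  }
  if (is.null(population) && inherits(pop, "frequency_table")) {
    population <- pop$population
  }
  rf <- as_freq_vector(ref)
  pf <- as_freq_vector(pop)
  if (length(rf) == 0L) stop("reference frequency table is empty")
  alleles <- union(names(rf), names(pf))
  ref_freq <- ifelse(alleles %in% names(rf), rf[alleles], 0)
  pop_freq <- ifelse(alleles %in% names(pf), pf[alleles], 0)
  ratio <- ifelse(ref_freq > 0, pop_freq / ref_freq, NA_real_)
  flag <- rep("none", length(alleles))
  flag[!is.na(ratio) & ratio > 2] <- "over"
  flag[!is.na(ratio) & ratio < 0.5] <- "under"
  disp <- ifelse(is.na(ratio), "-",
                 formatC(round_half_up(ratio, round_digits),
                         format = "f", digits = round_digits))
  out <- data.frame(allele = alleles, ref_freq = unname(ref_freq),
                    pop_freq = unname(pop_freq), ratio = unname(ratio),
                    ratio_display = disp, flag = flag,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ref_freq, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_population") <- reference_population
  attr(out, "population") <- population
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Report population-specific alleles
#'
#' From raw per-population allele counts, lists for every allele the set of
#' populations it was observed in, and separately the alleles seen in
#' exactly one population (with their count there). Alleles with zero count
#' everywhere are excluded entirely.
#'
#' @param counts named list: population -> named numeric vector of allele
#'   counts.
#' @return list with `presence` (named list allele -> character vector of
#'   populations) and `specific` (data frame `allele`, `population`,
#'   `count`).
#' @export
population_specific_alleles <- function(counts) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  alleles <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  presence <- lapply(alleles, function(a) {
    pops <- names(counts)[vapply(counts, function(ct) {
      !is.na(ct[a]) && ct[a] > 0
    }, logical(1))]
    pops
  })
  names(presence) <- alleles
  presence <- presence[lengths(presence) > 0L]
  single <- names(presence)[lengths(presence) == 1L]
  specific <- data.frame(
    allele = single,
    population = vapply(presence[single], `[[`, character(1), 1L),
    count = vapply(single, function(a) {
      unname(counts[[presence[[a]][[1L]]]][a])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(specific) <- NULL
  list(presence = presence, specific = specific)
}

#' Packaged multi-population MICA frequency table
#'
#' First-field MICA allele frequencies for seven donor-registry populations
#' (German reference plus Polish, British/Irish, South African White, South
#' African Black, non-indigenous Chilean and Turkish-background populations),
#' shipped as a plain-text fixture together with the per-population sample
#' sizes. The `"NEW"` row is the cumulative frequency of unnamed alleles.
#'
#' @return list with `freqs` (named list population -> named frequency
#'   vector), `novel` (named logical per allele) and `n_samples` (named
#'   integer per population).
#' @export
mica_population_frequencies <- function() {
  path <- system.file("extdata", "mica_population_frequencies.tsv",
                      package = "micapop", mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sizes <- utils::read.delim(
    system.file("extdata", "mica_population_sizes.tsv",
                package = "micapop", mustWork = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE)
  pops <- setdiff(names(tab), c("allele", "novel"))
  freqs <- lapply(pops, function(pp) stats::setNames(tab[[pp]], tab$allele))
  names(freqs) <- pops
  list(freqs = freqs,
       novel = stats::setNames(tab$novel == "Y", tab$allele),
       n_samples = stats::setNames(as.integer(sizes$n_samples),
                                   sizes$population))
}
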