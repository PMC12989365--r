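# MICA ~ HLA-B haplotype linkage by perfect co-occurrence: a MICA allele is
# called linked to an HLA-B allele when it was carried by at least
# `min_count` unambiguously typed samples and every one of them also carried
# the HLA-B allele. No phased data is used; ambiguous MICA calls are
# excluded from carrier counts.

#' Infer MICA to HLA-B linkage from co-occurrence
#'
#' @param calls genotype calls with an `hla_b` column (unordered pairs);
#'   calls without HLA-B data, and calls with ambiguous MICA candidate sets,
#'   are excluded.
#' @param min_count minimum number of carriers required for a linkage call
#'   (default 10).
#' @param alleles optional character vector restricting the MICA alleles
#'   analyzed (default: every allele observed in an unambiguous call).
#' @return data frame with one row per MICA allele and maximal partner:
#'   `mica_allele`, `partner` (HLA-B allele with the highest carrier
#'   co-occurrence), `n_carriers`, `n_co_occurring`, `fraction`, `linked`
#'   (`TRUE` only when `n_carriers >= min_count`, `fraction == 1` and the
#'   maximal partner is unique) and `tie` (`TRUE` when several partners share
#'   the maximum; all tied partners are reported, never linked).
#' @export
infer_linkage <- function(calls, min_count = 10, alleles = NULL) {
  stopifnot(is.data.frame(calls), "candidates" %in% names(calls))
  if (!"hla_b" %in% names(calls)) stop("calls carry no HLA-B data")
  has_b <- vapply(calls$hla_b, function(b) !is.null(b) && !all(is.na(b)),
                  logical(1))
  if (!any(has_b)) stop("calls carry no HLA-B data")
  unamb <- lengths(calls$candidates) == 1L & has_b
  calls <- calls[unamb, , drop = FALSE]
  mica <- lapply(calls$candidates, function(cc) unique(cc[[1L]]))
  if (is.null(alleles)) {
    alleles <- sort(unique(unlist(mica, use.names = FALSE)))
  }
  rows <- list()
  for (a in alleles) {
    carrier <- vapply(mica, function(m) a %in% m, logical(1))
    n_car <- sum(carrier)
    if (n_car == 0L) next
    btab <- table(unlist(lapply(calls$hla_b[carrier], unique),
                         use.names = FALSE))
    m <- max(btab)
    partners <- sort(names(btab)[btab == m])
    tie <- length(partners) > 1L
    linked <- !tie && n_car >= min_count && m == n_car
    for (p in partners) {
      rows[[length(rows) + 1L]] <- data.frame(
        mica_allele = a, partner = p, n_carriers = n_car,
        n_co_occurring = as.integer(m), fraction = m / n_car,
        linked = linked, tie = tie, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mica_allele = character(), partner = character(),
                      n_carriers = integer(), n_co_occurring = integer(),
                      fraction = numeric(), linked = logical(),
                      tie = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
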