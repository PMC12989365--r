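# Synthetic diploid cohort generator. Emulates the statistical structure the
# downstream analysis assumes: Hardy-Weinberg sampling of two haplotypes per
# sample, hash-group masking, phasing-ambiguity candidate sets, rare
# deletion/duplication artifacts, and deterministic MICA~HLA-B linkage.
# It never simulates reads or sequences.

#' Cohort simulation configuration
#'
#' @param populations list of populations, each a list with `label` (string),
#'   `n_samples` (count) and `freqs` (named numeric vector of allele
#'   frequencies summing to 1).
#' @param ambiguity_rate probability that a (non-duplication) sample's call is
#'   wrapped into a multi-candidate phasing-ambiguity set.
#' @param hash_groups optional ambiguity-group table
#'   ([read_ambiguity_groups()]); every reported allele is masked by its group
#'   representative.
#' @param deletion_rate probability of a hemizygous MICA deletion; the caller
#'   artifactually reports the surviving allele twice (homozygous masking).
#' @param duplication_rate probability of a MICA duplication; the call then
#'   carries three alleles. `deletion_rate + duplication_rate` must be <= 1.
#' @param linkage_map optional named character vector mapping a MICA allele to
#'   its deterministic HLA-B haplotype partner.
#' @param hla_b_background_freqs optional named numeric vector of HLA-B
#'   frequencies used for haplotypes whose MICA allele is not in
#'   `linkage_map`.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return validated `cohort_config` object.
#' @export
cohort_config <- function(populations, ambiguity_rate = 0, hash_groups = NULL,
                          deletion_rate = 0, duplication_rate = 0,
                          linkage_map = NULL, hla_b_background_freqs = NULL,
                          seed = 1L) {
  stopifnot(is.list(populations), length(populations) >= 1L)
  for (pop in populations) {
    stopifnot(is.character(pop$label), length(pop$label) == 1L,
              is.numeric(pop$n_samples), pop$n_samples >= 1,
              is.numeric(pop$freqs), !is.null(names(pop$freqs)))
    if (any(pop$freqs < 0) || any(pop$freqs > 1) ||
        abs(sum(pop$freqs) - 1) > 1e-9) {
      stop("allele frequencies of population ", sQuote(pop$label),
           " must lie in [0,1] and sum to 1")
    }
  }
  for (p in c(ambiguity_rate, deletion_rate, duplication_rate)) {
    stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  }
  if (deletion_rate + duplication_rate > 1) {
    stop("deletion_rate + duplication_rate must not exceed 1")
  }
  if (!is.null(hash_groups)) hash_groups <- validate_ambiguity_groups(hash_groups)
  if (!is.null(linkage_map)) {
    stopifnot(is.character(linkage_map), !is.null(names(linkage_map)))
  }
  if (!is.null(hla_b_background_freqs)) {
    stopifnot(is.numeric(hla_b_background_freqs),
              !is.null(names(hla_b_background_freqs)),
              abs(sum(hla_b_background_freqs) - 1) < 1e-9)
  }
  structure(list(populations = populations, ambiguity_rate = ambiguity_rate,
                 hash_groups = hash_groups, deletion_rate = deletion_rate,
                 duplication_rate = duplication_rate,
                 linkage_map = linkage_map,
                 hla_b_background_freqs = hla_b_background_freqs,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# masking lookup: member (hash-stripped) -> hash-marked representative
.mask_fun <- function(hash_groups) {
  if (is.null(hash_groups)) return(identity)
  map <- stats::setNames(hash_groups$representative, hash_groups$member)
  function(x) {
    hit <- x %in% names(map)
    x[hit] <- unname(map[x[hit]])
    x
  }
}

#' Simulate a genotyped cohort
#'
#' Per population, `n_samples` diploid samples are drawn under
#' Hardy-Weinberg equilibrium (two haplotypes i.i.d. from `freqs`). With
#' probability `duplication_rate` a third allele is added (duplication
#' carriers are never additionally ambiguity-masked); with probability
#' `deletion_rate` one haplotype is dropped and the survivor reported twice,
#' mirroring the caller's homozygous-for-hemizygous artifact. All reported
#' alleles are masked by their hash-group representative. With probability
#' `ambiguity_rate` the true (masked) pair is wrapped into a candidate set of
#' size 2 or 3 whose decoys swap one allele for another draw from `freqs`.
#' Each haplotype carries an HLA-B partner: the mapped allele when its MICA
#' allele is in `linkage_map`, otherwise a draw from
#' `hla_b_background_freqs`.
#'
#' @param cfg a [cohort_config()].
#' @return data frame of genotype calls with columns `sample_id`,
#'   `population`, `candidates` (list of candidate allele multisets; length-1
#'   means unambiguous), `hla_b` (list column, unordered pair or `NULL`) and
#'   a `truth` list column holding the realized pre-masking haplotypes
#'   (provenance for [true_frequencies()]; dropped by [write_cohort_tsv()]).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  mask <- .mask_fun(cfg$hash_groups)
  out <- vector("list", length(cfg$populations))
  for (pi in seq_along(cfg$populations)) {
    pop <- cfg$populations[[pi]]
    n <- as.integer(pop$n_samples)
    alleles <- names(pop$freqs)
    p <- as.numeric(pop$freqs)
    hap1 <- sample(alleles, n, replace = TRUE, prob = p)
    hap2 <- sample(alleles, n, replace = TRUE, prob = p)

    hla <- NULL
    if (!is.null(cfg$linkage_map) || !is.null(cfg$hla_b_background_freqs)) {
      hla <- cbind(.hla_partner(hap1, cfg), .hla_partner(hap2, cfg))
    }

    u <- stats::runif(n)
    dup <- u < cfg$duplication_rate
    del <- !dup & u < cfg$duplication_rate + cfg$deletion_rate
    third <- sample(alleles, n, replace = TRUE, prob = p)
    drop_first <- sample(c(TRUE, FALSE), n, replace = TRUE)

    amb <- stats::runif(n) < cfg$ambiguity_rate & !dup

    candidates <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      if (dup[[i]]) {
        truth[[i]] <- c(hap1[[i]], hap2[[i]], third[[i]])
        reported <- sort(mask(truth[[i]]))
        candidates[[i]] <- list(reported)
        next
      }
      if (del[[i]]) {
        survivor <- if (drop_first[[i]]) hap2[[i]] else hap1[[i]]
        truth[[i]] <- survivor
        reported <- rep(mask(survivor), 2L)
      } else {
        truth[[i]] <- c(hap1[[i]], hap2[[i]])
        reported <- sort(mask(truth[[i]]))
      }
      if (amb[[i]]) {
        candidates[[i]] <- .decoy_candidates(reported, alleles, p, mask)
      } else {
        candidates[[i]] <- list(reported)
      }
    }

    calls <- data.frame(
      sample_id = sprintf("%s_%06d", gsub("[^A-Za-z0-9_]", "", pop$label),
                          seq_len(n)),
      population = pop$label,
      stringsAsFactors = FALSE
    )
    calls$candidates <- candidates
    calls$hla_b <- if (is.null(hla)) rep(list(NULL), n) else
      lapply(seq_len(n), function(i) sort(hla[i, ]))
    calls$truth <- truth
    out[[pi]] <- calls
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.hla_partner <- function(hap, cfg) {
  partner <- rep(NA_character_, length(hap))
  if (!is.null(cfg$linkage_map)) {
    hit <- hap %in% names(cfg$linkage_map)
    partner[hit] <- unname(cfg$linkage_map[hap[hit]])
  }
  miss <- is.na(partner)
  if (any(miss)) {
    if (is.null(cfg$hla_b_background_freqs)) {
      stop("linkage_map does not cover allele(s) ",
           paste(sQuote(unique(hap[miss])), collapse = ", "),
           " and no hla_b_background_freqs are configured")
    }
    partner[miss] <- sample(names(cfg$hla_b_background_freqs), sum(miss),
                            replace = TRUE,
                            prob = cfg$hla_b_background_freqs)
  }
  partner
}

# Decoy rule: k uniform in {2,3} candidate multisets; each decoy swaps one
# position of the true (masked) pair for an allele drawn UNIFORMLY from the
# allele universe (masked), discarding decoys equal to the true pair or to
# each other. Uniform replacement keeps candidate-set membership
# (approximately) uninformative about which member is true, which is the
# assumption under which Hardy-Weinberg re-weighting of candidate sets is
# the correct posterior; frequency-weighted replacement would cancel the
# weight ratio and bias the estimator (see the methods vignette). If the
# masked universe cannot supply a distinct decoy the call stays unambiguous.
.decoy_candidates <- function(true_pair, alleles, p, mask) {
  k <- sample(2:3, 1L)
  cands <- list(true_pair)
  tries <- 0L
  while (length(cands) < k && tries < 50L) {
    tries <- tries + 1L
    pos <- sample(1:2, 1L)
    decoy <- true_pair
    decoy[[pos]] <- mask(sample(alleles, 1L))
    decoy <- sort(decoy)
    if (!any(vapply(cands, identical, logical(1), y = decoy))) {
      cands <- c(cands, list(decoy))
    }
  }
  cands
}

#' Realized (pre-masking) haplotype frequencies
#'
#' Ground-truth bookkeeping for parameter-recovery tests: frequencies of the
#' haplotypes actually sampled, before hash-group masking, deletion
#' duplication or ambiguity wrapping. Deletion carriers contribute their one
#' surviving haplotype; duplication carriers contribute all three.
#'
#' @param cfg the [cohort_config()] that produced `realized`.
#' @param realized calls from [simulate_cohort()] with the `truth` column
#'   still attached.
#' @return named list: per population a named frequency vector summing to 1.
#' @export
true_frequencies <- function(cfg, realized) {
  if (is.null(realized$truth)) {
    stop("haplotype provenance absent: 'truth' column missing ",
         "(was the cohort round-tripped through TSV?)")
  }
  pops <- unique(realized$population)
  out <- lapply(pops, function(pp) {
    hap <- unlist(realized$truth[realized$population == pp], use.names = FALSE)
    tab <- table(hap)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  stats::setNames(out, pops)
}
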