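# Allele nomenclature: LOCUS*F1[:F2[:F3[:F4]]][SUFFIX][#]
# The "#" marks a representative of a genotyping ambiguity group; it is
# metadata, never part of identity between an allele and its hash-stripped
# form. "NEW" is a reserved label for sequences matching no named allele.

.allele_regex <- "^([A-Za-z][A-Za-z0-9-]*)\\*([0-9]+(:[0-9]+){0,3})([A-Z])?(#)?$"

#' Parse allele names
#'
#' Parses IPD-IMGT/HLA style allele names such as `"MICA*008:28"`,
#' `"MICA*107N"` (expression suffix), `"MICA*002#"` (hash-marked ambiguity
#' group representative) or `"HLA-B*14:02:01G"` (G-group label). The reserved
#' label `"NEW"` denotes a sequence matching no named allele and parses to a
#' locus-less record.
#'
#' @param x character vector of allele names.
#' @return An `allele_tbl` data frame with one row per name and columns
#'   `locus`, `fields` (list column of field strings, leading zeros
#'   preserved), `suffix` (single uppercase letter or `NA`), `hash`
#'   (logical). `render_allele()` inverts the parse exactly.
#' @examples
#' a <- parse_allele(c("MICA*008:28", "MICA*107N", "MICA*002#"))
#' render_allele(a)
#' render_allele(first_field(a))
#' @export
parse_allele <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  locus <- character(length(x))
  fields <- vector("list", length(x))
  suffix <- rep(NA_character_, length(x))
  hash <- logical(length(x))
  m <- regexec(.allele_regex, x)
  mm <- regmatches(x, m)
  for (i in seq_along(x)) {
    if (identical(x[[i]], "NEW")) {
      locus[[i]] <- NA_character_
      fields[[i]] <- "NEW"
      next
    }
    g <- mm[[i]]
    if (length(g) == 0L) {
      stop("malformed allele name: ", sQuote(x[[i]]),
           " (expected LOCUS*F1[:F2[:F3[:F4]]][SUFFIX][#])", call. = FALSE)
    }
    locus[[i]] <- g[[2L]]
    fields[[i]] <- strsplit(g[[3L]], ":", fixed = TRUE)[[1L]]
    if (nzchar(g[[5L]])) suffix[[i]] <- g[[5L]]
    hash[[i]] <- nzchar(g[[6L]])
  }
  new_allele_tbl(locus, fields, suffix, hash)
}

new_allele_tbl <- function(locus, fields, suffix, hash) {
  out <- data.frame(locus = locus, suffix = suffix, hash = hash,
                    stringsAsFactors = FALSE)
  out$fields <- fields
  out <- out[, c("locus", "fields", "suffix", "hash")]
  class(out) <- c("allele_tbl", "data.frame")
  out
}

#' Render allele names
#'
#' @param a an `allele_tbl` from [parse_allele()].
#' @return character vector; `render_allele(parse_allele(x))` equals `x`.
#' @export
render_allele <- function(a) {
  stopifnot(inherits(a, "allele_tbl"))
  vapply(seq_len(nrow(a)), function(i) {
    if (is.na(a$locus[[i]])) return(a$fields[[i]][[1L]])
    paste0(a$locus[[i]], "*", paste(a$fields[[i]], collapse = ":"),
           if (!is.na(a$suffix[[i]])) a$suffix[[i]] else "",
           if (a$hash[[i]]) "#" else "")
  }, character(1))
}

#' @export
format.allele_tbl <- function(x, ...) render_allele(x)

#' @export
print.allele_tbl <- function(x, ...) {
  cat("<allele_tbl>", paste(render_allele(x), collapse = ", "), "\n")
  invisible(x)
}

#' Reduce allele names to first-field (protein) resolution
#'
#' Keeps only the first name field; the expression suffix and the hash flag
#' are preserved, so `"MICA*107N"` stays `"MICA*107N"` and `"MICA*009#"`
#' stays `"MICA*009#"`. The reserved `"NEW"` label passes through.
#'
#' @param a an `allele_tbl` or a character vector of allele names.
#' @return same type as the input.
#' @export
first_field <- function(a) {
  chr <- is.character(a)
  if (chr) a <- parse_allele(a)
  stopifnot(inherits(a, "allele_tbl"))
  a$fields <- lapply(a$fields, `[`, 1L)
  if (chr) render_allele(a) else a
}

# ---- ambiguity groups -------------------------------------------------------

#' Read ambiguity group definitions
#'
#' Groups of alleles that the genotyping workflow cannot distinguish; each
#' group is reported by a representative allele marked with `"#"`. Accepts a
#' two-column TSV (`representative`, `members` comma-separated) or a JSON
#' array of `{representative, members}` objects.
#'
#' @param path file path (`.json` or tab-separated text).
#' @return data frame with columns `representative` (hash-marked name) and
#'   `member` (one row per member allele).
#' @seealso [mica_ambiguity_groups()] for the packaged MICA groups.
#' @export
read_ambiguity_groups <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    reps <- vapply(raw, function(g) g$representative, character(1))
    members <- lapply(raw, function(g) unlist(g$members, use.names = FALSE))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("representative", "members") %in% names(tab))) {
      stop("ambiguity group table needs columns 'representative' and 'members'")
    }
    reps <- tab$representative
    members <- strsplit(tab$members, ",[[:space:]]*")
  }
  groups <- data.frame(
    representative = rep(reps, lengths(members)),
    member = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  validate_ambiguity_groups(groups)
}

validate_ambiguity_groups <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("representative", "member") %in% names(groups)))
  for (rep_name in unique(groups$representative)) {
    pa <- parse_allele(rep_name)
    if (!pa$hash[[1L]]) {
      stop("group representative ", sQuote(rep_name), " is not hash-marked")
    }
    members <- groups$member[groups$representative == rep_name]
    if (anyDuplicated(members)) {
      stop("duplicate members in group ", sQuote(rep_name))
    }
    stripped <- sub("#$", "", rep_name)
    if (!stripped %in% members) {
      stop("representative ", sQuote(rep_name), " is not one of its members")
    }
    loci <- parse_allele(members)$locus
    if (length(unique(loci)) != 1L) {
      stop("members of group ", sQuote(rep_name), " span multiple loci")
    }
  }
  if (anyDuplicated(groups$member)) {
    dup <- unique(groups$member[duplicated(groups$member)])
    stop("allele(s) assigned to two ambiguity groups: ",
         paste(sQuote(dup), collapse = ", "))
  }
  groups
}

#' Packaged MICA ambiguity groups
#'
#' The five MICA ambiguity groups of the high-throughput genotyping workflow
#' (e.g. `MICA*009#` covering `MICA*009` and `MICA*049`), shipped as a
#' plain-text fixture.
#'
#' @return data frame as from [read_ambiguity_groups()].
#' @export
mica_ambiguity_groups <- function() {
  read_ambiguity_groups(system.file("extdata", "mica_ambiguity_groups.tsv",
                                    package = "micapop", mustWork = TRUE))
}

#' Resolve alleles to their ambiguity group representative
#'
#' If an allele (after stripping any hash mark) is a member of a group, the
#' group's hash-marked representative is returned; otherwise the allele is
#' returned unchanged. Resolution is idempotent: representatives resolve to
#' themselves.
#'
#' @param a an `allele_tbl` or character vector of allele names.
#' @param groups group table from [read_ambiguity_groups()]; a membership in
#'   two groups is a configuration error (caught on validation).
#' @return same type as the input.
#' @export
resolve_group <- function(a, groups) {
  groups <- validate_ambiguity_groups(groups)
  chr <- is.character(a)
  nm <- if (chr) a else render_allele(a)
  stripped <- sub("#$", "", nm)
  map <- stats::setNames(groups$representative, groups$member)
  hit <- stripped %in% names(map)
  nm[hit] <- unname(map[stripped[hit]])
  if (chr) nm else parse_allele(nm)
}

# ---- submission ledger ------------------------------------------------------

.ledger_categories <- c("novel_proteins", "synonymous_exon",
                        "intron_variations", "confirmations_extensions")

#' Read a sequence-submission ledger
#'
#' CSV with columns `batch_id`, `novel_proteins`, `synonymous_exon`,
#' `intron_variations`, `confirmations_extensions` (non-negative counts of
#' database submissions per characterization batch).
#'
#' @param path CSV file path.
#' @return validated ledger data frame.
#' @export
read_submission_ledger <- function(path) {
  ledger <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("batch_id", .ledger_categories), names(ledger))
  if (length(missing_cols)) {
    stop("ledger is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(as.matrix(ledger[.ledger_categories]) < 0)) {
    stop("ledger counts must be non-negative")
  }
  ledger
}

#' Submission ledger totals
#'
#' Per-batch totals plus the grand total over all categories and the novel
#' total (everything except confirmations/sequence extensions, i.e. novel
#' proteins + synonymous exon + intron variations).
#'
#' @param ledger data frame as from [read_submission_ledger()].
#' @return list with `per_batch` (data frame `batch_id`, `total`),
#'   `grand_total` and `novel_total` (integers).
#' @export
ledger_totals <- function(ledger) {
  stopifnot(all(c("batch_id", .ledger_categories) %in% names(ledger)))
  cat_mat <- as.matrix(ledger[.ledger_categories])
  storage.mode(cat_mat) <- "integer"
  if (any(cat_mat < 0L)) stop("ledger counts must be non-negative")
  per_batch <- data.frame(batch_id = ledger$batch_id,
                          total = as.integer(rowSums(cat_mat)))
  grand <- sum(cat_mat)
  novel <- grand - sum(cat_mat[, "confirmations_extensions"])
  list(per_batch = per_batch,
       grand_total = as.integer(grand),
       novel_total = as.integer(novel))
}

#' Packaged MICA submission ledger
#'
#' Category counts of the two MICA characterization batches submitted to the
#' reference database, shipped as a CSV fixture.
#'
#' @return ledger data frame.
#' @export
mica_submission_ledger <- function() {
  read_submission_ledger(system.file("extdata", "mica_submission_ledger.csv",
                                     package = "micapop", mustWork = TRUE))
}
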