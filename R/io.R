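# Readers/writers for the cohort TSV dialect and FASTA, plus run reports.
# Conventions: internal coordinates are 0-based half-open, user-facing
# positions 1-based (mature-protein numbering); tabular output uses "."
# decimals, UTF-8 and Unix newlines.

#' Write genotype calls as TSV
#'
#' Dialect: columns `sample_id`, `population`, `candidates` (candidate
#' multisets separated by `";"`, alleles joined by `"+"`, e.g.
#' `"MICA*008+MICA*002;MICA*008+MICA*004"`) and `hla_b` (pair joined by
#' `"+"`, empty when absent). The simulation provenance (`truth` column) is
#' deliberately not serialized.
#'
#' @param calls genotype call data frame.
#' @param path output path.
#' @export
write_cohort_tsv <- function(calls, path) {
  stopifnot(is.data.frame(calls),
            all(c("sample_id", "population", "candidates") %in% names(calls)))
  cand <- vapply(calls$candidates, function(cc) {
    paste(vapply(cc, paste, character(1), collapse = "+"), collapse = ";")
  }, character(1))
  hla <- if ("hla_b" %in% names(calls)) {
    vapply(calls$hla_b, function(b) {
      if (is.null(b) || all(is.na(b))) "" else paste(b, collapse = "+")
    }, character(1))
  } else rep("", nrow(calls))
  out <- data.frame(sample_id = calls$sample_id,
                    population = calls$population,
                    candidates = cand, hla_b = hla,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read genotype calls from TSV
#'
#' Reads the [write_cohort_tsv()] dialect back; malformed rows are reported
#' with their line numbers. A three-allele candidate is parsed as a
#' duplication carrier.
#'
#' @param path TSV path.
#' @return genotype call data frame (without simulation provenance).
#' @export
read_cohort_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("sample_id", "population", "candidates")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("cohort TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- integer(0)
  candidates <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    raw <- tab$candidates[[i]]
    if (is.na(raw) || !nzchar(raw)) { bad <- c(bad, i); next }
    sets <- lapply(strsplit(raw, ";", fixed = TRUE)[[1]],
                   function(s) strsplit(s, "+", fixed = TRUE)[[1]])
    sizes <- lengths(sets)
    if (any(sizes < 2L) || length(unique(sizes)) != 1L) {
      bad <- c(bad, i); next
    }
    candidates[[i]] <- sets
  }
  if (length(bad)) {
    stop("malformed candidate set(s) at line(s) ",
         paste(bad + 1L, collapse = ", "),  # +1 for the header line
         " of ", path)
  }
  tab$candidates <- candidates
  tab$hla_b <- if ("hla_b" %in% names(tab)) {
    lapply(tab$hla_b, function(s) {
      if (is.na(s) || !nzchar(s)) NULL else strsplit(s, "+", fixed = TRUE)[[1]]
    })
  } else rep(list(NULL), nrow(tab))
  tab[, c("sample_id", "population", "candidates", "hla_b")]
}

#' Read amino-acid FASTA with allele-name headers
#'
#' Headers must parse as allele names ([parse_allele()]); sequences are
#' uppercased. Duplicate headers and empty files are errors.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("[[:space:]].*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA headers: ",
         paste(sQuote(unique(nm[duplicated(nm)])), collapse = ", "))
  }
  parse_allele(nm)  # validates; errors name the offending header
  stats::setNames(toupper(as.character(set)), nm)
}

#' Write a machine-readable run report
#'
#' Every pipeline run can emit a JSON report of its inputs, seed, package
#' version and warnings, so results remain reproducible and auditable.
#'
#' @param path output JSON path.
#' @param subcommand name of the stage that ran.
#' @param inputs named list of input paths/parameters.
#' @param seed integer seed (or `NA`).
#' @param warnings character vector.
#' @return the report list, invisibly.
#' @export
write_run_report <- function(path, subcommand, inputs = list(), seed = NA,
                             warnings = character(0)) {
  report <- list(
    subcommand = subcommand,
    inputs = inputs,
    seed = seed,
    package = "micapop",
    version = as.character(utils::packageVersion("micapop")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = as.list(warnings)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
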