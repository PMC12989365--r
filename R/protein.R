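# Reference-anchored protein comparison. Every sequence is globally aligned
# to the reference allele (MICA*002 by default) and the pairwise alignments
# are merged on reference coordinates into a star alignment; positions are
# numbered on the mature protein, with AA1 the first residue encoded by
# exon 2. This keeps mature-position numbering exact without a full MSA,
# which is appropriate because MICA proteins are near-identical in length.

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

#' Build a reference-anchored protein alignment
#'
#' Each sequence is aligned to the reference with global pairwise alignment
#' (BLOSUM62 scoring, gap open 10 / extend 1) and the alignments are merged
#' on reference coordinates. Insertion columns (residues absent from the
#' reference) are tagged `"<pos>+<i>"`; all other columns carry the mature
#' position of the reference residue.
#'
#' @param sequences named character vector or `Biostrings::AAStringSet` of
#'   amino-acid sequences (mature protein, or full-length with
#'   `leader_length` to strip).
#' @param reference_id name of the reference sequence (default
#'   `"MICA*002"`); must be present.
#' @param leader_length number of leading residues (leader peptide) to strip
#'   from every sequence before alignment (default 0, i.e. inputs are mature
#'   sequences).
#' @return a `protein_alignment`: list with `reference`, `matrix` (character
#'   matrix, one row per allele, gap `"-"`), `ref_pos` (integer mature
#'   position per column, `NA` for insertion columns) and `labels` (column
#'   labels).
#' @export
build_alignment <- function(sequences, reference_id = "MICA*002",
                            leader_length = 0) {
  seqs <- .as_aa_character(sequences)
  if (!reference_id %in% names(seqs)) {
    stop("reference ", sQuote(reference_id), " not among the sequences")
  }
  if (leader_length > 0) {
    seqs <- vapply(seqs, substring, character(1), leader_length + 1L)
  }
  bad <- !vapply(strsplit(seqs, ""), function(ch) all(ch %in% .aa_alphabet),
                 logical(1))
  if (any(bad)) {
    stop("non-amino-acid symbols in sequence(s): ",
         paste(sQuote(names(seqs)[bad]), collapse = ", "))
  }
  ref_seq <- seqs[[reference_id]]
  others <- setdiff(names(seqs), reference_id)
  L <- nchar(ref_seq)

  # per sequence: residue aligned to each reference position ('-' if
  # deleted) and insertions keyed by the preceding reference position (0..L)
  per_seq <- lapply(others, function(nm) {
    .anchor_to_reference(seqs[[nm]], ref_seq)
  })
  names(per_seq) <- others

  ins_max <- integer(L + 1L)   # index p+1 = insertions after ref position p
  for (ps in per_seq) {
    for (key in names(ps$insertions)) {
      p <- as.integer(key)
      ins_max[p + 1L] <- max(ins_max[p + 1L], nchar(ps$insertions[[key]]))
    }
  }

  n_cols <- L + sum(ins_max)
  ref_pos <- integer(0)
  labels <- character(0)
  col_kind <- character(0)   # "ref" or "ins"
  for (p in 0:L) {
    if (ins_max[p + 1L] > 0) {
      k <- ins_max[p + 1L]
      ref_pos <- c(ref_pos, rep(NA_integer_, k))
      labels <- c(labels, paste0(p, "+", seq_len(k)))
      col_kind <- c(col_kind, rep("ins", k))
    }
    if (p < L) {
      ref_pos <- c(ref_pos, p + 1L)
      labels <- c(labels, as.character(p + 1L))
      col_kind <- c(col_kind, "ref")
    }
  }
  stopifnot(length(ref_pos) == n_cols)

  mat <- matrix("-", nrow = length(seqs), ncol = n_cols,
                dimnames = list(c(reference_id, others), labels))
  ref_chars <- strsplit(ref_seq, "")[[1]]
  mat[reference_id, col_kind == "ref"] <- ref_chars
  for (nm in others) {
    ps <- per_seq[[nm]]
    mat[nm, col_kind == "ref"] <- ps$at_ref
    for (key in names(ps$insertions)) {
      p <- as.integer(key)
      ins <- strsplit(ps$insertions[[key]], "")[[1]]
      cols <- which(is.na(ref_pos) & labels %in% paste0(p, "+", seq_along(ins)))
      mat[nm, cols] <- ins
    }
  }
  structure(list(reference = reference_id, matrix = mat,
                 ref_pos = ref_pos, labels = labels),
            class = "protein_alignment")
}

# global pairwise alignment of one sequence against the reference, reduced
# to reference coordinates
.anchor_to_reference <- function(seq, ref_seq) {
  if (identical(seq, ref_seq)) {
    return(list(at_ref = strsplit(seq, "")[[1]],
                insertions = list()))
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(seq),
    subject = Biostrings::AAString(ref_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  L <- nchar(ref_seq)
  at_ref <- rep("-", L)
  insertions <- list()
  refpos <- 0L
  for (k in seq_along(s)) {
    if (s[[k]] == "-") {
      key <- as.character(refpos)
      cur <- if (is.null(insertions[[key]])) "" else insertions[[key]]
      insertions[[key]] <- paste0(cur, p[[k]])
    } else {
      refpos <- refpos + 1L
      at_ref[[refpos]] <- p[[k]]
    }
  }
  list(at_ref = at_ref, insertions = insertions)
}

.as_aa_character <- function(sequences) {
  if (inherits(sequences, "AAStringSet") || inherits(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (anyDuplicated(names(sequences))) stop("duplicate sequence names")
  toupper(sequences)
}

#' Per-allele differences from the reference
#'
#' Lists, for every allele, all alignment columns whose symbol differs from
#' the reference symbol; gaps count as differences and are reported with the
#' gap symbol `"-"`. `X` is an unknown residue, not a wildcard: it matches
#' only itself.
#'
#' @param aln a `protein_alignment`.
#' @return a `variant_matrix`: list with `variants` (data frame `allele`,
#'   `position` (column label), `ref_symbol`, `alt_symbol`) and `n_variants`
#'   (named integer per allele; 0 for the reference by construction).
#' @export
variant_matrix <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  ref_row <- aln$matrix[aln$reference, ]
  rows <- lapply(rownames(aln$matrix), function(nm) {
    diff <- which(aln$matrix[nm, ] != ref_row)
    if (!length(diff)) return(NULL)
    data.frame(allele = nm, position = aln$labels[diff],
               ref_symbol = unname(ref_row[diff]),
               alt_symbol = unname(aln$matrix[nm, diff]),
               stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, rows)
  if (is.null(variants)) {
    variants <- data.frame(allele = character(), position = character(),
                           ref_symbol = character(), alt_symbol = character(),
                           stringsAsFactors = FALSE)
  }
  rownames(variants) <- NULL
  n_var <- vapply(rownames(aln$matrix), function(nm) {
    sum(variants$allele == nm)
  }, integer(1))
  structure(list(variants = variants, n_variants = n_var,
                 reference = aln$reference),
            class = "variant_matrix")
}

#' Classify the MICA-129 Met/Val dimorphism
#'
#' Reads the symbol at mature position 129 for every allele: methionine
#' (high-affinity NKG2D binding) maps to `"Met"`, valine (low-affinity) to
#' `"Val"`, anything else -- including a gap, which triggers a warning -- to
#' `"other"`.
#'
#' @param aln a `protein_alignment` whose reference covers position 129.
#' @return named character vector (`"Met"`, `"Val"` or `"other"`).
#' @export
classify_aa129 <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  col <- which(!is.na(aln$ref_pos) & aln$ref_pos == 129L)
  if (length(col) != 1L) stop("alignment has no column at mature position 129")
  sym <- aln$matrix[, col]
  if (any(sym == "-")) {
    warning("allele(s) with a gap at position 129 classified as 'other': ",
            paste(sQuote(names(sym)[sym == "-"]), collapse = ", "))
  }
  out <- ifelse(sym == "M", "Met", ifelse(sym == "V", "Val", "other"))
  stats::setNames(out, rownames(aln$matrix))
}

#' Detect null alleles from a coding sequence
#'
#' Aligns a CDS to the reference CDS and inspects it for loss-of-function
#' mechanisms: an indel whose length is not a multiple of 3 is a frameshift
#' (the exon harboring it is reported); otherwise, an in-frame stop codon
#' upstream of the reference stop is a premature stop. Translation uses the
#' standard nuclear genetic code.
#'
#' @param cds query coding sequence (character, A/C/G/T).
#' @param ref_cds reference coding sequence; its length must be a multiple
#'   of 3 and it should end in a stop codon.
#' @param exon_boundaries data frame with columns `exon`, `start`, `end`
#'   (1-based inclusive positions on the reference CDS).
#' @return list with `is_null` (logical), `mechanism` (`"frameshift"`,
#'   `"premature_stop"` or `"none"`) and `exon` (integer or `NA`).
#' @export
detect_null <- function(cds, ref_cds, exon_boundaries) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds); ref_cds <- toupper(ref_cds)
  if (nchar(cds) == 0L) stop("empty coding sequence")
  stopifnot(nchar(ref_cds) %% 3 == 0,
            all(c("exon", "start", "end") %in% names(exon_boundaries)))

  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(cds),
    subject = Biostrings::DNAString(ref_cds),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = TRUE),
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]

  # walk alignment columns: collect indel runs and a query->reference map
  refpos <- 0L; qpos <- 0L
  q2r <- integer(nchar(cds))
  indels <- list()
  run_type <- ""; run_len <- 0L; run_ref <- NA_integer_
  flush_run <- function() {
    if (run_len > 0L) {
      indels[[length(indels) + 1L]] <<- list(type = run_type, len = run_len,
                                             ref_pos = run_ref)
    }
    run_type <<- ""; run_len <<- 0L; run_ref <<- NA_integer_
  }
  for (k in seq_along(s)) {
    if (s[[k]] != "-" && p[[k]] != "-") {
      flush_run()
      refpos <- refpos + 1L; qpos <- qpos + 1L
      q2r[[qpos]] <- refpos
    } else if (s[[k]] == "-") {          # insertion relative to reference
      if (run_type != "ins") { flush_run(); run_type <- "ins"
        run_ref <- min(refpos + 1L, nchar(ref_cds)) }
      run_len <- run_len + 1L
      qpos <- qpos + 1L
      q2r[[qpos]] <- refpos              # maps to preceding ref base
    } else {                             # deletion relative to reference
      if (run_type != "del") { flush_run(); run_type <- "del"
        run_ref <- refpos + 1L }
      run_len <- run_len + 1L
      refpos <- refpos + 1L
    }
  }
  flush_run()

  for (ind in indels) {
    if (ind$len %% 3L != 0L) {
      return(list(is_null = TRUE, mechanism = "frameshift",
                  exon = .exon_of(ind$ref_pos, exon_boundaries)))
    }
  }

  # no frameshift: reading frame preserved, translate the query directly
  n_codons <- nchar(cds) %/% 3L
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n_codons * 3L)),
    if.fuzzy.codon = "solve"))
  ref_prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(ref_cds), if.fuzzy.codon = "solve"))
  ref_stop_nt <- (regexpr("*", ref_prot, fixed = TRUE)[[1]] - 1L) * 3L + 1L
  if (ref_stop_nt < 1L) ref_stop_nt <- nchar(ref_cds) + 1L
  stop_aa <- regexpr("*", prot, fixed = TRUE)[[1]]
  if (stop_aa > 0L) {
    stop_nt_query <- (stop_aa - 1L) * 3L + 1L
    stop_nt_ref <- q2r[[min(stop_nt_query, length(q2r))]]
    if (stop_nt_ref < ref_stop_nt) {
      return(list(is_null = TRUE, mechanism = "premature_stop",
                  exon = .exon_of(stop_nt_ref, exon_boundaries)))
    }
  }
  list(is_null = FALSE, mechanism = "none", exon = NA_integer_)
}

.exon_of <- function(ref_pos, exon_boundaries) {
  hit <- exon_boundaries$start <= ref_pos & exon_boundaries$end >= ref_pos
  if (!any(hit)) return(NA_integer_)
  as.integer(exon_boundaries$exon[which(hit)[1L]])
}

#' Group alleles by their nearest frequent allele
#'
#' Automated stand-in for manual similarity sorting: every allele is assigned
#' to the frequent allele with the smallest hamming distance between their
#' alignment rows (gap-vs-gap columns match). Ties go to the
#' lexicographically smallest frequent allele and are flagged.
#'
#' @param aln a `protein_alignment`.
#' @param frequent character vector of frequent allele names present in the
#'   alignment.
#' @return data frame with columns `allele`, `group`, `distance`, `tie`.
#' @export
group_by_nearest_frequent <- function(aln, frequent) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (!length(frequent)) stop("empty list of frequent alleles")
  missing_f <- setdiff(frequent, rownames(aln$matrix))
  if (length(missing_f)) {
    stop("frequent allele(s) not in alignment: ",
         paste(sQuote(missing_f), collapse = ", "))
  }
  frequent <- sort(frequent)
  rows <- rownames(aln$matrix)
  out <- lapply(rows, function(nm) {
    d <- vapply(frequent, function(f) {
      sum(aln$matrix[nm, ] != aln$matrix[f, ])
    }, numeric(1))
    dmin <- min(d)
    hits <- frequent[d == dmin]
    data.frame(allele = nm, group = hits[[1L]], distance = dmin,
               tie = length(hits) > 1L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
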