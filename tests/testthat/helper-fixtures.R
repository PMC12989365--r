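# Shared fixtures, built in code at test time.

# genotype-call data frame from a list of candidate-set lists
make_calls <- function(cand_list, population = "P", hla_b = NULL) {
  n <- length(cand_list)
  calls <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                      population = population, stringsAsFactors = FALSE)
  calls$candidates <- cand_list
  calls$hla_b <- if (is.null(hla_b)) rep(list(NULL), n) else hla_b
  calls
}

# random amino-acid sequence
random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")
}

substitute_at <- function(seq, pos, ch) {
  substr(seq, pos, pos) <- ch
  seq
}

delete_at <- function(seq, pos, len) {
  paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + len, nchar(seq)))
}

insert_at <- function(seq, pos, ins) {
  # insert after position pos
  paste0(substr(seq, 1L, pos), ins, substr(seq, pos + 1L, nchar(seq)))
}

# random binary tree with integer branch lengths; returns its exact
# path-distance matrix (additive by construction) for NJ exactness checks
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  labels <- paste0("t", seq_len(n_taxa))
  tree <- ape::rtree(n_taxa, tip.label = labels, rooted = FALSE,
                     br = function(k) sample(1:5, k, replace = TRUE))
  d <- ape::cophenetic.phylo(tree)
  d[labels, labels]
}

# toy CDS: codons without internal stops, ends with TAA; exon table splits
# it into exon 2 (codons 1..10) and exon 3 (codons 11..20)
toy_cds <- function() {
  codons <- c("ATG", rep(c("GCT", "GAA", "TGC", "CTG", "AAA"), 4)[1:18], "TAA")
  list(cds = paste(codons, collapse = ""),
       exons = data.frame(exon = c(2L, 3L), start = c(1L, 31L),
                          end = c(30L, 60L)))
}
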