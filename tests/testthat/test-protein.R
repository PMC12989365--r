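# Toy MICA-like sequences built in code; position 129 carries the Met/Val
# dimorphism of interest.
make_toy_proteins <- function() {
  ref <- random_protein(200, seed = 101)
  ref <- substitute_at(ref, 129, "M")
  list(
    ref = ref,
    sub1 = substitute_at(ref, 10, "A"),                       # 1 substitution
    val129 = substitute_at(substitute_at(ref, 129, "V"), 40, "H"),
    del3 = delete_at(ref, 50, 3),                             # 3-res deletion
    ins2 = insert_at(ref, 70, "QQ")                           # 2-res insertion
  )
}

test_that("identical sequences align without gaps or differences", {
  p <- make_toy_proteins()
  aln <- build_alignment(c("MICA*002" = p$ref, "MICA*900" = p$ref))
  expect_identical(ncol(aln$matrix), 200L)
  expect_identical(unname(aln$matrix["MICA*900", ]),
                   unname(aln$matrix["MICA*002", ]))
  vm <- variant_matrix(aln)
  expect_identical(nrow(vm$variants), 0L)
  # idempotence: re-aligning the already consistent rows changes nothing
  aln2 <- build_alignment(c("MICA*002" = p$ref, "MICA*900" = p$ref))
  expect_identical(aln2$matrix, aln$matrix)
})

test_that("substitutions and deletions produce the expected variant calls", {
  p <- make_toy_proteins()
  aln <- build_alignment(c("MICA*002" = p$ref, "MICA*901" = p$sub1,
                           "MICA*902" = p$del3))
  vm <- variant_matrix(aln)
  v901 <- vm$variants[vm$variants$allele == "MICA*901", ]
  expect_identical(nrow(v901), 1L)
  expect_identical(v901$position, "10")
  expect_identical(v901$alt_symbol, "A")
  v902 <- vm$variants[vm$variants$allele == "MICA*902", ]
  expect_identical(nrow(v902), 3L)
  expect_identical(v902$position, c("50", "51", "52"))
  expect_true(all(v902$alt_symbol == "-"))
  # reference row has an empty variant list by construction
  expect_identical(unname(vm$n_variants["MICA*002"]), 0L)
})

test_that("insertions get tagged columns and leave numbering anchored", {
  p <- make_toy_proteins()
  aln <- build_alignment(c("MICA*002" = p$ref, "MICA*903" = p$ins2))
  expect_identical(ncol(aln$matrix), 202L)
  ins_cols <- which(is.na(aln$ref_pos))
  expect_identical(aln$labels[ins_cols], c("70+1", "70+2"))
  expect_true(all(aln$matrix["MICA*002", ins_cols] == "-"))
  expect_identical(paste(aln$matrix["MICA*903", ins_cols], collapse = ""),
                   "QQ")
  # mature numbering of downstream columns is unchanged
  expect_identical(aln$matrix["MICA*903", which(aln$ref_pos == 129L)],
                   aln$matrix["MICA*002", which(aln$ref_pos == 129L)])
})

test_that("number of variants equals hamming distance to the reference", {
  p <- make_toy_proteins()
  seqs <- c("MICA*002" = p$ref, "MICA*901" = p$sub1, "MICA*904" = p$val129,
            "MICA*902" = p$del3)
  aln <- build_alignment(seqs)
  vm <- variant_matrix(aln)
  d <- hamming_matrix(aln)
  for (nm in names(seqs)) {
    expect_identical(unname(vm$n_variants[nm]),
                     as.integer(d["MICA*002", nm]))
  }
})

test_that("AA129 classification distinguishes Met, Val and gaps", {
  p <- make_toy_proteins()
  gap129 <- delete_at(p$ref, 128, 3)
  aln <- build_alignment(c("MICA*002" = p$ref, "MICA*904" = p$val129,
                           "MICA*905" = gap129))
  expect_warning(cls <- classify_aa129(aln), "gap")
  expect_identical(unname(cls["MICA*002"]), "Met")
  expect_identical(unname(cls["MICA*904"]), "Val")
  expect_identical(unname(cls["MICA*905"]), "other")
})

test_that("input validation catches bad sequences and missing reference", {
  expect_error(build_alignment(c("MICA*002" = "MKV1X")), "non-amino-acid")
  expect_error(build_alignment(c("MICA*004" = "MKV"), "MICA*002"),
               "reference")
})

test_that("frameshift indels are flagged with the harboring exon", {
  toy <- toy_cds()
  # single-base deletion in exon 2
  res <- detect_null(delete_at(toy$cds, 10, 1), toy$cds, toy$exons)
  expect_true(res$is_null)
  expect_identical(res$mechanism, "frameshift")
  expect_identical(res$exon, 2L)
  # two-base deletion in exon 3
  res <- detect_null(delete_at(toy$cds, 40, 2), toy$cds, toy$exons)
  expect_identical(res$mechanism, "frameshift")
  expect_identical(res$exon, 3L)
  # single-base insertion in exon 3
  res <- detect_null(insert_at(toy$cds, 35, "A"), toy$cds, toy$exons)
  expect_identical(res$mechanism, "frameshift")
  expect_identical(res$exon, 3L)
})

test_that("in-frame changes are not null; premature stops are detected", {
  toy <- toy_cds()
  expect_identical(detect_null(delete_at(toy$cds, 10, 3), toy$cds,
                               toy$exons)$mechanism, "none")
  expect_identical(detect_null(insert_at(toy$cds, 33, "GCTGCA"), toy$cds,
                               toy$exons)$mechanism, "none")
  # substitution creating TAA at codon 12 (exon 3)
  mutated <- toy$cds
  substr(mutated, 34, 36) <- "TAA"
  res <- detect_null(mutated, toy$cds, toy$exons)
  expect_true(res$is_null)
  expect_identical(res$mechanism, "premature_stop")
  expect_identical(res$exon, 3L)
  # untouched CDS is clean
  expect_identical(detect_null(toy$cds, toy$cds, toy$exons)$mechanism,
                   "none")
  expect_error(detect_null("", toy$cds, toy$exons), "empty")
})

test_that("random small indels behave per the frameshift rule", {
  toy <- toy_cds()
  set.seed(77)
  for (i in 1:25) {
    pos <- sample(5:50, 1)
    len <- sample(1:2, 1)
    res <- detect_null(delete_at(toy$cds, pos, len), toy$cds, toy$exons)
    expect_identical(res$mechanism, "frameshift")
    # in-frame stop-free insertion of length 3k never flags null
    res3 <- detect_null(insert_at(toy$cds, pos, strrep("GCA", sample(1:3, 1))),
                        toy$cds, toy$exons)
    expect_identical(res3$mechanism, "none")
  }
})

test_that("nearest-frequent grouping assigns by hamming with tie flags", {
  p <- make_toy_proteins()
  # equidistant fixture: one substitution away from each of two frequent
  # alleles that differ from each other at two positions
  f1 <- p$ref
  f2 <- substitute_at(substitute_at(p$ref, 5, "W"), 6, "W")
  eq <- substitute_at(p$ref, 5, "W")  # distance 1 from both
  aln <- build_alignment(c("MICA*002" = f1, "MICA*008" = f2,
                           "MICA*950" = eq, "MICA*951" = p$sub1))
  grp <- group_by_nearest_frequent(aln, c("MICA*002", "MICA*008"))
  g <- function(a) grp[grp$allele == a, ]
  expect_identical(g("MICA*002")$group, "MICA*002")
  expect_equal(g("MICA*002")$distance, 0)
  expect_identical(g("MICA*951")$group, "MICA*002")
  expect_true(g("MICA*950")$tie)
  expect_identical(g("MICA*950")$group, "MICA*002")  # lexicographic winner
  expect_error(group_by_nearest_frequent(aln, character(0)), "empty")
  # invariance under row order
  aln2 <- build_alignment(c("MICA*002" = f1, "MICA*951" = p$sub1,
                            "MICA*008" = f2, "MICA*950" = eq))
  grp2 <- group_by_nearest_frequent(aln2, c("MICA*002", "MICA*008"))
  grp2 <- grp2[match(grp$allele, grp2$allele), ]
  expect_equal(grp2$group, grp$group)
  expect_equal(grp2$distance, grp$distance)
})
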