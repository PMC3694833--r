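# Joint space: product reconstruction, enumeration against a brute-force
# oracle, canonical descriptors, identifier codec, Moore-Haber aliases.

test_that("product_sequence reconstructs hand-built products", {
  loc <- toy_locus()
  v <- 4
  # precise religation is the identity
  expect_equal(product_sequence(joint_descriptor(0, 0, v, "", v), loc),
               loc$top_strand)
  # fill-in of unresected 3' overhangs duplicates sequence: L=1 gives D=+3
  d <- joint_descriptor(1, 0, 0, "", v)
  expect_equal(d$D, 3)
  expect_equal(product_sequence(d, loc), "AAAACGTCGTACGTTTT")
  expect_equal(nchar(product_sequence(d, loc)), loc$n + d$D)
  # 2-base partial annealing + fill-in on a repeat-ended overhang: D=+2
  rl <- repeat_locus()
  d2 <- joint_descriptor(0, 0, 2, "", 4)
  expect_equal(d2$D, 2)
  p2 <- product_sequence(d2, rl)
  expect_equal(nchar(p2), rl$n + 2)
  # M-identity constraint rejects annealing of non-matching bases
  expect_error(product_sequence(joint_descriptor(0, 0, 2, "", 4), toy_locus()),
               "M-identity")
})

test_that("descriptor constructor enforces the algebra and insertion rules", {
  expect_error(joint_descriptor(0, 0, 1, "AC", 4), "M = 0")
  expect_error(joint_descriptor(0, 0, 0, "ACG", 4), "two inserted")
  expect_error(joint_descriptor(-1, 0, 0, "", 4), ">= 0")
  d <- joint_descriptor(3, 0, 4, "", 4)
  expect_equal(d$D, -3)
  expect_false(d$is_precise)
  expect_true(joint_descriptor(0, 0, 4, "", 4)$is_precise)
})

test_that("enumeration equals the brute-force string oracle", {
  for (loc in list(toy_locus(), repeat_locus(),
                   dsb_locus("ACGTACGTACGTACGT", 8, 2),
                   dsb_locus("AATTGGCCAATTGGCC", 8, 0))) {
    v <- loc$overhang_len
    js <- enumerate_joints(loc, NULL, L_max = 3, R_max = 3, M_max = max(v, 3))
    expect_setequal(js$product,
                    oracle_products(loc, 3, 3, max(v, 3)))
    # algebra holds exhaustively; no two templates share a product
    expect_equal(js$product_length - loc$n, js$D)
    expect_equal(js$D, v - js$L - js$R - js$M + nchar(js$I))
    expect_false(any(duplicated(js$product)))
    expect_true("precise" %in% js$joint_id)
  }
})

test_that("descriptors giving the same product collapse to one canonical
           template", {
  rl <- repeat_locus()
  # on this locus (L=0, M=1) and (L=1, M=0) both join ...CACA|A...: the
  # overhang ends in A and the first right-end base is C A C A -> check a
  # concrete collision through product strings
  js <- enumerate_joints(rl, NULL, L_max = 2, R_max = 2, M_max = 4)
  g <- nhejseq:::enumerate_descriptors(rl, 2, 2, 4)
  prods <- vapply(seq_len(nrow(g)), function(i)
    product_sequence(joint_descriptor(g$L[i], g$R[i], g$M[i], g$I[i], 4), rl),
    character(1))
  expect_true(any(duplicated(prods)))        # collisions exist...
  expect_false(any(duplicated(js$product)))  # ...and are collapsed
  # the canonical choice maximises M for at least one collided product
  dup_prod <- prods[duplicated(prods)][1]
  alts <- g[prods == dup_prod, ]
  keep <- js[js$product == dup_prod, ]
  expect_equal(keep$M, max(alts$M))
})

test_that("minimal limits give the religation family only", {
  loc <- toy_locus()
  js <- enumerate_joints(loc, NULL, L_max = 0, R_max = 0, M_max = 4,
                         insertion_alphabet = character(0))
  expect_setequal(js$product, oracle_products(loc, 0, 0, 4, character(0)))
  expect_true(loc$top_strand %in% js$product)
  expect_true(all(js$L == 0 & js$R == 0))
})

test_that("canonical_descriptor round-trips and is stable", {
  loc <- toy_locus()
  expect_true(canonical_descriptor(loc$top_strand, loc)$is_precise)
  p <- product_sequence(joint_descriptor(1, 0, 0, "", 4), loc)
  cd <- canonical_descriptor(p, loc, 3, 3, 4)
  expect_equal(product_sequence(cd, loc), p)
  expect_error(canonical_descriptor("GGGGGGGGGGGG", loc, 2, 2, 4),
               class = "nhejseq_unexplainable")
  # property: 1000 random descriptors over random loci round-trip by product
  set.seed(77)
  for (i in 1:1000) {
    rloc <- random_locus(n = 30, v = sample(0:4, 1))
    d <- random_descriptor(rloc)
    p <- product_sequence(d, rloc)
    cd <- canonical_descriptor(p, rloc, 3, 3, 6)
    expect_identical(product_sequence(cd, rloc), p)
    # canonicalisation is idempotent
    cd2 <- canonical_descriptor(product_sequence(cd, rloc), rloc, 3, 3, 6)
    expect_identical(encode_joint_id(cd2), encode_joint_id(cd))
  }
})

test_that("joint identifier codec is bijective on canonical descriptors", {
  expect_equal(encode_joint_id(joint_descriptor(0, 0, 4, "", 4)), "precise")
  expect_equal(encode_joint_id(joint_descriptor(3, 0, 4, "", 4)),
               "D-3_M4_L3_R0")
  expect_equal(encode_joint_id(joint_descriptor(1, 1, 0, "CA", 4)),
               "D+4_M0_L1_R1_Ica")
  expect_equal(encode_joint_id(joint_descriptor(4, 0, 0, "", 4)),
               "D0_M0_L4_R0")  # zero net change renders as D0
  expect_error(decode_joint_id("D1_M_L0", 4), "malformed")
  expect_error(decode_joint_id("D-9_M4_L3_R0", 4), "inconsistent")
  set.seed(5)
  for (i in 1:1000) {
    L <- sample(0:9, 1); R <- sample(0:9, 1)
    if (stats::runif(1) < 0.4) {
      M <- 0L
      I <- paste(sample(c("A", "C", "G", "T"), sample(0:2, 1), replace = TRUE),
                 collapse = "")
    } else { M <- sample(0:8, 1); I <- "" }
    v <- sample(0:6, 1)
    d <- joint_descriptor(L, R, M, I, v)
    d2 <- decode_joint_id(encode_joint_id(d), v)
    expect_identical(d2[c("D", "M", "L", "R", "I")],
                     d[c("D", "M", "L", "R", "I")])
  }
})

test_that("Moore-Haber aliases name fill-in duplications and pure deletions", {
  rl <- repeat_locus()
  # partial annealing of the CACA overhang at its CA repeat: duplicates CA
  expect_equal(alias_moore_haber(joint_descriptor(0, 0, 2, "", 4), rl), "+CA")
  expect_null(alias_moore_haber(joint_descriptor(0, 0, 4, "", 4), rl))  # precise
  expect_null(alias_moore_haber(joint_descriptor(0, 0, 0, "A", 4), rl))  # insertion
  # an unambiguous pure deletion gets a -bases alias
  loc <- toy_locus()
  del <- joint_descriptor(0, 5, 0, "", 4)  # D=-1, deletes top[9]="C"
  expect_equal(product_sequence(del, loc), "AAAACGTAGTTTT")
  expect_equal(alias_moore_haber(del, loc), "-C")
  # a deletion inside a repeat run can slide, so it has no unambiguous alias
  slid <- joint_descriptor(5, 0, 0, "", 4)  # deletes one A of the AAAA run
  expect_null(alias_moore_haber(slid, loc))
})

test_that("joint space exports round-trip through TSV", {
  fx <- classer_fixture()
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fa")
  write_joint_space(fx$templates, tsv_path = tsv, fasta_path = fa)
  back <- utils::read.table(tsv, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expect_equal(back$joint_id, fx$templates$joint_id)
  expect_equal(back$product, fx$templates$product)
  fasta <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(fasta), nrow(fx$templates))
})
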